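# Behavioural statistics: signal-detection scoring of the control
# discrimination task, accuracy aggregation by group/condition/phase, the
# pooled-variance two-sample t-test used for group contrasts, and the
# boxplot-style outlier rule. The binomial mixed-effects analyses of the
# original design are deliberately not reimplemented here; trials_long()
# exports a model-ready table for any off-the-shelf routine.

#' Signal-detection d-prime from response counts
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with the standard-normal
#' quantile `z`. Extreme rates are adjusted before the quantile transform:
#' a rate of 0 becomes 0.01 and a rate of 1 becomes 0.99.
#'
#' @param hits,misses Signal-trial counts.
#' @param fas,crs Noise-trial counts (false alarms, correct rejections).
#' @return Object of class `dprime_result` with `hit_rate`, `fa_rate`
#'   (post-adjustment) and `dprime`.
#' @examples
#' dprime(20, 0, 0, 20)$dprime   # ceiling performance -> ~4.653
#' @export
dprime <- function(hits, misses, fas, crs) {
  for (v in c(hits, misses, fas, crs)) assert_count(v, "count", min = 0L)
  n_signal <- hits + misses
  n_noise <- fas + crs
  if (n_signal == 0L || n_noise == 0L) {
    stop_invalid("need at least one signal and one noise trial")
  }
  adjust <- function(r) if (r == 0) 0.01 else if (r == 1) 0.99 else r
  hr <- adjust(hits / n_signal)
  fr <- adjust(fas / n_noise)
  structure(list(hit_rate = hr, fa_rate = fr,
                 dprime = stats::qnorm(hr) - stats::qnorm(fr)),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %.4f (hit rate %.3f, FA rate %.3f)\n",
              x$dprime, x$hit_rate, x$fa_rate))
  invisible(x)
}

#' Model-ready long trial table for a cohort
#'
#' Flattens the experimental (non-catch) trials of a cohort into one long
#' data frame with the grouping variables needed by any downstream
#' regression: `participant_id`, `group`, `task`, `condition`, `phase`,
#' `stimulus_id`, `block`, `trial_index`, `response`, `correct`. Condition
#' is the session condition for the single-cue task, the stimulus
#' ambiguity class for the multi-cue task, and `NA` for the bandit.
#'
#' @param cohort An `rl_cohort` (see [simulate_cohort()]) or a list of
#'   `rl_session` objects plus a `roster` data frame mapping
#'   `participant_id` to `group`.
#' @param roster Optional roster when `cohort` is a plain session list.
#' @return A long-format data frame, one row per experimental trial.
#' @export
trials_long <- function(cohort, roster = NULL) {
  if (inherits(cohort, "rl_cohort")) {
    roster <- cohort$roster
    sessions <- cohort$sessions
  } else {
    sessions <- cohort
  }
  amb <- multicue_design()
  rows <- lapply(sessions, function(s) {
    d <- session_design(s)
    x <- as.data.frame(s)[!s$is_catch, , drop = FALSE]
    task <- d$task %||% x$task[1L]
    x$condition <- NA_character_
    if (identical(task, "single_cue")) {
      x$condition <- d$condition %||% infer_singlecue_condition(x)
    } else if (identical(task, "multi_cue")) {
      x$condition <- amb$condition[match(as.integer(x$stimulus_id),
                                         amb$stimulus_id)]
    }
    x[, c("participant_id", "task", "condition", "phase", "stimulus_id",
          "block", "trial_index", "response", "correct")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(roster)) {
    out$group <- roster$group[match(out$participant_id, roster$participant_id)]
  } else {
    out$group <- NA_character_
  }
  out[, c("participant_id", "group", "task", "condition", "phase",
          "stimulus_id", "block", "trial_index", "response", "correct")]
}

#' Accuracy summary by group, task, condition and phase
#'
#' Computes the participant-level proportion correct for every group x
#' task x condition x phase cell (catch trials and timed-out trials are
#' excluded; correctness is "chose the most probable outcome"), then the
#' cell mean, SD and n across participants, a one-sample t-test of the
#' cell against chance (0.5), and significance stars.
#'
#' @param trials A long trial table from [trials_long()] (or any data
#'   frame with `participant_id`, `group`, `task`, `condition`, `phase`,
#'   `correct`).
#' @return Data frame of class `accuracy_summary`, one row per cell:
#'   `group`, `task`, `condition`, `phase`, `mean`, `sd`, `n`, `t`, `df`,
#'   `p_chance`, `stars`. Cells with no data are reported with `NA`
#'   statistics.
#' @export
accuracy_table <- function(trials) {
  keep <- !is.na(trials$correct)
  trials <- trials[keep, , drop = FALSE]
  if (!nrow(trials)) stop_invalid("no scored trials supplied")
  trials$condition[is.na(trials$condition)] <- "overall"
  key <- interaction(trials$group, trials$task, trials$condition,
                     trials$phase, trials$participant_id, drop = TRUE)
  prop <- tapply(trials$correct, key, mean)
  meta <- do.call(rbind, strsplit(names(prop), ".", fixed = TRUE))
  per <- data.frame(group = meta[, 1L], task = meta[, 2L],
                    condition = meta[, 3L], phase = meta[, 4L],
                    participant_id = meta[, 5L], prop = as.numeric(prop))
  cell_key <- interaction(per$group, per$task, per$condition, per$phase,
                          drop = TRUE)
  cells <- split(per, cell_key)
  out <- do.call(rbind, lapply(cells, function(cc) {
    x <- cc$prop
    tt <- if (length(x) >= 2L && stats::sd(x) > 0) {
      stats::t.test(x, mu = 0.5)
    } else NULL
    data.frame(group = cc$group[1L], task = cc$task[1L],
               condition = cc$condition[1L], phase = cc$phase[1L],
               mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               n = length(x),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p_chance = if (is.null(tt)) NA_real_ else tt$p.value)
  }))
  rownames(out) <- NULL
  out$stars <- stars_for(out$p_chance)
  out <- out[order(out$task, out$condition, out$phase, out$group), ]
  rownames(out) <- NULL
  class(out) <- c("accuracy_summary", "data.frame")
  out
}

# recover a single-cue session's condition from its own trials: the target
# feature is the one most congruent with the feedback period; perfect
# congruence means the deterministic condition
infer_singlecue_condition <- function(x) {
  bits <- do.call(rbind, strsplit(x$cue_levels, "|", fixed = TRUE))
  lvl <- as.integer(x$outcome == x$outcome[1L])
  congruence <- apply(bits, 2L, function(b) {
    p <- mean(as.integer(b) == lvl)
    max(p, 1 - p)
  })
  if (max(congruence) >= 0.999) "deterministic" else "probabilistic"
}

stars_for <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Pooled-variance independent-samples t-test
#'
#' Student's two-sample t-test with pooled variance and
#' `df = n_a + n_b - 2` (the convention implied by the task's group
#' contrasts on 52 + 52 participants, df = 102).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, and the group means.
#' @export
independent_ttest <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop_invalid("each group needs at least 2 values")
  }
  na <- length(values_a)
  nb <- length(values_b)
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop_invalid("zero pooled variance: t statistic undefined")
  ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Flag outliers by the boxplot-style rule
#'
#' Flags values outside `median(x) +/- 1.5 * IQR(x)`. With zero IQR
#' (constant data) only exact deviants from the median are flagged.
#'
#' @param values Numeric vector of length >= 4.
#' @return Logical vector, `TRUE` for flagged values.
#' @export
outlier_flag <- function(values) {
  if (!is.numeric(values) || length(values) < 4L) {
    stop_invalid("`values` must be numeric with at least 4 entries")
  }
  med <- stats::median(values)
  iqr <- stats::IQR(values)
  values < med - 1.5 * iqr | values > med + 1.5 * iqr
}
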