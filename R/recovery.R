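# Recovery harness: simulate cohorts with known parameters, fit, and score
# how well the pipeline recovers the generating model and parameters.

recovered_alpha <- function(estimates) {
  # generic learning-rate column across models
  if ("alpha" %in% names(estimates)) estimates$alpha
  else rowMeans(estimates[, c("alpha_pos", "alpha_neg")])
}

#' Parameter- and model-recovery experiment
#'
#' For each replicate: simulate a cohort from `spec` (with a
#' replicate-specific child seed), apply the exclusion rules, fit the
#' requested models to each group, and score (i) whether LOOIC selects
#' the generating model, (ii) the correlation and bias of recovered
#' versus true learning rates, and (iii) the group-difference t-test on
#' the recovered learning rates.
#'
#' @param spec A [cohort_spec()]; `spec$model` is the generating model.
#' @param models Models to fit and compare. With `method = "mle"` only the
#'   generating model is fitted (no LOOIC comparison) and the model
#'   selection score is `NA`.
#' @param n_replicates Number of independent replicates (0 gives an empty
#'   report).
#' @param method `"hierarchical"` (Bayesian group fit, LOOIC comparison)
#'   or `"mle"` (fast per-participant point estimates).
#' @param sampler Sampler configuration list for
#'   [fit_rw_hier()] (`chains`, `warmup`, `draws`, `adapt`).
#' @return Object of class `recovery_report`: per-replicate details and a
#'   summary data frame with `selection_rate` (generating model chosen by
#'   lowest LOOIC, across group fits), `alpha_cor`, `alpha_bias`,
#'   `ttest_rejection_rate` and `ordering_rate` (first group mean above
#'   second).
#' @export
recovery_experiment <- function(spec, models = c("simple", "posneg", "counterfactual"),
                                n_replicates = 1L,
                                method = c("hierarchical", "mle"),
                                sampler = list(chains = 2L, warmup = 500L,
                                               draws = 500L, adapt = 300L)) {
  stopifnot(inherits(spec, "cohort_spec"))
  method <- match.arg(method)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 0L)
  models <- match.arg(models, RW_MODELS, several.ok = TRUE)
  if (n_replicates == 0L) {
    return(structure(list(replicates = list(), summary = data.frame(),
                          spec = spec, models = models, method = method),
                     class = "recovery_report"))
  }
  rep_seeds <- child_seeds(spec$seed, n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reps[[r]] <- tryCatch(
      recovery_replicate(spec, models, method, sampler, rep_seeds[r]),
      error = function(e) list(error = conditionMessage(e)))
  }
  ok <- !vapply(reps, function(x) !is.null(x$error), logical(1))
  sel <- unlist(lapply(reps[ok], `[[`, "selected_generating"))
  summary <- data.frame(
    n_replicates = n_replicates,
    n_failed = sum(!ok),
    selection_rate = if (length(sel)) mean(sel) else NA_real_,
    alpha_cor = mean(vapply(reps[ok], `[[`, numeric(1), "alpha_cor")),
    alpha_bias = mean(vapply(reps[ok], `[[`, numeric(1), "alpha_bias")),
    ttest_rejection_rate = mean(vapply(reps[ok], function(x) x$ttest_p < 0.05,
                                       logical(1))),
    ordering_rate = mean(vapply(reps[ok], `[[`, logical(1), "ordering"))
  )
  structure(list(replicates = reps, summary = summary, spec = spec,
                 models = models, method = method),
            class = "recovery_report")
}

recovery_replicate <- function(spec, models, method, sampler, seed) {
  spec_r <- spec
  spec_r$seed <- seed
  cohort <- simulate_cohort(spec_r)
  kept <- apply_exclusions(cohort_sessions(cohort, "bandit"))
  roster <- cohort$roster[!(cohort$roster$participant_id %in% kept$excluded), ]
  by_group <- split(kept$sessions,
                    roster$group[match(vapply(kept$sessions,
                                              function(s) s$participant_id[1L], ""),
                                       roster$participant_id)])
  by_group <- by_group[spec$groups[spec$groups %in% names(by_group)]]
  selected <- logical(0)
  est <- NULL
  for (g in names(by_group)) {
    if (method == "hierarchical") {
      fits <- lapply(models, function(m) {
        fit_rw_hier(by_group[[g]], model = m, group = g,
                    chains = sampler$chains %||% 2L,
                    warmup = sampler$warmup %||% 500L,
                    draws = sampler$draws %||% 500L,
                    adapt = sampler$adapt %||% 300L,
                    seed = seed)
      })
      if (length(fits) >= 2L) {
        cmp <- compare_models(fits, group = g)
        selected <- c(selected,
                      cmp$table$model[cmp$table$best] == spec$model)
      }
      gen <- fits[[match(spec$model, models)]]
      ge <- gen$posterior_mean
    } else {
      ge <- do.call(rbind, lapply(by_group[[g]], function(s) {
        f <- fit_rw_mle(s, model = spec$model, n_restarts = 3L, seed = seed)
        cbind(data.frame(participant_id = s$participant_id[1L]),
              as.data.frame(as.list(f$estimate)))
      }))
    }
    ge$group <- g
    est <- rbind(est, ge)
  }
  est$alpha_hat <- recovered_alpha(est)
  truth <- recovered_alpha(roster)
  est$alpha_true <- truth[match(est$participant_id, roster$participant_id)]
  a <- est$alpha_hat[est$group == spec$groups[1L]]
  b <- est$alpha_hat[est$group == spec$groups[2L]]
  tt <- independent_ttest(a, b)
  list(seed = seed,
       selected_generating = if (length(selected)) selected else NULL,
       alpha_cor = stats::cor(est$alpha_true, est$alpha_hat),
       alpha_bias = mean(est$alpha_hat - est$alpha_true),
       ttest_p = tt$p, ttest_t = tt$t,
       ordering = tt$mean_a > tt$mean_b,
       estimates = est)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> generating=%s method=%s replicates=%d\n",
              x$spec$model, x$method, length(x$replicates)))
  if (nrow(x$summary)) print(signif(x$summary, 4), row.names = FALSE)
  else cat("(empty report)\n")
  invisible(x)
}

#' Fit Rescorla-Wagner models to bandit data
#'
#' The package's single fitting front end. `method = "hierarchical"` fits
#' one hierarchical Bayesian model per group of sessions (see
#' [fit_rw_hier()]); `method = "mle"` returns per-participant
#' maximum-likelihood fits (see [fit_rw_mle()]).
#'
#' @param sessions List of bandit `rl_session`s (or a single session for
#'   `method = "mle"`).
#' @param model One of `"simple"`, `"posneg"`, `"counterfactual"`.
#' @param method Estimation method.
#' @param ... Passed to the underlying fitting function.
#' @return An `rw_hfit`, or a list of `rw_mle` (one per session; a single
#'   `rw_mle` when one session is supplied).
#' @export
rw_fit <- function(sessions, model = c("simple", "posneg", "counterfactual"),
                   method = c("hierarchical", "mle"), ...) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (method == "hierarchical") {
    fit_rw_hier(sessions, model = model, ...)
  } else {
    if (inherits(sessions, "rl_session")) {
      fit_rw_mle(sessions, model = model, ...)
    } else {
      lapply(sessions, fit_rw_mle, model = model, ...)
    }
  }
}
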