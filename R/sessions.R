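# Session generators for the three task designs. A session is a data frame
# of trial records (one row per presented trial, catch trials included) in
# presentation order, with the design parameters attached as an attribute.

SESSION_COLUMNS <- c("participant_id", "task", "trial_index", "stimulus_id",
                     "cue_levels", "outcome", "response", "correct",
                     "is_catch", "phase", "block")

new_rl_session <- function(trials, design) {
  stopifnot(identical(names(trials), SESSION_COLUMNS))
  rownames(trials) <- NULL
  structure(trials, design = design, class = c("rl_session", "data.frame"))
}

#' @export
print.rl_session <- function(x, ...) {
  d <- session_design(x)
  n_exp <- sum(!x$is_catch)
  cat(sprintf("<rl_session> task=%s participant=%s trials=%d (+%d catch) seed=%s\n",
              d$task, x$participant_id[1L], n_exp, sum(x$is_catch),
              format(d$seed %||% NA)))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("... ", nrow(x) - 4L, " more trials\n", sep = "")
  invisible(x)
}

#' Design metadata of a session
#'
#' @param session An `rl_session`.
#' @return The list of design parameters (task, seed, contingencies, cue
#'   assignment, ...) recorded when the session was generated.
#' @export
session_design <- function(session) {
  attr(session, "design")
}

# phase labels for experimental trials: first half early, second half late;
# catch trials carry NA and never count towards the split
phase_labels <- function(is_catch) {
  n_exp <- sum(!is_catch)
  rank <- cumsum(!is_catch)
  out <- ifelse(rank <= ceiling(n_exp / 2), "early", "late")
  out[is_catch] <- NA_character_
  out
}

# interleave catch rows among experimental rows at uniformly drawn slots
interleave_catch <- function(n_exp, n_catch) {
  total <- n_exp + n_catch
  catch_pos <- sort(sample.int(total, n_catch))
  is_catch <- logical(total)
  is_catch[catch_pos] <- TRUE
  is_catch
}

#' Generate a multi-cue probabilistic learning session
#'
#' The 16 stimuli form a set repeated `n_repeats` times (128 experimental
#' trials by default); presentation is blocked by set and randomised within
#' each set. On every trial the stimulus' `p_high` is compared with a
#' uniform random number on \[0, 1\]: the art piece receives a high rating
#' when `p_high` exceeds the draw. Eight catch trials (a displayed
#' "high"/"low" label that simply has to be copied) are interleaved at
#' random positions. Responses are left `NA`; see [simulate_agent()] to
#' fill them in.
#'
#' @param seed Integer seed; the session is fully reproducible from it.
#' @param n_repeats Number of repetitions of the 16-stimulus set.
#' @param n_catch Number of interleaved catch trials.
#' @param cue_assignment Permutation of `1:4`, see [build_multicue_stimuli()].
#' @param participant_id Identifier stored on every trial row.
#' @param stimuli Optional stimulus table overriding
#'   [build_multicue_stimuli()] (for degenerate-probability stubs).
#' @return An `rl_session` data frame.
#' @export
generate_multicue_session <- function(seed, n_repeats = 8L, n_catch = 8L,
                                      cue_assignment = 1:4,
                                      participant_id = "sim",
                                      stimuli = NULL) {
  n_repeats <- assert_count(n_repeats, "n_repeats")
  n_catch <- assert_count(n_catch, "n_catch", min = 0L)
  stim <- stimuli %||% build_multicue_stimuli(cue_assignment)
  with_seed(seed, {
    ord <- unlist(lapply(seq_len(n_repeats), function(i) sample.int(16L)))
    n_exp <- length(ord)
    u <- stats::runif(n_exp)
    p <- stim$p_high[ord]
    outcome <- ifelse(p > u, "high", "low")
    block <- rep(seq_len(n_repeats), each = 16L)
    is_catch <- interleave_catch(n_exp, n_catch)
    catch_label <- sample(c("high", "low"), n_catch, replace = TRUE)
  })
  total <- n_exp + n_catch
  trials <- data.frame(
    participant_id = participant_id,
    task = "multi_cue",
    trial_index = seq_len(total),
    stimulus_id = NA_integer_,
    cue_levels = NA_character_,
    outcome = NA_character_,
    response = NA_character_,
    correct = NA,
    is_catch = is_catch,
    phase = phase_labels(is_catch),
    block = NA_integer_,
    stringsAsFactors = FALSE
  )
  trials$stimulus_id[!is_catch] <- stim$stimulus_id[ord]
  trials$cue_levels[!is_catch] <- stim$cue_levels[ord]
  trials$outcome[!is_catch] <- outcome
  trials$block[!is_catch] <- block
  trials$outcome[is_catch] <- catch_label
  design <- list(task = "multi_cue", seed = seed, n_repeats = n_repeats,
                 n_catch = n_catch, cue_assignment = as.integer(cue_assignment),
                 stimuli = stim)
  new_rl_session(trials, design)
}

#' Generate a single-cue probabilistic learning session
#'
#' One hundred experimental trials (50 per art period) in which exactly one
#' of four binary stimulus features is predictive of the art period shown
#' as feedback. In the deterministic condition the target feature level is
#' congruent with the feedback period on every trial; in the probabilistic
#' condition on a fixed count of 75% of trials (37/38 split between the two
#' periods at random). Non-target features are i.i.d. uniform bits. Eight
#' catch trials (a displayed period label to be copied) are interleaved.
#'
#' @param condition `"deterministic"` (100% predictive) or
#'   `"probabilistic"` (75% predictive).
#' @param seed Integer seed.
#' @param n_trials Number of experimental trials (even).
#' @param n_catch Number of catch trials.
#' @param participant_id Identifier stored on every trial row.
#' @return An `rl_session` data frame.
#' @export
generate_singlecue_session <- function(condition = c("deterministic", "probabilistic"),
                                       seed, n_trials = 100L, n_catch = 8L,
                                       participant_id = "sim") {
  condition <- match.arg(condition)
  n_trials <- assert_count(n_trials, "n_trials", min = 2L)
  if (n_trials %% 2L != 0L) stop_invalid("`n_trials` must be even (equal periods)")
  n_catch <- assert_count(n_catch, "n_catch", min = 0L)
  periods <- c("periodA", "periodB")
  half <- n_trials %/% 2L
  with_seed(seed, {
    target_slot <- sample.int(4L, 1L)
    # which target-feature level maps to which period
    level_period <- sample(periods)
    names(level_period) <- c("0", "1")
    outcome <- sample(rep(periods, each = half))
    congruent <- rep(TRUE, n_trials)
    if (condition == "probabilistic") {
      n_con <- round(0.75 * n_trials)
      base <- n_con %/% 2L
      split_a <- base + sample(0:(n_con %% 2L), 1L)   # 37 or 38 for the default
      split_b <- n_con - split_a
      congruent <- rep(FALSE, n_trials)
      idx_a <- which(outcome == periods[1L])
      idx_b <- which(outcome == periods[2L])
      congruent[sample(idx_a, split_a)] <- TRUE
      congruent[sample(idx_b, split_b)] <- TRUE
    }
    outcome_level <- ifelse(outcome == level_period[["0"]], 0L, 1L)
    target_level <- ifelse(congruent, outcome_level, 1L - outcome_level)
    other <- matrix(sample(0:1, 3L * n_trials, replace = TRUE), ncol = 3L)
    is_catch <- interleave_catch(n_trials, n_catch)
    catch_label <- sample(periods, n_catch, replace = TRUE)
  })
  feats <- matrix(NA_integer_, nrow = n_trials, ncol = 4L)
  feats[, target_slot] <- target_level
  feats[, setdiff(1:4, target_slot)] <- other
  total <- n_trials + n_catch
  trials <- data.frame(
    participant_id = participant_id,
    task = "single_cue",
    trial_index = seq_len(total),
    stimulus_id = NA_character_,
    cue_levels = NA_character_,
    outcome = NA_character_,
    response = NA_character_,
    correct = NA,
    is_catch = is_catch,
    phase = phase_labels(is_catch),
    block = 1L,
    stringsAsFactors = FALSE
  )
  trials$stimulus_id[!is_catch] <- paste0("s", seq_len(n_trials))
  trials$cue_levels[!is_catch] <- apply(feats, 1L, paste, collapse = "|")
  trials$outcome[!is_catch] <- outcome
  trials$stimulus_id[is_catch] <- "catch"
  trials$outcome[is_catch] <- catch_label
  trials$block[is_catch] <- NA_integer_
  design <- list(task = "single_cue", seed = seed, condition = condition,
                 n_trials = n_trials, n_catch = n_catch,
                 target_slot = target_slot, level_period = as.list(level_period),
                 predictive_strength = if (condition == "deterministic") 1 else 0.75)
  new_rl_session(trials, design)
}

#' Generate a two-armed bandit session
#'
#' Two options are presented on every trial; one option (chosen uniformly
#' at random at the start of the session) carries the reward with
#' probability `p_contingency` on each trial, independently. Outcomes are
#' strictly anti-correlated: exactly one option is rewarded per trial. The
#' contingency is constant throughout (no reversals). Two catch trials are
#' interleaved. There are 20 experimental trials by default.
#'
#' @param seed Integer seed.
#' @param p_contingency Probability that the better option is the rewarded
#'   one on a given trial; must lie strictly in (0, 1\] (1 permitted for
#'   degenerate stubs).
#' @param n_trials Number of experimental trials.
#' @param n_catch Number of catch trials.
#' @param participant_id Identifier stored on every trial row.
#' @return An `rl_session` data frame; the design metadata records which
#'   option is the better one.
#' @export
generate_bandit_session <- function(seed, p_contingency = 0.7, n_trials = 20L,
                                    n_catch = 2L, participant_id = "sim") {
  assert_number(p_contingency, "p_contingency", 0, 1, open_lower = TRUE)
  n_trials <- assert_count(n_trials, "n_trials")
  n_catch <- assert_count(n_catch, "n_catch", min = 0L)
  options <- c("A", "B")
  with_seed(seed, {
    better <- sample(options, 1L)
    better_rewarded <- stats::runif(n_trials) < p_contingency
    is_catch <- interleave_catch(n_trials, n_catch)
    catch_label <- sample(options, n_catch, replace = TRUE)
  })
  worse <- setdiff(options, better)
  rewarded <- ifelse(better_rewarded, better, worse)
  total <- n_trials + n_catch
  trials <- data.frame(
    participant_id = participant_id,
    task = "bandit",
    trial_index = seq_len(total),
    stimulus_id = "pair",
    cue_levels = NA_character_,
    outcome = NA_character_,
    response = NA_character_,
    correct = NA,
    is_catch = is_catch,
    phase = phase_labels(is_catch),
    block = 1L,
    stringsAsFactors = FALSE
  )
  trials$outcome[!is_catch] <- rewarded
  trials$stimulus_id[is_catch] <- "catch"
  trials$outcome[is_catch] <- catch_label
  trials$block[is_catch] <- NA_integer_
  design <- list(task = "bandit", seed = seed, p_contingency = p_contingency,
                 n_trials = n_trials, n_catch = n_catch,
                 options = options, better_option = better)
  new_rl_session(trials, design)
}

#' Write / read a session as tidy CSV with a JSON metadata side-car
#'
#' One row per trial with columns `participant_id, task, trial_index,
#' stimulus_id, cue_levels, outcome, response, correct, is_catch, phase,
#' block`. The design metadata (seed, cue assignment, contingency
#' parameters) is written alongside as `<path sans ext>.meta.json`.
#'
#' @param session An `rl_session`.
#' @param path CSV file path.
#' @return `write_session_csv` returns `path` invisibly;
#'   `read_session_csv` returns an `rl_session` (design metadata restored
#'   from the side-car when present).
#' @export
write_session_csv <- function(session, path) {
  utils::write.csv(as.data.frame(session)[, SESSION_COLUMNS], path,
                   row.names = FALSE)
  meta <- session_design(session)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

coerce_session_columns <- function(trials) {
  for (col in c("participant_id", "stimulus_id", "cue_levels", "outcome",
                "response", "phase")) {
    trials[[col]] <- as.character(trials[[col]])
  }
  trials$trial_index <- as.integer(trials$trial_index)
  trials$correct <- as.logical(trials$correct)
  trials$is_catch <- as.logical(trials$is_catch)
  trials
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SESSION_COLUMNS, names(trials))
  if (length(missing)) {
    stop_invalid("session CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  trials <- coerce_session_columns(trials)
  design <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    design <- jsonlite::read_json(sc, simplifyVector = TRUE)
  }
  new_rl_session(trials[, SESSION_COLUMNS], design)
}
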