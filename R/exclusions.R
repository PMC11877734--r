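# Preprocessing: the participant- and trial-level exclusion rules applied
# before any model fitting. Participants scoring below the catch-trial
# accuracy threshold (pooled across all their sessions) are removed
# entirely; timed-out experimental trials stay in the record but are never
# given a likelihood term (see bandit_included()).

#' Apply participant and trial exclusion rules
#'
#' Pools catch-trial accuracy per participant across every supplied
#' session and removes participants whose pooled accuracy is strictly
#' below `catch_threshold` (a participant at exactly the threshold is
#' retained). A timed-out catch trial counts as incorrect. Timed-out
#' experimental trials are reported but retained: downstream likelihood
#' code excludes them per trial.
#'
#' @param sessions List of `rl_session` objects (any mix of tasks;
#'   multiple sessions per participant are pooled).
#' @param catch_threshold Minimum pooled catch accuracy, default 0.75.
#' @return List with `sessions` (the retained sessions), `excluded`
#'   (participant ids removed), and `report` (a data frame with one row
#'   per participant: pooled catch counts, accuracy, timed-out trial
#'   count, and whether they were excluded).
#' @export
apply_exclusions <- function(sessions, catch_threshold = 0.75) {
  assert_number(catch_threshold, "catch_threshold", 0, 1)
  if (inherits(sessions, "rl_session")) sessions <- list(sessions)
  ids <- vapply(sessions, function(s) s$participant_id[1L], character(1))
  per <- lapply(split(seq_along(sessions), ids), function(ix) {
    rows <- do.call(rbind, lapply(sessions[ix], as.data.frame))
    catch <- rows[rows$is_catch, , drop = FALSE]
    # catch trials with a recorded response (timeout counts as incorrect);
    # all-NA responses mean a design-only session: no exclusion evidence
    scored <- catch[!is.na(catch$response), , drop = FALSE]
    n_correct <- sum(scored$response == scored$outcome)
    timeouts <- sum(!rows$is_catch & !is.na(rows$response) &
                      rows$response == "timeout")
    data.frame(participant_id = rows$participant_id[1L],
               n_catch = nrow(scored), catch_correct = n_correct,
               catch_accuracy = if (nrow(scored)) n_correct / nrow(scored) else NA_real_,
               n_timeout = timeouts)
  })
  report <- do.call(rbind, per)
  rownames(report) <- NULL
  if (all(report$n_catch == 0L)) {
    warning("no catch trials found in any session; ",
            "participant-level exclusion not applied")
    report$excluded <- FALSE
  } else {
    report$excluded <- !is.na(report$catch_accuracy) &
      report$catch_accuracy < catch_threshold
  }
  excluded <- report$participant_id[report$excluded]
  list(sessions = sessions[!(ids %in% excluded)],
       excluded = excluded,
       report = report)
}
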