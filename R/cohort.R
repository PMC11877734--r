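# Synthetic two-group cohorts: Rescorla-Wagner agents playing the bandit
# task (the generative inverse of the likelihood) and, optionally,
# heuristic cue-weight responders for the single- and multi-cue tasks so
# that accuracy summaries have realistic inputs. The cue-weight responder
# is a package device, not a model taken from the study.

#' Specification of a synthetic two-group cohort
#'
#' Defaults encode the study conditions: 52 participants per group,
#' bandit sessions of 20 trials at 70% contingency, counterfactual
#' generating model, group learning-rate distributions
#' Normal(0.39, 0.05) (autistic) and Normal(0.34, 0.06) (non-autistic)
#' truncated to (0, 1), inverse temperature Normal(3, 0.5) truncated to
#' (0, 10), 2% trial timeouts and 2% catch-response errors.
#'
#' @param n_per_group Participants per group.
#' @param model Generating model for the bandit task.
#' @param alpha_mean,alpha_sd Length-2 vectors (autistic, non-autistic):
#'   group learning-rate distribution before truncation to (0, 1).
#' @param beta_mean,beta_sd Inverse-temperature distribution before
#'   truncation to (0, 10), shared by both groups.
#' @param timeout_prob Per-trial probability of a timeout.
#' @param catch_error_prob Probability of answering a catch trial wrongly.
#' @param tasks Which tasks each participant plays; the bandit is the
#'   modelled task, the other two use the cue-weight responder.
#' @param n_trials,p_contingency Bandit design parameters.
#' @param groups Group labels.
#' @param seed Master seed (mandatory); every participant receives
#'   deterministic child seeds.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 52L,
                        model = c("counterfactual", "simple", "posneg"),
                        alpha_mean = c(0.39, 0.34),
                        alpha_sd = c(0.05, 0.06),
                        beta_mean = 3, beta_sd = 0.5,
                        timeout_prob = 0.02, catch_error_prob = 0.02,
                        tasks = "bandit",
                        n_trials = 20L, p_contingency = 0.7,
                        groups = c("autistic", "non_autistic"),
                        seed) {
  model <- match.arg(model)
  if (missing(seed)) stop_invalid("`seed` is mandatory for a cohort spec")
  n_per_group <- assert_count(n_per_group, "n_per_group")
  stopifnot(length(alpha_mean) == 2L, length(alpha_sd) == 2L,
            length(groups) == 2L)
  for (i in 1:2) assert_number(alpha_mean[i], "alpha_mean", 0, 1,
                               open_lower = TRUE, open_upper = TRUE)
  for (i in 1:2) assert_number(alpha_sd[i], "alpha_sd", 0, Inf)
  assert_number(beta_mean, "beta_mean", 0, 10)
  assert_number(beta_sd, "beta_sd", 0, Inf)
  assert_number(timeout_prob, "timeout_prob", 0, 1)
  assert_number(catch_error_prob, "catch_error_prob", 0, 1)
  tasks <- match.arg(tasks, c("bandit", "single_cue", "multi_cue"),
                     several.ok = TRUE)
  if (!"bandit" %in% tasks) stop_invalid("`tasks` must include the bandit task")
  structure(list(n_per_group = n_per_group, model = model,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 timeout_prob = timeout_prob,
                 catch_error_prob = catch_error_prob,
                 tasks = tasks, n_trials = assert_count(n_trials, "n_trials"),
                 p_contingency = p_contingency, groups = as.character(groups),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated-normal draws by rejection
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Parameters of the heuristic cue-weight responder
#'
#' A delta-rule associative learner over the binary stimulus features with
#' a softmax response rule, used to produce single- and multi-cue
#' responses for synthetic cohorts. It is a plausibility device for
#' accuracy summaries, not a fitted model.
#'
#' @param eta Delta-rule learning rate.
#' @param beta Softmax inverse temperature on the summed associative
#'   strength.
#' @return List of class `cueweight_params`.
#' @export
cueweight_params <- function(eta = 0.15, beta = 2) {
  assert_number(eta, "eta", 0, 1, open_lower = TRUE)
  assert_number(beta, "beta", 0, Inf)
  structure(list(model = "cueweight", eta = eta, beta = beta),
            class = "cueweight_params")
}

parse_bits <- function(cue_levels) {
  vapply(strsplit(cue_levels, "|", fixed = TRUE),
         function(b) as.numeric(b), numeric(4))
}

#' Simulate an agent playing a session design
#'
#' Fills in the `response` and `correct` columns of a generated session.
#' For the bandit task the agent is a Rescorla-Wagner learner
#' ([agent_params()]): choices are sampled from the softmax of the running
#' option values, which are then updated with the realised reward under
#' the requested model. For the single- and multi-cue tasks the agent is
#' the heuristic cue-weight responder ([cueweight_params()]). Timeouts are
#' injected independently per trial (response `"timeout"`, no learning);
#' catch trials are answered correctly with probability
#' `1 - catch_error_prob`.
#'
#' @param params [agent_params()] (bandit) or [cueweight_params()]
#'   (single-/multi-cue); a mismatch with the session's task is an error.
#' @param session An `rl_session` design (responses ignored/overwritten).
#' @param seed Integer seed; the same seed reproduces the same responses.
#' @param timeout_prob,catch_error_prob Response-noise parameters.
#' @return The session with `response` and `correct` filled in.
#' @export
simulate_agent <- function(params, session, seed, timeout_prob = 0,
                           catch_error_prob = 0) {
  d <- session_design(session)
  task <- d$task %||% session$task[1L]
  if (task == "bandit") {
    if (!inherits(params, "agent_params")) {
      stop_invalid("bandit sessions need Rescorla-Wagner `agent_params`")
    }
    simulate_bandit_agent(params, session, seed, timeout_prob, catch_error_prob)
  } else {
    if (!inherits(params, "cueweight_params")) {
      stop_invalid(task, " sessions need `cueweight_params` (the heuristic responder)")
    }
    simulate_cueweight_agent(params, session, seed, timeout_prob, catch_error_prob)
  }
}

simulate_bandit_agent <- function(params, session, seed, timeout_prob,
                                  catch_error_prob) {
  d <- session_design(session)
  opts <- as.character(d$options %||% c("A", "B"))
  better <- d$better_option %||% NA_character_
  n <- nrow(session)
  response <- character(n)
  correct <- rep(NA, n)
  with_seed(seed, {
    v <- stats::setNames(c(0, 0), opts)
    for (i in seq_len(n)) {
      if (stats::runif(1) < timeout_prob) {
        response[i] <- "timeout"
        next
      }
      if (session$is_catch[i]) {
        label <- session$outcome[i]
        ok <- stats::runif(1) >= catch_error_prob
        response[i] <- if (ok) label else setdiff(opts, label)[1L]
        correct[i] <- response[i] == label
        next
      }
      p1 <- choice_prob(v[[opts[1L]]], v[[opts[2L]]], params$beta)
      k <- if (stats::runif(1) < p1) opts[1L] else opts[2L]
      j <- setdiff(opts, k)
      response[i] <- k
      if (!is.na(better)) correct[i] <- k == better
      r <- if (identical(k, session$outcome[i])) 1 else -1
      if (params$model == "simple") {
        v[[k]] <- update_simple(v[[k]], r, params$alpha)$value
      } else if (params$model == "posneg") {
        v[[k]] <- update_posneg(v[[k]], r, params$alpha_pos,
                                params$alpha_neg)$value
      } else {
        up <- update_counterfactual(v[[k]], v[[j]], r, params$alpha)
        v[[k]] <- up$v_chosen
        v[[j]] <- up$v_unchosen
      }
    }
  })
  session$response <- response
  session$correct <- correct
  session
}

simulate_cueweight_agent <- function(params, session, seed, timeout_prob,
                                     catch_error_prob) {
  d <- session_design(session)
  task <- d$task
  if (task == "single_cue") {
    labels <- c("periodA", "periodB")
    lp <- d$level_period
    # most probable outcome per trial from the target-feature level
    target_level <- function(bits) bits[d$target_slot]
    most_probable <- function(bits) lp[[as.character(target_level(bits))]]
    outcome_sign <- function(o) if (o == labels[1L]) 1 else -1
  } else {
    labels <- c("high", "low")
    amb <- d$stimuli %||% multicue_design()
    most_probable_by_id <- ifelse(amb$p_high > 0.5, "high", "low")
    outcome_sign <- function(o) if (o == "high") 1 else -1
  }
  n <- nrow(session)
  response <- character(n)
  correct <- rep(NA, n)
  with_seed(seed, {
    w <- rep(0, 5)                       # 4 features + bias
    for (i in seq_len(n)) {
      if (stats::runif(1) < timeout_prob) {
        response[i] <- "timeout"
        next
      }
      if (session$is_catch[i]) {
        label <- session$outcome[i]
        ok <- stats::runif(1) >= catch_error_prob
        response[i] <- if (ok) label else setdiff(labels, label)[1L]
        correct[i] <- response[i] == label
        next
      }
      bits <- as.numeric(strsplit(session$cue_levels[i], "|", fixed = TRUE)[[1L]])
      x <- c(2 * bits - 1, 1)            # +/-1 coding plus bias
      u <- sum(w * x)
      p_first <- stats::plogis(params$beta * u)
      response[i] <- if (stats::runif(1) < p_first) labels[1L] else labels[2L]
      if (task == "single_cue") {
        correct[i] <- response[i] == most_probable(bits)
      } else {
        sid <- as.integer(session$stimulus_id[i])
        correct[i] <- response[i] == most_probable_by_id[match(sid, amb$stimulus_id)]
      }
      y <- outcome_sign(session$outcome[i])
      w <- w + params$eta * (y - u) * x / length(x)
    }
  })
  session$response <- response
  session$correct <- correct
  session
}

#' Simulate a complete two-group cohort
#'
#' Draws per-participant true parameters from the group distributions of
#' the spec, generates each requested task design with deterministic
#' per-participant child seeds, and lets the agents play them. True
#' parameters are retained on the roster for recovery scoring.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `rl_cohort`: `roster` (participant id, group,
#'   true parameters), `sessions` (list of played `rl_session`s across all
#'   requested tasks) and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  total <- 2L * n
  ids <- c(sprintf("%s_%02d", substr(spec$groups[1L], 1, 3), seq_len(n)),
           sprintf("%s_%02d", substr(spec$groups[2L], 1, 3), seq_len(n)))
  group <- rep(spec$groups, each = n)
  seeds <- child_seeds(spec$seed, 3L + 9L * total)
  roster <- data.frame(participant_id = ids, group = group,
                       model = spec$model, stringsAsFactors = FALSE)
  alpha <- c(
    with_seed(seeds[1L], rtruncnorm(n, spec$alpha_mean[1L], spec$alpha_sd[1L], 0, 1)),
    with_seed(seeds[2L], rtruncnorm(n, spec$alpha_mean[2L], spec$alpha_sd[2L], 0, 1)))
  beta <- with_seed(seeds[3L],
                    rtruncnorm(total, spec$beta_mean, spec$beta_sd, 0, 10))
  if (spec$model == "posneg") {
    roster$alpha_pos <- alpha
    roster$alpha_neg <- alpha
  } else {
    roster$alpha <- alpha
  }
  roster$beta <- beta
  sessions <- list()
  resp <- cueweight_params()
  for (i in seq_len(total)) {
    base <- 3L + 9L * (i - 1L)
    par_i <- if (spec$model == "posneg") {
      agent_params("posneg", alpha_pos = alpha[i], alpha_neg = alpha[i],
                   beta = beta[i])
    } else {
      agent_params(spec$model, alpha = alpha[i], beta = beta[i])
    }
    des <- generate_bandit_session(seeds[base + 1L],
                                   p_contingency = spec$p_contingency,
                                   n_trials = spec$n_trials,
                                   participant_id = ids[i])
    sessions[[length(sessions) + 1L]] <-
      simulate_agent(par_i, des, seeds[base + 2L],
                     timeout_prob = spec$timeout_prob,
                     catch_error_prob = spec$catch_error_prob)
    if ("single_cue" %in% spec$tasks) {
      for (k in 1:2) {
        cond <- c("deterministic", "probabilistic")[k]
        des <- generate_singlecue_session(cond, seeds[base + 2L + k],
                                          participant_id = ids[i])
        sessions[[length(sessions) + 1L]] <-
          simulate_agent(resp, des, seeds[base + 4L + k],
                         timeout_prob = spec$timeout_prob,
                         catch_error_prob = spec$catch_error_prob)
      }
    }
    if ("multi_cue" %in% spec$tasks) {
      ca <- with_seed(seeds[base + 9L], sample.int(4L))
      des <- generate_multicue_session(seeds[base + 7L], cue_assignment = ca,
                                       participant_id = ids[i])
      sessions[[length(sessions) + 1L]] <-
        simulate_agent(resp, des, seeds[base + 8L],
                       timeout_prob = spec$timeout_prob,
                       catch_error_prob = spec$catch_error_prob)
    }
  }
  structure(list(roster = roster, sessions = sessions, spec = spec),
            class = "rl_cohort")
}

#' @export
print.rl_cohort <- function(x, ...) {
  cat(sprintf("<rl_cohort> %d participants (%s), tasks: %s, %d sessions, seed=%d\n",
              nrow(x$roster),
              paste(table(x$roster$group), names(table(x$roster$group)),
                    collapse = " + "),
              paste(x$spec$tasks, collapse = ", "),
              length(x$sessions), x$spec$seed))
  invisible(x)
}

#' Sessions of a cohort restricted to one task
#'
#' @param cohort An `rl_cohort`.
#' @param task Task name.
#' @return List of sessions.
#' @export
cohort_sessions <- function(cohort, task = "bandit") {
  keep <- vapply(cohort$sessions,
                 function(s) identical(session_design(s)$task, task),
                 logical(1))
  cohort$sessions[keep]
}

#' Write cohort trial and roster CSV files
#'
#' Emits the standard trial CSV (all sessions stacked), a roster CSV with
#' the true generating parameters, and a metadata JSON with the spec and
#' master seed.
#'
#' @param cohort An `rl_cohort`.
#' @param dir Output directory (created if its parent exists).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = FALSE)
  trials <- do.call(rbind, lapply(cohort$sessions, as.data.frame))
  paths <- c(trials = file.path(dir, "trials.csv"),
             roster = file.path(dir, "roster.csv"),
             meta = file.path(dir, "metadata.json"))
  utils::write.csv(trials, paths[["trials"]], row.names = FALSE)
  utils::write.csv(cohort$roster, paths[["roster"]], row.names = FALSE)
  jsonlite::write_json(unclass(cohort$spec), paths[["meta"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
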