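# shared builders for hand-crafted sessions and quick simulated data

# bandit session from explicit choice/reward sequences (no generator)
manual_bandit <- function(choices, rewarded, is_catch = NULL,
                          participant_id = "p1", better = "A") {
  n <- length(choices)
  if (is.null(is_catch)) is_catch <- rep(FALSE, n)
  df <- data.frame(
    participant_id = participant_id, task = "bandit",
    trial_index = seq_len(n), stimulus_id = "pair",
    cue_levels = NA_character_, outcome = rewarded, response = choices,
    correct = NA, is_catch = is_catch, phase = NA_character_, block = 1L,
    stringsAsFactors = FALSE
  )
  structure(df,
            design = list(task = "bandit", options = c("A", "B"),
                          better_option = better),
            class = c("rl_session", "data.frame"))
}

# a played bandit session from a known agent
played_bandit <- function(seed, alpha = 0.4, beta = 3,
                          model = "counterfactual", n_trials = 20L,
                          p_contingency = 0.7, participant_id = "sim",
                          timeout_prob = 0, catch_error_prob = 0) {
  des <- generate_bandit_session(seed, p_contingency = p_contingency,
                                 n_trials = n_trials,
                                 participant_id = participant_id)
  par <- if (model == "posneg") {
    agent_params("posneg", alpha_pos = alpha, alpha_neg = alpha, beta = beta)
  } else {
    agent_params(model, alpha = alpha, beta = beta)
  }
  simulate_agent(par, des, seed = seed + 1000L,
                 timeout_prob = timeout_prob,
                 catch_error_prob = catch_error_prob)
}

# independent trial-by-trial likelihood oracle: naive arithmetic loop,
# written against the model equations, sharing no code with the package
oracle_bandit_loglik <- function(model, alpha, beta, session,
                                 alpha_pos = NULL, alpha_neg = NULL) {
  rows <- as.data.frame(session)
  rows <- rows[!rows$is_catch & !is.na(rows$response) &
                 rows$response != "timeout", ]
  vA <- 0
  vB <- 0
  total <- 0
  pw <- numeric(0)
  for (i in seq_len(nrow(rows))) {
    chose_a <- rows$response[i] == "A"
    va <- if (chose_a) vA else vB
    vb <- if (chose_a) vB else vA
    p <- 1 / (1 + exp(-beta * (va - vb)))
    pw <- c(pw, log(p))
    r <- if (rows$response[i] == rows$outcome[i]) 1 else -1
    if (model == "simple") {
      if (chose_a) vA <- vA + alpha * (r - vA) else vB <- vB + alpha * (r - vB)
    } else if (model == "posneg") {
      d <- r - (if (chose_a) vA else vB)
      a <- if (d >= 0) alpha_pos else alpha_neg
      if (chose_a) vA <- vA + a * d else vB <- vB + a * d
    } else {
      if (chose_a) {
        vA <- vA + alpha * (r - vA)
        vB <- vB + alpha * (-r - vB)
      } else {
        vB <- vB + alpha * (r - vB)
        vA <- vA + alpha * (-r - vA)
      }
    }
  }
  list(total = sum(pw), pointwise = pw)
}
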