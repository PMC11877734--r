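# The three Rescorla-Wagner value-update rules, the softmax choice rule,
# and trial-by-trial session log-likelihood for two-armed bandit data.
#
# Conventions: rewards are coded R = +1 (rewarded) / -1 (not rewarded);
# option values start at 0; the choice-probability term for a trial is
# accumulated before the value update of the same trial (predict, then
# learn). With this coding and zero initialisation all values stay in
# [-1, 1].

RW_MODELS <- c("simple", "posneg", "counterfactual")

# number of free parameters per model (used for comparison tie-breaks)
rw_n_params <- function(model) {
  switch(model, simple = 2L, posneg = 3L, counterfactual = 2L,
         stop_invalid("unknown model: ", model))
}

#' Construct and validate model parameters
#'
#' @param model One of `"simple"`, `"posneg"`, `"counterfactual"`.
#' @param alpha Learning rate in (0, 1) (`simple` and `counterfactual`).
#' @param alpha_pos,alpha_neg Learning rates in (0, 1) for positive
#'   (including zero) and negative prediction errors (`posneg` only).
#' @param beta Inverse temperature of the softmax choice rule, in \[0, 10\].
#' @return A named list of class `agent_params`.
#' @export
agent_params <- function(model = c("simple", "posneg", "counterfactual"),
                         alpha = NULL, alpha_pos = NULL, alpha_neg = NULL,
                         beta = 1) {
  model <- match.arg(model)
  assert_number(beta, "beta", 0, 10)
  p <- list(model = model, beta = beta)
  if (model == "posneg") {
    assert_number(alpha_pos, "alpha_pos", 0, 1, open_lower = TRUE, open_upper = TRUE)
    assert_number(alpha_neg, "alpha_neg", 0, 1, open_lower = TRUE, open_upper = TRUE)
    p$alpha_pos <- alpha_pos
    p$alpha_neg <- alpha_neg
  } else {
    assert_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
    p$alpha <- alpha
  }
  structure(p, class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "model")])
  cat("<agent_params> model=", x$model, ": ",
      paste(names(vals), signif(vals, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Rescorla-Wagner value updates
#'
#' `update_simple()` applies the delta rule to the chosen option only:
#' `delta = R - V`, `V' = V + alpha * delta`. `update_posneg()` is the dual
#' learning-rate variant: `alpha_pos` scales non-negative prediction errors
#' (the zero-difference case included), `alpha_neg` negative ones.
#' `update_counterfactual()` updates the chosen option with `R` and the
#' unchosen option with the fictitious outcome `-R`, so both options learn
#' on every trial. All functions are vectorised over states and rewards.
#'
#' @param v,v_chosen,v_unchosen Current expected values.
#' @param reward Realised reward for the chosen option (+1 / -1 coding in
#'   the bandit task).
#' @param alpha,alpha_pos,alpha_neg Learning rates in (0, 1).
#' @return `update_simple()` and `update_posneg()`: list with `value` and
#'   `delta`. `update_counterfactual()`: list with `v_chosen`,
#'   `v_unchosen`, `delta_chosen`, `delta_unchosen`.
#' @export
update_simple <- function(v, reward, alpha) {
  check_alpha(alpha)
  delta <- reward - v
  list(value = v + alpha * delta, delta = delta)
}

#' @rdname update_simple
#' @export
update_posneg <- function(v, reward, alpha_pos, alpha_neg) {
  check_alpha(alpha_pos, "alpha_pos")
  check_alpha(alpha_neg, "alpha_neg")
  delta <- reward - v
  a <- ifelse(delta >= 0, alpha_pos, alpha_neg)
  list(value = v + a * delta, delta = delta)
}

#' @rdname update_simple
#' @export
update_counterfactual <- function(v_chosen, v_unchosen, reward, alpha) {
  check_alpha(alpha)
  delta_c <- reward - v_chosen
  delta_nc <- -reward - v_unchosen
  list(v_chosen = v_chosen + alpha * delta_c,
       v_unchosen = v_unchosen + alpha * delta_nc,
       delta_chosen = delta_c, delta_unchosen = delta_nc)
}

check_alpha <- function(alpha, name = "alpha") {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha <= 0) || any(alpha >= 1)) {
    stop_invalid("`", name, "` must lie strictly in (0, 1)")
  }
  invisible(alpha)
}

#' Softmax choice probability for a two-option task
#'
#' `p(a) = 1 / (1 + exp(-beta * (v_a - v_b)))`; `beta = 0` gives
#' indifference (p = 0.5) regardless of the values.
#'
#' @param v_a,v_b Option values.
#' @param beta Inverse temperature, >= 0.
#' @return Probability of choosing option a. Vectorised.
#' @export
choice_prob <- function(v_a, v_b, beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta < 0)) {
    stop_invalid("`beta` must be >= 0")
  }
  stats::plogis(beta * (v_a - v_b))
}

# included trials of a bandit session: experimental, responded
bandit_included <- function(session) {
  !session$is_catch & !is.na(session$response) & session$response != "timeout"
}

#' Trial-by-trial log-likelihood of a bandit session
#'
#' Runs the requested model forward through the session in presentation
#' order: option values start at 0; each included trial contributes the log
#' choice probability of the observed response *before* the values are
#' updated with the realised reward (+1 when the chosen option was the
#' rewarded one, -1 otherwise). Catch trials and timed-out trials
#' contribute no likelihood term and trigger no value update.
#'
#' @param params An [agent_params()] object.
#' @param session A bandit `rl_session` with responses.
#' @return List with `total` (sum of pointwise terms; 0 when no trial is
#'   included), `pointwise` (one entry per included trial, in order) and
#'   `n` (number of included trials).
#' @export
session_loglik <- function(params, session) {
  if (!inherits(params, "agent_params")) {
    stop_invalid("`params` must be an `agent_params` object")
  }
  if (!all(session$task == "bandit")) {
    stop_invalid("`session` must come from the bandit task")
  }
  inc <- bandit_included(session)
  ch <- session$response[inc]
  rewarded <- session$outcome[inc]
  opts <- session_design(session)$options %||% sort(unique(c(ch, rewarded)))
  opts <- as.character(opts)
  if (length(opts) > 2L) stop_invalid("bandit session has more than two options")
  if (length(opts) < 2L) opts <- unique(c(opts, "A", "B"))[1:2]
  ki <- match(ch, opts)
  ri <- match(rewarded, opts)
  if (anyNA(ki) || anyNA(ri)) {
    stop_invalid("responses/outcomes outside the session's two options")
  }
  # inline arithmetic (equivalent to the update_* primitives; equivalence
  # is covered by tests) to keep repeated likelihood evaluation cheap
  beta <- params$beta
  model <- params$model
  alpha <- params$alpha
  ap <- params$alpha_pos
  an <- params$alpha_neg
  v <- c(0, 0)
  pw <- numeric(length(ki))
  for (i in seq_along(pw)) {
    k <- ki[i]
    j <- 3L - k
    pw[i] <- stats::plogis(beta * (v[k] - v[j]), log.p = TRUE)
    r <- if (k == ri[i]) 1 else -1
    if (model == "simple") {
      v[k] <- v[k] + alpha * (r - v[k])
    } else if (model == "posneg") {
      d <- r - v[k]
      v[k] <- v[k] + (if (d >= 0) ap else an) * d
    } else {
      v[k] <- v[k] + alpha * (r - v[k])
      v[j] <- v[j] + alpha * (-r - v[j])
    }
  }
  list(total = sum(pw), pointwise = pw, n = length(pw))
}
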