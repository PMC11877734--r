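# Per-participant maximum-likelihood estimation: a fast point-estimate
# companion to the hierarchical fit. Box-constrained quasi-Newton with
# seeded multi-start.

ALPHA_EPS <- 1e-4
BETA_MAX <- 10

mle_par_info <- function(model) {
  if (model == "posneg") {
    list(names = c("alpha_pos", "alpha_neg", "beta"),
         lower = c(ALPHA_EPS, ALPHA_EPS, 0),
         upper = c(1 - ALPHA_EPS, 1 - ALPHA_EPS, BETA_MAX),
         mid = c(0.5, 0.5, 1))
  } else {
    list(names = c("alpha", "beta"),
         lower = c(ALPHA_EPS, 0),
         upper = c(1 - ALPHA_EPS, BETA_MAX),
         mid = c(0.5, 1))
  }
}

params_from_vector <- function(model, par, names) {
  p <- as.list(par)
  names(p) <- names
  do.call(agent_params, c(list(model = model), p))
}

#' Maximum-likelihood fit of one bandit session
#'
#' Maximises [session_loglik()] over the model parameters within their
#' bounds (learning rates in (0, 1), inverse temperature in \[0, 10\])
#' using L-BFGS-B from `n_restarts` seeded random starts plus a fixed
#' midpoint start.
#'
#' @param session A bandit `rl_session` with responses.
#' @param model One of `"simple"`, `"posneg"`, `"counterfactual"`.
#' @param n_restarts Number of random restarts.
#' @param seed Integer seed for the restart jitter.
#' @return An object of class `rw_mle` with elements `params` (an
#'   [agent_params()]), `estimate` (named vector), `logLik`, `n_obs`,
#'   `identifiable` (`FALSE` when the likelihood is essentially flat: the
#'   fitted inverse temperature is ~0, or the fit fails to beat the
#'   random-choice model by a likelihood-ratio margin),
#'   `model` and `convergence`.
#' @export
fit_rw_mle <- function(session, model = c("simple", "posneg", "counterfactual"),
                       n_restarts = 10L, seed = 1L) {
  model <- match.arg(model)
  n_restarts <- assert_count(n_restarts, "n_restarts", min = 0L)
  if (sum(bandit_included(session)) == 0L) {
    stop_invalid("no included trials: cannot fit (all trials timed out or catch)")
  }
  info <- mle_par_info(model)
  negll <- function(par) {
    par <- pmin(pmax(par, info$lower), info$upper)
    -session_loglik(params_from_vector(model, par, info$names), session)$total
  }
  starts <- rbind(info$mid,
                  with_seed(seed, {
                    matrix(stats::runif(n_restarts * length(info$mid),
                                        info$lower + 0.01,
                                        pmin(info$upper, c(rep(0.98, length(info$mid) - 1L), 8))),
                           ncol = length(info$mid), byrow = TRUE)
                  }))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], negll, method = "L-BFGS-B",
                   lower = info$lower, upper = info$upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_invalid("optimisation failed for every start")
  est <- pmin(pmax(best$par, info$lower), info$upper)
  names(est) <- info$names
  n_inc <- sum(bandit_included(session))
  # alpha is unidentifiable when the likelihood is essentially flat: either
  # the fitted inverse temperature is ~0 or the fit beats the random-choice
  # model by less than a likelihood-ratio margin
  flat <- est[["beta"]] <= 1e-3 ||
    (-best$value - n_inc * log(0.5)) < stats::qchisq(0.95, 2) / 2
  structure(list(
    model = model,
    params = params_from_vector(model, est, info$names),
    estimate = est,
    logLik = -best$value,
    n_obs = n_inc,
    identifiable = !flat,
    convergence = best$convergence,
    participant_id = session$participant_id[1L]
  ), class = "rw_mle")
}

#' @export
print.rw_mle <- function(x, ...) {
  cat("<rw_mle> model=", x$model, " participant=", x$participant_id,
      " logLik=", format(x$logLik, digits = 6),
      " n=", x$n_obs, if (!x$identifiable) "  [alpha unidentifiable: beta ~ 0]",
      "\n", sep = "")
  print(signif(x$estimate, 4))
  invisible(x)
}

#' @export
coef.rw_mle <- function(object, ...) object$estimate

#' @export
logLik.rw_mle <- function(object, ...) {
  structure(object$logLik, df = rw_n_params(object$model),
            nobs = object$n_obs, class = "logLik")
}
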