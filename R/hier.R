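# Hierarchical Bayesian estimation of the Rescorla-Wagner models, one
# group per fit, via JAGS (rjags). Individual parameters are non-centred
# deviations on a latent normal scale, mapped to their ranges by the
# standard-normal CDF: alpha = phi(mu_a + sig_a * z), beta = 10 * phi(...).
# Hyperpriors: mu ~ N(0, 1); sig_alpha ~ half-N(0, 0.2); sig_beta ~
# half-N(0, 1). Pointwise log-likelihood draws are computed in R from the
# posterior parameter draws with the package's own likelihood recursion.

jags_hyper_block <- function(prefix, sd) {
  prec <- 1 / sd^2
  sprintf("  mu_%s ~ dnorm(0, 1)\n  sig_%s ~ dnorm(0, %.8g) T(0,)\n",
          prefix, prefix, prec)
}

jags_model_string <- function(model) {
  head <- "model {\n"
  beta_block <- paste0(jags_hyper_block("b", 1),
                       "  for (s in 1:S) {\n    zb[s] ~ dnorm(0, 1)\n",
                       "    beta[s] <- 10 * phi(mu_b + sig_b * zb[s])\n  }\n")
  if (model == "posneg") {
    par_block <- paste0(
      jags_hyper_block("ap", 0.2), jags_hyper_block("an", 0.2),
      "  for (s in 1:S) {\n",
      "    zap[s] ~ dnorm(0, 1)\n    zan[s] ~ dnorm(0, 1)\n",
      "    alpha_pos[s] <- phi(mu_ap + sig_ap * zap[s])\n",
      "    alpha_neg[s] <- phi(mu_an + sig_an * zan[s])\n  }\n")
    update_block <- paste0(
      "      d[s,t] <- rw[s,t] - V[s,t,kk[s,t]]\n",
      "      at[s,t] <- step(d[s,t]) * alpha_pos[s] + (1 - step(d[s,t])) * alpha_neg[s]\n",
      "      for (o in 1:2) {\n",
      "        V[s,t+1,o] <- V[s,t,o] + equals(kk[s,t], o) * at[s,t] * (rw[s,t] - V[s,t,o])\n",
      "      }\n")
  } else if (model == "counterfactual") {
    par_block <- paste0(
      jags_hyper_block("a", 0.2),
      "  for (s in 1:S) {\n    za[s] ~ dnorm(0, 1)\n",
      "    alpha[s] <- phi(mu_a + sig_a * za[s])\n  }\n")
    update_block <- paste0(
      "      for (o in 1:2) {\n",
      "        V[s,t+1,o] <- V[s,t,o] + alpha[s] * (equals(kk[s,t], o) * (rw[s,t] - V[s,t,o])",
      " + (1 - equals(kk[s,t], o)) * (-rw[s,t] - V[s,t,o]))\n",
      "      }\n")
  } else {
    par_block <- paste0(
      jags_hyper_block("a", 0.2),
      "  for (s in 1:S) {\n    za[s] ~ dnorm(0, 1)\n",
      "    alpha[s] <- phi(mu_a + sig_a * za[s])\n  }\n")
    update_block <- paste0(
      "      for (o in 1:2) {\n",
      "        V[s,t+1,o] <- V[s,t,o] + equals(kk[s,t], o) * alpha[s] * (rw[s,t] - V[s,t,o])\n",
      "      }\n")
  }
  lik_block <- paste0(
    "  for (s in 1:S) {\n",
    "    V[s,1,1] <- 0\n    V[s,1,2] <- 0\n",
    "    for (t in 1:Tn[s]) {\n",
    "      logit(p1[s,t]) <- beta[s] * (V[s,t,1] - V[s,t,2])\n",
    "      ch[s,t] ~ dbern(p1[s,t])\n",
    update_block,
    "    }\n  }\n")
  paste0(head, par_block, beta_block, lik_block, "}\n")
}

# ragged data arrays from a list of bandit sessions
prepare_bandit_data <- function(sessions) {
  if (!length(sessions)) stop_invalid("no sessions supplied")
  per <- lapply(sessions, function(s) {
    if (!all(s$task == "bandit")) stop_invalid("all sessions must be bandit sessions")
    inc <- bandit_included(s)
    opts <- as.character(session_design(s)$options %||%
                           sort(unique(s$outcome[!s$is_catch])))
    ch <- s$response[inc]
    rewarded <- s$outcome[inc]
    list(id = s$participant_id[1L],
         ch1 = as.integer(ch == opts[1L]),          # 1 if option 1 chosen
         kk = ifelse(ch == opts[1L], 1L, 2L),       # chosen option index
         rw = ifelse(ch == rewarded, 1, -1),
         trial_index = s$trial_index[inc])
  })
  n_inc <- vapply(per, function(p) length(p$ch1), integer(1))
  empty <- n_inc == 0L
  if (any(empty)) {
    warning("dropping participant(s) with no included trials: ",
            paste(vapply(per[empty], `[[`, "", "id"), collapse = ", "))
    per <- per[!empty]
    n_inc <- n_inc[!empty]
  }
  S <- length(per)
  if (S < 2L) stop_invalid("hierarchical fitting needs at least 2 participants")
  Tmax <- max(n_inc)
  pad <- function(x, fill) c(x, rep(fill, Tmax - length(x)))
  list(S = S, Tn = n_inc, Tmax = Tmax,
       ids = vapply(per, `[[`, "", "id"),
       ch = t(vapply(per, function(p) pad(p$ch1, NA_integer_), integer(Tmax))),
       kk = t(vapply(per, function(p) pad(p$kk, 1L), integer(Tmax))),
       rw = t(vapply(per, function(p) pad(p$rw, 0), numeric(Tmax))),
       obs = data.frame(
         participant_id = rep(vapply(per, `[[`, "", "id"), n_inc),
         trial_index = unlist(lapply(per, `[[`, "trial_index"))))
}

hier_monitors <- function(model) {
  if (model == "posneg") {
    c("mu_ap", "sig_ap", "mu_an", "sig_an", "mu_b", "sig_b",
      "alpha_pos", "alpha_neg", "beta")
  } else {
    c("mu_a", "sig_a", "mu_b", "sig_b", "alpha", "beta")
  }
}

hier_inits <- function(model, S, chains, seed) {
  lapply(seq_len(chains), function(k) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (seed %% 1000000L) * 100L + k,
                mu_b = 0, sig_b = 0.5, zb = rep(0, S))
    if (model == "posneg") {
      ini <- c(ini, list(mu_ap = 0, sig_ap = 0.1, mu_an = 0, sig_an = 0.1,
                         zap = rep(0, S), zan = rep(0, S)))
    } else {
      ini <- c(ini, list(mu_a = 0, sig_a = 0.1, za = rep(0, S)))
    }
    ini
  })
}

#' Hierarchical Bayesian group fit of a Rescorla-Wagner model
#'
#' Fits one group of bandit sessions with a hierarchical model: individual
#' learning rates and inverse temperatures are probit-transformed normal
#' deviates around group-level location/scale parameters (non-centred).
#' Sampling is by MCMC through JAGS; pointwise log-likelihood draws for
#' PSIS-LOO are computed from the posterior parameter draws.
#'
#' @param sessions List of bandit `rl_session` objects (>= 2 participants),
#'   already preprocessed (see [apply_exclusions()]); timed-out and catch
#'   trials are never included in the likelihood.
#' @param model One of `"simple"`, `"posneg"`, `"counterfactual"`.
#' @param group Optional group label stored on the fit.
#' @param chains,warmup,draws,adapt,thin Sampler configuration: number of
#'   chains, burn-in iterations, retained iterations per chain, adaptation
#'   steps, thinning.
#' @param seed Integer seed; chains are seeded deterministically from it.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `rw_hfit`: posterior draws (`draws`, chains
#'   stacked), per-participant posterior means (`posterior_mean`),
#'   pointwise log-likelihood draws (`log_lik`, draws x included trials,
#'   with `obs` identifying each column), sampler diagnostics
#'   (`diagnostics$rhat`, `$ess`, `$converged`; the Gibbs sampler has no
#'   divergence diagnostic, so `$divergences` is `NA`), and the sampler
#'   configuration.
#' @export
fit_rw_hier <- function(sessions, model = c("simple", "posneg", "counterfactual"),
                        group = NULL, chains = 4L, warmup = 1000L, draws = 1000L,
                        adapt = 500L, thin = 1L, seed = 1L, quiet = TRUE) {
  model <- match.arg(model)
  chains <- assert_count(chains, "chains")
  warmup <- assert_count(warmup, "warmup", min = 0L)
  draws <- assert_count(draws, "draws", min = 2L)
  dat <- prepare_bandit_data(sessions)
  jd <- list(S = dat$S, Tn = dat$Tn, ch = dat$ch, kk = dat$kk, rw = dat$rw)
  jm <- rjags::jags.model(textConnection(jags_model_string(model)), data = jd,
                          inits = hier_inits(model, dat$S, chains, seed),
                          n.chains = chains, n.adapt = adapt, quiet = quiet)
  if (warmup > 0L) stats::update(jm, warmup, progress.bar = if (quiet) "none" else "text")
  sam <- rjags::coda.samples(jm, hier_monitors(model), n.iter = draws * thin,
                             thin = thin,
                             progress.bar = if (quiet) "none" else "text")
  mat <- as.matrix(sam)
  diagnostics <- hier_diagnostics(sam)
  post <- hier_posterior_means(model, mat, dat)
  ll <- loglik_draws(model, mat, dat)
  structure(list(
    model = model, group = group, participants = dat$ids,
    draws = mat, posterior_mean = post$individual, hyper = post$hyper,
    log_lik = ll, obs = dat$obs, n_obs = nrow(dat$obs),
    diagnostics = diagnostics,
    sampler = list(chains = chains, warmup = warmup, draws = draws,
                   adapt = adapt, thin = thin, seed = seed)
  ), class = "rw_hfit")
}

hier_diagnostics <- function(sam) {
  nchains <- coda::nchain(sam)
  rhat <- tryCatch({
    if (nchains >= 2L) {
      gd <- coda::gelman.diag(sam, autoburnin = FALSE, multivariate = FALSE)
      stats::setNames(gd$psrf[, 1L], rownames(gd$psrf))
    } else NULL
  }, error = function(e) NULL)
  ess <- tryCatch(coda::effectiveSize(sam), error = function(e) NULL)
  max_rhat <- if (length(rhat)) max(rhat, na.rm = TRUE) else NA_real_
  converged <- if (is.na(max_rhat)) NA else max_rhat <= 1.1
  if (isFALSE(converged)) {
    warning("possible non-convergence: max split-chain Rhat = ",
            format(max_rhat, digits = 4))
  }
  list(rhat = rhat, ess = ess, max_rhat = max_rhat, converged = converged,
       divergences = NA_integer_)
}

hier_posterior_means <- function(model, mat, dat) {
  cm <- colMeans(mat)
  pick <- function(stem) cm[paste0(stem, "[", seq_len(dat$S), "]")]
  individual <- data.frame(participant_id = dat$ids, row.names = NULL)
  if (model == "posneg") {
    individual$alpha_pos <- unname(pick("alpha_pos"))
    individual$alpha_neg <- unname(pick("alpha_neg"))
    hyper_names <- c("mu_ap", "sig_ap", "mu_an", "sig_an", "mu_b", "sig_b")
  } else {
    individual$alpha <- unname(pick("alpha"))
    hyper_names <- c("mu_a", "sig_a", "mu_b", "sig_b")
  }
  individual$beta <- unname(pick("beta"))
  list(individual = individual, hyper = cm[hyper_names])
}

# pointwise log-likelihood draws, vectorised over posterior draws
loglik_draws <- function(model, mat, dat) {
  ndraw <- nrow(mat)
  ll <- matrix(NA_real_, ndraw, sum(dat$Tn))
  col <- 0L
  for (s in seq_len(dat$S)) {
    beta <- mat[, paste0("beta[", s, "]")]
    if (model == "posneg") {
      ap <- mat[, paste0("alpha_pos[", s, "]")]
      an <- mat[, paste0("alpha_neg[", s, "]")]
    } else {
      a <- mat[, paste0("alpha[", s, "]")]
    }
    v1 <- numeric(ndraw)
    v2 <- numeric(ndraw)
    for (t in seq_len(dat$Tn[s])) {
      p1 <- stats::plogis(beta * (v1 - v2))
      col <- col + 1L
      ll[, col] <- if (dat$ch[s, t] == 1L) log(p1) else log1p(-p1)
      r <- dat$rw[s, t]
      chosen1 <- dat$kk[s, t] == 1L
      if (model == "simple") {
        if (chosen1) v1 <- v1 + a * (r - v1) else v2 <- v2 + a * (r - v2)
      } else if (model == "posneg") {
        if (chosen1) {
          d <- r - v1
          v1 <- v1 + ifelse(d >= 0, ap, an) * d
        } else {
          d <- r - v2
          v2 <- v2 + ifelse(d >= 0, ap, an) * d
        }
      } else {
        if (chosen1) {
          v1 <- v1 + a * (r - v1)
          v2 <- v2 + a * (-r - v2)
        } else {
          v2 <- v2 + a * (r - v2)
          v1 <- v1 + a * (-r - v1)
        }
      }
    }
  }
  ll
}

#' @export
print.rw_hfit <- function(x, ...) {
  cat(sprintf("<rw_hfit> model=%s group=%s participants=%d obs=%d chains=%d draws=%d\n",
              x$model, x$group %||% "-", length(x$participants), x$n_obs,
              x$sampler$chains, nrow(x$draws)))
  cat("group-level (transformed scale):\n")
  print(signif(x$hyper, 4))
  cat(sprintf("max Rhat = %s; converged: %s\n",
              format(x$diagnostics$max_rhat, digits = 4),
              format(x$diagnostics$converged)))
  invisible(x)
}

#' @export
summary.rw_hfit <- function(object, ...) {
  pm <- object$posterior_mean
  num <- vapply(pm[setdiff(names(pm), "participant_id")], mean, numeric(1))
  out <- list(model = object$model, group = object$group,
              n_participants = length(object$participants),
              group_means = num, hyper = object$hyper,
              diagnostics = object$diagnostics)
  class(out) <- "summary.rw_hfit"
  out
}

#' @export
print.summary.rw_hfit <- function(x, ...) {
  cat(sprintf("Hierarchical %s Rescorla-Wagner fit (%s, n = %d)\n",
              x$model, x$group %||% "unlabelled group", x$n_participants))
  cat("mean of individual posterior means:\n")
  print(signif(x$group_means, 4))
  cat("group-level hyperparameters (latent scale):\n")
  print(signif(x$hyper, 4))
  cat(sprintf("max Rhat = %s; min ESS = %s\n",
              format(x$diagnostics$max_rhat, digits = 4),
              format(if (length(x$diagnostics$ess)) floor(min(x$diagnostics$ess)) else NA)))
  invisible(x)
}

#' @export
coef.rw_hfit <- function(object, ...) object$posterior_mean
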