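# Pareto-smoothed importance sampling leave-one-out cross-validation
# (PSIS-LOO). Importance ratios for observation i are 1/p(y_i | theta^s);
# the largest ratios are replaced by quantiles of a generalized Pareto
# distribution fitted to the tail (Zhang-Stephens profile posterior-mean
# estimator with the usual weakly-informative shape regularisation).

# Generalized Pareto fit to exceedances x (> 0). Returns shape k and
# scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 - sqrt(m / (jj - 0.5))
  b <- b / (3 * xstar) + 1 / x[n]
  k_prof <- vapply(b, function(bj) mean(log1p(-bj * x)), numeric(1))
  l_prof <- n * (log(-b / k_prof) - k_prof - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_prof - l_prof[j])), numeric(1))
  b_post <- sum(b * w)
  k0 <- mean(log1p(-b_post * x))
  sigma <- -k0 / b_post
  k <- (n * k0 + 10 * 0.5) / (n + 10)   # regularise shape towards 0.5
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(k * (-log1p(-p))) / k
}

# smooth one vector of log importance ratios in place; returns the
# normalised log weights and the Pareto-k estimate
psis_smooth <- function(lw) {
  s <- length(lw)
  n_tail <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  khat <- NA_real_
  if (n_tail >= 5L && s - n_tail >= 1L) {
    ord <- order(lw)
    cutoff <- lw[ord[s - n_tail]]
    tail_ids <- ord[(s - n_tail + 1L):s]
    exc <- exp(lw[tail_ids]) - exp(cutoff)
    if (any(exc > 0) && stats::sd(lw[tail_ids]) > 0) {
      fit <- gpd_fit(exc[exc > 0])
      khat <- fit$k
      if (is.finite(khat)) {
        pr <- (seq_len(n_tail) - 0.5) / n_tail
        smoothed <- log(gpd_quantile(pr, fit$k, fit$sigma) + exp(cutoff))
        lw[tail_ids[order(lw[tail_ids])]] <- smoothed
      }
    }
  }
  lw <- pmin(lw, 0)             # truncate at the raw maximum (lw already centred)
  lw <- lw - logsumexp(lw)
  list(log_weights = lw, k = khat)
}

#' PSIS-LOO from pointwise log-likelihood draws
#'
#' Computes the expected log pointwise predictive density under exact
#' leave-one-out cross-validation, estimated by Pareto-smoothed importance
#' sampling, and the corresponding information criterion
#' `LOOIC = -2 * elpd_loo` (lower is better).
#'
#' @param log_lik Matrix of pointwise log-likelihood draws, rows =
#'   posterior draws (>= 2), columns = observations. All entries must be
#'   finite.
#' @return Object of class `psis_loo`: `elpd_loo`, `se`, `looic`,
#'   `pointwise` (per-observation elpd), `pareto_k` (per-observation
#'   generalized-Pareto shape; `NA` when the tail was too short or too
#'   concentrated to need smoothing) and `n_obs`, `n_draws`.
#' @export
compute_loo <- function(log_lik) {
  log_lik <- as.matrix(log_lik)
  if (nrow(log_lik) < 2L) stop_invalid("`log_lik` needs at least 2 draws")
  bad <- which(!apply(log_lik, 2L, function(x) all(is.finite(x))))
  if (length(bad)) {
    stop_invalid("non-finite log-likelihood draws for observation(s): ",
                 paste(utils::head(bad, 5L), collapse = ", "))
  }
  n <- ncol(log_lik)
  pointwise <- numeric(n)
  ks <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ll <- log_lik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    sm <- psis_smooth(lw)
    ks[i] <- sm$k
    pointwise[i] <- logsumexp(sm$log_weights + ll)
  }
  elpd <- sum(pointwise)
  se <- sqrt(n * stats::var(pointwise))
  structure(list(elpd_loo = elpd, se = se, looic = -2 * elpd,
                 looic_se = 2 * se, pointwise = pointwise, pareto_k = ks,
                 n_obs = n, n_draws = nrow(log_lik)),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd_loo = %.2f (SE %.2f), LOOIC = %.2f (%d obs, %d draws)\n",
              x$elpd_loo, x$se, x$looic, x$n_obs, x$n_draws))
  kk <- x$pareto_k[is.finite(x$pareto_k)]
  if (length(kk)) {
    cat(sprintf("Pareto k: max %.2f; %d of %d observations > 0.7\n",
                max(kk), sum(kk > 0.7), x$n_obs))
  }
  invisible(x)
}
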