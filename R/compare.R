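# LOOIC model comparison across fits of the same data.

#' Compare fitted models by LOOIC
#'
#' Ranks two or more fits of the *same* observations by LOOIC (lower is
#' better) and flags the best model. Fits with mismatched observation sets
#' (different participants or included trials) are refused. Exact ties are
#' broken by parsimony: fewer free parameters first, then declaration
#' order (`simple`, `posneg`, `counterfactual`).
#'
#' @param fits List of `rw_hfit` objects (or any objects carrying
#'   `$model`, `$log_lik` and `$obs`), all fitted to the same sessions.
#' @param group Optional group label for the comparison table.
#' @return Object of class `rw_model_comparison`: a data frame `table`
#'   with one row per model (`model`, `elpd_loo`, `se`, `looic`,
#'   `looic_se`, `max_pareto_k`, `best`), sorted by LOOIC ascending, plus
#'   the per-model `psis_loo` objects in `$loo`.
#' @export
compare_models <- function(fits, group = NULL) {
  if (!is.list(fits) || length(fits) < 2L) {
    stop_invalid("need at least 2 fitted models to compare")
  }
  models <- vapply(fits, function(f) f$model %||% NA_character_, character(1))
  if (anyNA(models)) stop_invalid("every fit must carry a `model` field")
  if (anyDuplicated(models)) stop_invalid("duplicate model fits supplied")
  obs0 <- fits[[1L]]$obs
  for (f in fits[-1L]) {
    if (!identical(dim(f$obs), dim(obs0)) ||
        !identical(f$obs$participant_id, obs0$participant_id) ||
        !identical(f$obs$trial_index, obs0$trial_index)) {
      stop_invalid("fits cover different observation sets; refusing to compare")
    }
  }
  loos <- lapply(fits, function(f) f$loo %||% compute_loo(f$log_lik))
  names(loos) <- models
  tab <- data.frame(
    model = models,
    elpd_loo = vapply(loos, `[[`, numeric(1), "elpd_loo"),
    se = vapply(loos, `[[`, numeric(1), "se"),
    looic = vapply(loos, `[[`, numeric(1), "looic"),
    looic_se = vapply(loos, `[[`, numeric(1), "looic_se"),
    max_pareto_k = vapply(loos, function(l) {
      kk <- l$pareto_k[is.finite(l$pareto_k)]
      if (length(kk)) max(kk) else NA_real_
    }, numeric(1)),
    row.names = NULL
  )
  npar <- vapply(tab$model, rw_n_params, integer(1))
  canon <- match(tab$model, RW_MODELS)
  ord <- order(tab$looic, npar, canon)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$best <- seq_len(nrow(tab)) == 1L
  structure(list(table = tab, group = group, loo = loos[tab$model],
                 n_obs = nrow(obs0)),
            class = "rw_model_comparison")
}

#' @export
print.rw_model_comparison <- function(x, ...) {
  cat("Model comparison by LOOIC",
      if (!is.null(x$group)) paste0(" (", x$group, ")"),
      " -- ", x$n_obs, " observations\n", sep = "")
  tab <- x$table
  tab$elpd_loo <- round(tab$elpd_loo, 2)
  tab$se <- round(tab$se, 2)
  tab$looic <- round(tab$looic, 2)
  tab$looic_se <- round(tab$looic_se, 2)
  tab$max_pareto_k <- round(tab$max_pareto_k, 2)
  print(tab, row.names = FALSE)
  cat("best model: ", tab$model[tab$best], " (lowest LOOIC)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.rw_model_comparison <- function(x, ...) x$table
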