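#' Likelihood-ratio test for an individual random slope
#'
#' Compares a model with a female random slope (plus intercept-slope
#' covariance) against the nested random-intercept model with the identical
#' fixed structure: `chi2 = -2 * (logLik_reduced - logLik_full)` referred to
#' a chi-squared distribution with 2 degrees of freedom (slope variance +
#' covariance). The plain chi-squared reference is conservative at the
#' variance boundary. Negative statistics (numerical noise) are clamped to
#' zero with a warning.
#'
#' @param fit_full `pheno_lmm` with the random slope.
#' @param fit_reduced `pheno_lmm` without it, same fixed terms and method.
#' @return One-row tibble: `chi2`, `df`, `p`.
#' @export
lrt_random_slope <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "pheno_lmm"), inherits(fit_reduced, "pheno_lmm"))
  if (!fit_full$spec$random_slope || fit_reduced$spec$random_slope) {
    stop("fit_full must contain the random slope and fit_reduced must not",
         call. = FALSE)
  }
  if (!identical(fit_full$spec$terms, fit_reduced$spec$terms)) {
    stop("fits must share the same fixed-effect terms", call. = FALSE)
  }
  if (fit_full$method != fit_reduced$method) {
    stop("fits must use the same estimation method", call. = FALSE)
  }
  chi2 <- -2 * (fit_reduced$loglik - fit_full$loglik)
  if (chi2 < 0) {
    warning("negative LRT statistic clamped to 0", call. = FALSE)
    chi2 <- 0
  }
  tibble::tibble(chi2 = chi2, df = 2L, p = pchisq(chi2, 2, lower.tail = FALSE))
}

#' Rank fixed-effect structures by AIC
#'
#' Fits every candidate specification by maximum likelihood with the common
#' random structure (year intercept + female intercept and moult slope,
#' unless a spec says otherwise), computes `AIC = deviance + 2 n.p.` and
#' sorts by AIC. Ties are broken by fewer parameters, then input order.
#' Non-converged fits are kept but flagged.
#'
#' @param records `pheno_data` tibble.
#' @param env Environment table (needed for environmental terms).
#' @param specs List of [model_spec()] objects; defaults to the twelve
#'   candidate structures of [marion_models()].
#' @return Tibble of class `pheno_aic_table`: `label`, `n_params`, `AIC`,
#'   `delta_aic`, `deviance`, `converged`, `singular`, best model first. The
#'   fitted models are attached as attribute `"fits"`.
#' @export
rank_models <- function(records, env = NULL, specs = marion_models()) {
  if (length(specs) == 0) stop("`specs` must contain at least one model",
                               call. = FALSE)
  fits <- purrr::map(specs, function(sp) fit_lmm(records, sp, env, "ML"))
  tab <- purrr::imap(fits, function(f, nm) {
    tibble::tibble(label = if (nzchar(nm)) nm else f$spec$label,
                   n_params = f$n_params,
                   AIC = aic(f),
                   deviance = f$deviance,
                   converged = f$converged,
                   singular = f$singular)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(.input = dplyr::row_number()) |>
    dplyr::arrange(.data$AIC, .data$n_params, .data$.input) |>
    dplyr::mutate(delta_aic = .data$AIC - .data$AIC[1]) |>
    dplyr::select("label", "n_params", "AIC", "delta_aic", "deviance",
                  "converged", "singular")
  structure(tab, fits = fits,
            class = c("pheno_aic_table", class(tab)))
}

#' Recompute a delta-AIC column from parameter counts and deviances
#'
#' Pure bookkeeping on an existing table: `AIC = deviance + 2 * n_params`,
#' differenced against the smallest value. Used to check reported
#' model-selection tables without refitting anything.
#'
#' @param table Tibble with columns `n_params` and `deviance`.
#' @return The table with recomputed `AIC` and `delta_aic` columns appended.
#' @export
recompute_delta_aic <- function(table) {
  stopifnot(all(c("n_params", "deviance") %in% names(table)))
  table |>
    dplyr::mutate(AIC = .data$deviance + 2 * .data$n_params,
                  delta_aic = .data$AIC - min(.data$AIC))
}
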