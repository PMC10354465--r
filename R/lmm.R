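#' Fit the crossed-random-effects arrival-date model
#'
#' Gaussian linear mixed model for arrival date with a year random intercept
#' and a female random intercept plus (optionally) a correlated random slope
#' on the standardized moult-departure date - the trait-trait reaction norm.
#' Estimation is by REML or ML through `lme4::lmer()`. Boundary solutions
#' (a variance at zero or |correlation| = 1) are flagged as singular rather
#' than treated as errors.
#'
#' @param records `pheno_data` tibble (see [simulate_population()] /
#'   [load_phenology()]).
#' @param spec A [model_spec()]; defaults to the top-ranked structure
#'   `age*state + moult + wean`.
#' @param env Environment table, required for environmental terms.
#' @param method `"REML"` (parameter estimation) or `"ML"` (model
#'   comparison / AIC).
#' @return A `pheno_lmm` object: the underlying `merMod` plus the variance
#'   components (`sigma_i2`, `sigma_m2`, `cov_im`, `sigma_j2`, `sigma_e2`),
#'   fixed effects with standard errors, log-likelihood, deviance
#'   (`-2 logLik`, ML fits), parameter count, convergence/singularity flags
#'   and BLUPs.
#' @export
fit_lmm <- function(records,
                    spec = model_spec(c("age*state", "moult", "wean")),
                    env = NULL,
                    method = c("REML", "ML"),
                    control = NULL) {
  method <- match.arg(method)
  des <- build_design(records, env, spec)
  d <- des$frame
  if (!all(is.finite(d$arrival))) stop("non-finite arrival dates", call. = FALSE)
  if (dplyr::n_distinct(d$female_id) < 2) {
    stop("need records from at least 2 females", call. = FALSE)
  }
  if (spec$year_effect && dplyr::n_distinct(d$year) < 2) {
    stop("need records from at least 2 years", call. = FALSE)
  }
  ctrl <- control %||% lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = "ignore",
    check.nobs.vs.nRE = "warning",
    check.nobs.vs.nlev = "warning"
  )
  msgs <- character()
  model <- withCallingHandlers(
    lme4::lmer(des$formula, data = d, REML = (method == "REML"),
               control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  p_fixed <- length(lme4::fixef(model))
  if (nrow(d) < p_fixed) stop("fewer observations than fixed-effect columns",
                              call. = FALSE)
  vc <- lme4::VarCorr(model)
  fem <- vc$female_id
  sigma_m2 <- if (spec$random_slope) unname(fem["moult_z", "moult_z"]) else 0
  cov_im <- if (spec$random_slope) unname(fem["(Intercept)", "moult_z"]) else 0
  sigma_j2 <- if (spec$year_effect) unname(vc$year[1, 1]) else 0
  n_random <- spec$n_params - spec$n_fixed
  ll <- as.numeric(logLik(model))
  opt_ok <- isTRUE(model@optinfo$conv$opt == 0)
  structure(
    list(
      model = model,
      spec = spec,
      method = method,
      sigma_i2 = unname(fem["(Intercept)", "(Intercept)"]),
      sigma_m2 = sigma_m2,
      cov_im = cov_im,
      sigma_j2 = sigma_j2,
      sigma_e2 = sigma(model)^2,
      loglik = ll,
      deviance = if (method == "ML") -2 * ll else NA_real_,
      n_fixed = p_fixed,
      n_params = p_fixed + n_random,
      converged = opt_ok && !any(grepl("failed to converge", msgs)),
      singular = lme4::isSingular(model, tol = 1e-6),
      messages = msgs,
      n_obs = nrow(d),
      n_females = dplyr::n_distinct(d$female_id),
      n_years = dplyr::n_distinct(d$year)
    ),
    class = "pheno_lmm"
  )
}

#' @export
#' @method print pheno_lmm
print.pheno_lmm <- function(x, ...) {
  cat("<pheno_lmm> ", x$spec$label, " [", x$method, "]\n", sep = "")
  cat(sprintf("  %d obs, %d females, %d years; n.p. = %d\n",
              x$n_obs, x$n_females, x$n_years, x$n_params))
  cat(sprintf(
    "  sigma_i2 = %.2f  sigma_m2 = %.2f  cov = %.3f  sigma_j2 = %.2f  sigma_e2 = %.2f\n",
    x$sigma_i2, x$sigma_m2, x$cov_im, x$sigma_j2, x$sigma_e2))
  cat(sprintf("  logLik (%s) = %.2f%s%s\n", x$method, x$loglik,
              if (x$singular) "  [singular]" else "",
              if (!x$converged) "  [NOT converged]" else ""))
  invisible(x)
}

#' Akaike information criterion of an ML fit
#'
#' `AIC = deviance + 2 * n.p.`, where n.p. counts fixed-effect columns plus
#' random-effect parameters (5 with the female moult slope: two variances, a
#' covariance, the year variance and the residual variance; 3 without).
#' Comparing fixed-effect structures requires ML fits, so REML fits are
#' rejected.
#'
#' @param fit A `pheno_lmm` fitted with `method = "ML"`.
#' @return AIC (scalar).
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "pheno_lmm"))
  if (fit$method != "ML") {
    stop("AIC comparison of fixed-effect structures requires an ML fit",
         call. = FALSE)
  }
  fit$deviance + 2 * fit$n_params
}

#' Individual reaction norms of arrival on moult date
#'
#' Returns the population regression line of arrival date on the
#' standardized moult-departure date, together with each female's
#' BLUP-shifted line (intercept + random intercept, slope + random slope)
#' and the SDs of the BLUP intercepts and slopes. Intercepts are evaluated
#' at the average fixed-effect profile of the data with moult at its mean.
#'
#' @param fit A `pheno_lmm` whose spec includes the moult random slope.
#' @return List with `population` (one-row tibble: `intercept`, `slope`),
#'   `females` (per-female tibble: `female_id`, `intercept`, `slope`,
#'   `blup_intercept`, `blup_slope`) and `blup_sd` (tibble with the two SDs).
#' @export
predict_reaction_norms <- function(fit) {
  stopifnot(inherits(fit, "pheno_lmm"))
  if (!fit$spec$random_slope) {
    stop("fit has no female moult-date random slope", call. = FALSE)
  }
  model <- fit$model
  mf <- model@frame
  mf0 <- mf
  mf0$moult_z <- 0
  b0 <- mean(predict(model, newdata = mf0, re.form = NA))
  slope <- unname(lme4::fixef(model)["moult_z"])
  re <- lme4::ranef(model)$female_id
  females <- tibble::tibble(
    female_id = rownames(re),
    blup_intercept = re[["(Intercept)"]],
    blup_slope = re[["moult_z"]],
    intercept = b0 + re[["(Intercept)"]],
    slope = slope + re[["moult_z"]]
  )
  list(
    population = tibble::tibble(intercept = b0, slope = slope),
    females = females,
    blup_sd = tibble::tibble(sd_intercept = sd(females$blup_intercept),
                             sd_slope = sd(females$blup_slope))
  )
}

#' @export
tidy.pheno_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects, c("fixed", "ran_pars"), several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    b <- lme4::fixef(x$model)
    se <- sqrt(diag(as.matrix(vcov(x$model))))
    out$fixed <- tibble::tibble(
      effect = "fixed", term = names(b),
      estimate = unname(b), std.error = unname(se),
      conf.low = unname(b) - qnorm(0.975) * unname(se),
      conf.high = unname(b) + qnorm(0.975) * unname(se)
    )
  }
  if ("ran_pars" %in% effects) {
    terms <- c("var_female_intercept", "var_female_slope",
               "cov_female_intercept_slope", "var_year", "var_residual")
    est <- c(x$sigma_i2, x$sigma_m2, x$cov_im, x$sigma_j2, x$sigma_e2)
    keep <- if (x$spec$random_slope) 1:5 else c(1, 4, 5)
    out$ran <- tibble::tibble(
      effect = "ran_pars", term = terms[keep], estimate = est[keep],
      std.error = NA_real_, conf.low = NA_real_, conf.high = NA_real_
    )
  }
  dplyr::bind_rows(out)
}

#' @export
glance.pheno_lmm <- function(x, ...) {
  tibble::tibble(
    nobs = x$n_obs, n_females = x$n_females, n_years = x$n_years,
    n_params = x$n_params, logLik = x$loglik,
    deviance = x$deviance,
    AIC = if (x$method == "ML") x$deviance + 2 * x$n_params else NA_real_,
    method = x$method, converged = x$converged, singular = x$singular
  )
}
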