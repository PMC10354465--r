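#' Age-by-state cell mean arrival dates from a fitted model
#'
#' Extracts the estimated mean arrival date of every age-by-state cell at
#' reference covariate values (standardized covariates at zero), with Wald
#' 95% confidence intervals. Requires a fit whose fixed structure uses the
#' cell-means coding (`age*state`). Cells absent from the data are reported
#' as rows with `NA` estimates, never imputed.
#'
#' @param fit `pheno_lmm` of a spec containing `age*state` (typically the
#'   REML refit of the top-ranked model).
#' @return Tibble: `cell`, `age`, `state`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `observed`.
#' @export
age_state_means <- function(fit) {
  stopifnot(inherits(fit, "pheno_lmm"))
  if (!"age*state" %in% fit$spec$terms) {
    stop("fit must use the age*state cell structure", call. = FALSE)
  }
  b <- lme4::fixef(fit$model)
  se <- sqrt(diag(as.matrix(vcov(fit$model))))
  cell_terms <- grep("^cell", names(b), value = TRUE)
  est <- setNames(unname(b[cell_terms]), sub("^cell", "", cell_terms))
  ses <- setNames(unname(se[cell_terms]), sub("^cell", "", cell_terms))
  lv <- age_state_cell_levels()
  age <- as.integer(sub("[FE]$", "", lv))
  state <- dplyr::case_when(grepl("F$", lv) ~ "first",
                            grepl("E$", lv) ~ "experienced",
                            lv == "3" ~ "first",
                            TRUE ~ "experienced")
  tibble::tibble(
    cell = lv, age = age, state = state,
    estimate = unname(est[lv]),
    std.error = unname(ses[lv]),
    conf.low = .data$estimate - qnorm(0.975) * .data$std.error,
    conf.high = .data$estimate + qnorm(0.975) * .data$std.error,
    observed = lv %in% names(est)
  )
}

#' Linear age trend in arrival date among older females
#'
#' Weighted least-squares regression of the experienced-breeder cell mean
#' arrival dates on age, from `start_age` to the capped age 21; weights are
#' the inverse squared standard errors of the cell means.
#'
#' @param cell_means Output of [age_state_means()], or a `pheno_lmm` from
#'   which it is computed.
#' @param start_age First age included (default 8).
#' @return One-row tibble: `slope` (days per year of age), `std.error`,
#'   `conf.low`, `conf.high`, `start_age`, `end_age`, `n_cells`.
#' @export
old_age_trend <- function(cell_means, start_age = 8) {
  if (inherits(cell_means, "pheno_lmm")) {
    cell_means <- age_state_means(cell_means)
  }
  d <- cell_means |>
    dplyr::filter(.data$state == "experienced", .data$age >= start_age,
                  !is.na(.data$estimate))
  if (nrow(d) < 3) stop("fewer than 3 usable cells", call. = FALSE)
  w <- if (all(is.finite(d$std.error)) && all(d$std.error > 0)) {
    1 / d$std.error^2
  } else {
    rep(1, nrow(d))
  }
  m <- lm(estimate ~ age, data = d, weights = w)
  s <- summary(m)$coefficients
  ci <- stats::confint(m)["age", ]
  tibble::tibble(
    slope = unname(s["age", "Estimate"]),
    std.error = unname(s["age", "Std. Error"]),
    conf.low = unname(ci[1]), conf.high = unname(ci[2]),
    start_age = start_age, end_age = max(d$age), n_cells = nrow(d)
  )
}
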