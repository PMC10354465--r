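#' Partition random-effect variance components into percentages
#'
#' Divides each of the four random-structure components (individual
#' intercept, individual slope, year, residual) by their sum.
#'
#' @param components Numeric vector of the four non-negative components
#'   `sigma_i2`, `sigma_m2`, `sigma_j2`, `sigma_e2` (in that order if
#'   unnamed), or a `pheno_lmm` fit.
#' @return Tibble with `component`, `variance`, `percent`; percentages sum
#'   to 100.
#' @export
variance_partition <- function(components) {
  if (inherits(components, "pheno_lmm")) {
    components <- c(sigma_i2 = components$sigma_i2,
                    sigma_m2 = components$sigma_m2,
                    sigma_j2 = components$sigma_j2,
                    sigma_e2 = components$sigma_e2)
  }
  if (is.null(names(components))) {
    names(components) <- c("sigma_i2", "sigma_m2", "sigma_j2", "sigma_e2")
  }
  if (length(components) != 4 || any(components < 0)) {
    stop("need four non-negative variance components", call. = FALSE)
  }
  tot <- sum(components)
  if (tot == 0) stop("all variance components are zero", call. = FALSE)
  tibble::tibble(
    component = c("individual", "slope", "year", "residual"),
    variance = unname(components[c("sigma_i2", "sigma_m2",
                                   "sigma_j2", "sigma_e2")]),
    percent = 100 * .data$variance / tot
  )
}

# population variance (divide by n) of the fixed-effect linear predictor
fixed_effect_variance <- function(fit) {
  xb <- predict(fit$model, re.form = NA)
  mean((xb - mean(xb))^2)
}

#' Repeatability of arrival date for a grouping factor
#'
#' The ratio of the grouping factor's variance (female or year) to the total
#' phenotypic variance. With `include_fixed = TRUE` (the default) the
#' variance explained by the fixed effects - the population variance of the
#' fitted linear predictor - is added back into the denominator ("enhanced
#' agreement" repeatability). The female slope variance is excluded from the
#' denominator by default; set `include_slope = TRUE` to add it.
#'
#' @param fit Converged `pheno_lmm` (typically the REML refit of the
#'   top-ranked model).
#' @param group `"female"` or `"year"`.
#' @param include_fixed Add the fixed-effect variance to the denominator.
#' @param include_slope Add the female slope variance to the denominator.
#' @return One-row tibble: `group`, `R`, `sigma_group2`, `sigma_f2`,
#'   `denominator`, `include_fixed`, `include_slope`, `singular`.
#' @export
repeatability <- function(fit, group = c("female", "year"),
                          include_fixed = TRUE, include_slope = FALSE) {
  stopifnot(inherits(fit, "pheno_lmm"))
  group <- match.arg(group)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  sigma_f2 <- if (include_fixed) fixed_effect_variance(fit) else 0
  out <- repeatability_from_components(
    sigma_i2 = fit$sigma_i2, sigma_j2 = fit$sigma_j2,
    sigma_e2 = fit$sigma_e2, sigma_f2 = sigma_f2,
    sigma_m2 = fit$sigma_m2, group = group, include_slope = include_slope
  )
  dplyr::mutate(out, include_fixed = include_fixed, singular = fit$singular)
}

#' Repeatability from explicit variance components
#'
#' The arithmetic core of [repeatability()]:
#' `R = sigma_group^2 / (sigma_i2 + sigma_j2 + sigma_e2 + sigma_f2
#' [+ sigma_m2])`.
#'
#' @param sigma_i2,sigma_j2,sigma_e2 Individual, year and residual
#'   variances.
#' @param sigma_f2 Fixed-effect variance added back into the denominator.
#' @param sigma_m2 Individual slope variance (only used when
#'   `include_slope`).
#' @param group `"female"` or `"year"`.
#' @param include_slope Add `sigma_m2` to the denominator.
#' @return One-row tibble: `group`, `R`, `sigma_group2`, `sigma_f2`,
#'   `denominator`, `include_slope`.
#' @export
repeatability_from_components <- function(sigma_i2, sigma_j2, sigma_e2,
                                          sigma_f2 = 0, sigma_m2 = 0,
                                          group = c("female", "year"),
                                          include_slope = FALSE) {
  group <- match.arg(group)
  num <- if (group == "female") sigma_i2 else sigma_j2
  denom <- sigma_i2 + sigma_j2 + sigma_e2 + sigma_f2 +
    if (include_slope) sigma_m2 else 0
  if (denom == 0) stop("total phenotypic variance is zero", call. = FALSE)
  tibble::tibble(
    group = group, R = num / denom,
    sigma_group2 = num, sigma_f2 = sigma_f2, denominator = denom,
    include_slope = include_slope
  )
}

#' Parametric-bootstrap confidence interval for repeatability
#'
#' Simulates `n_boot` response vectors from the fitted model (fixed part
#' plus random draws at the estimated components), refits the model to each,
#' recomputes repeatability and returns percentile 2.5/97.5 bounds.
#'
#' @inheritParams repeatability
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed (reproducible given the same seed).
#' @param max_fail_frac Error if more than this fraction of refits fail.
#' @return One-row tibble: the [repeatability()] columns plus `ci_low`,
#'   `ci_high`, `n_boot`, `n_fail`. The bootstrap replicates are attached
#'   as attribute `"boot"`.
#' @export
bootstrap_ci <- function(fit, group = c("female", "year"), n_boot = 1000,
                         seed = 1L, include_fixed = TRUE,
                         include_slope = FALSE, max_fail_frac = 0.1) {
  stopifnot(inherits(fit, "pheno_lmm"))
  group <- match.arg(group)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  point <- repeatability(fit, group, include_fixed, include_slope)
  withr::local_seed(child_seed(seed, "bootstrap"))
  ysim <- stats::simulate(fit$model, nsim = n_boot)
  idx_group <- if (group == "female") "sigma_i2" else "sigma_j2"
  reps <- vapply(seq_len(n_boot), function(b) {
    refitted <- tryCatch(
      suppressMessages(suppressWarnings(lme4::refit(fit$model, ysim[[b]]))),
      error = function(e) NULL
    )
    if (is.null(refitted)) return(NA_real_)
    vc <- lme4::VarCorr(refitted)
    s_i2 <- unname(vc$female_id["(Intercept)", "(Intercept)"])
    s_m2 <- if (fit$spec$random_slope) {
      unname(vc$female_id["moult_z", "moult_z"])
    } else 0
    s_j2 <- unname(vc$year[1, 1])
    s_e2 <- sigma(refitted)^2
    s_f2 <- if (include_fixed) {
      xb <- predict(refitted, re.form = NA)
      mean((xb - mean(xb))^2)
    } else 0
    num <- if (group == "female") s_i2 else s_j2
    num / (s_i2 + s_j2 + s_e2 + s_f2 + if (include_slope) s_m2 else 0)
  }, numeric(1))
  n_fail <- sum(is.na(reps))
  if (n_fail > max_fail_frac * n_boot) {
    stop(sprintf("%d of %d bootstrap refits failed", n_fail, n_boot),
         call. = FALSE)
  }
  ci <- unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE, type = 1))
  out <- dplyr::mutate(point, ci_low = ci[1], ci_high = ci[2],
                       n_boot = as.integer(n_boot),
                       n_fail = as.integer(n_fail))
  if (out$R < out$ci_low || out$R > out$ci_high) {
    warning("percentile CI does not contain the point estimate",
            call. = FALSE)
  }
  structure(out, boot = reps)
}

#' Regression of later arrivals on the first-breeding arrival
#'
#' A direct visualization of within-individual repeatability: each
#' experienced-breeder arrival is regressed (OLS) on the same female's
#' arrival date as a first-time breeder. Within-female noise attenuates the
#' slope below 1.
#'
#' @param records `pheno_data` tibble; females need a first and at least one
#'   later record.
#' @return One-row tibble: `slope`, `std.error`, `conf.low`, `conf.high`,
#'   `intercept`, `n_females`, `n_pairs`.
#' @export
first_vs_later_regression <- function(records) {
  d <- tibble::as_tibble(records)
  first_map <- d |>
    dplyr::filter(.data$state == "first") |>
    dplyr::select("female_id", first = "arrival")
  pairs <- d |>
    dplyr::filter(.data$state == "experienced") |>
    dplyr::select("female_id", later = "arrival") |>
    dplyr::inner_join(first_map, by = "female_id")
  if (dplyr::n_distinct(pairs$female_id) < 2) {
    stop("need >= 2 females with both a first and a later record",
         call. = FALSE)
  }
  m <- lm(later ~ first, data = pairs)
  s <- summary(m)$coefficients
  ci <- stats::confint(m)["first", ]
  tibble::tibble(
    slope = unname(s["first", "Estimate"]),
    std.error = unname(s["first", "Std. Error"]),
    conf.low = unname(ci[1]), conf.high = unname(ci[2]),
    intercept = unname(s["(Intercept)", "Estimate"]),
    n_females = dplyr::n_distinct(pairs$female_id),
    n_pairs = nrow(pairs)
  )
}
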