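#' Build mother-daughter dyads of first-breeding arrival dates
#'
#' Pairs each mother's arrival date at her first recorded reproduction with
#' the first-breeding arrival dates of her recruited daughters. When a
#' mother has several recruited daughters their mean first arrival is used,
#' so each mother contributes exactly one dyad.
#'
#' @param records `pheno_data` tibble with `mother_id` links; a female's
#'   "first reproduction" is her earliest record in the dataset.
#' @return Tibble: `mother_id`, `mother_arrival`,
#'   `daughter_arrival` (daughters' mean), `n_daughters`. May be empty.
#' @export
build_dyads <- function(records) {
  d <- tibble::as_tibble(records)
  firsts <- d |>
    dplyr::arrange(.data$female_id, .data$year) |>
    dplyr::slice_head(n = 1, by = "female_id") |>
    dplyr::select("female_id", "arrival", "mother_id")
  daughters <- dplyr::filter(firsts, !is.na(.data$mother_id) &
                               .data$mother_id %in% firsts$female_id)
  if (nrow(daughters) == 0) {
    return(tibble::tibble(mother_id = character(), mother_arrival = numeric(),
                          daughter_arrival = numeric(),
                          n_daughters = integer()))
  }
  mothers <- dplyr::select(firsts, mother_id = "female_id",
                           mother_arrival = "arrival")
  daughters |>
    dplyr::summarise(daughter_arrival = mean(.data$arrival),
                     n_daughters = dplyr::n(), .by = "mother_id") |>
    dplyr::inner_join(mothers, by = "mother_id") |>
    dplyr::select("mother_id", "mother_arrival", "daughter_arrival",
                  "n_daughters")
}

#' Narrow-sense heritability from parent-offspring regression
#'
#' OLS regression of the daughters' (mean) first-breeding arrival date on
#' the mother's first-breeding arrival date. With only one parent measured,
#' narrow-sense heritability is twice the regression slope. Estimates
#' outside \[0, 1\] are reported with a warning, never clipped.
#'
#' @param dyads Dyad table from [build_dyads()] (>= 3 rows).
#' @return One-row tibble: `slope`, `std.error`, `p_value`, `h2`
#'   (`= 2 * slope`), `r_squared`, `n_dyads`.
#' @export
parent_offspring_h2 <- function(dyads) {
  if (nrow(dyads) < 3) stop("need at least 3 dyads", call. = FALSE)
  if (sd(dyads$mother_arrival) == 0) {
    stop("all mother arrival dates identical; slope undefined", call. = FALSE)
  }
  m <- lm(daughter_arrival ~ mother_arrival, data = dyads)
  s <- summary(m)
  co <- s$coefficients["mother_arrival", ]
  h2 <- 2 * unname(co["Estimate"])
  if (h2 < 0 || h2 > 1) {
    warning(sprintf("h2 estimate %.2f outside [0, 1]; reported unclipped", h2),
            call. = FALSE)
  }
  tibble::tibble(
    slope = unname(co["Estimate"]),
    std.error = unname(co["Std. Error"]),
    p_value = unname(co["Pr(>|t|)"]),
    h2 = h2,
    r_squared = s$r.squared,
    n_dyads = nrow(dyads)
  )
}

#' Randomized-dyad permutation test for heritability
#'
#' Builds a null distribution for the parent-offspring slope by pairing the
#' observed mothers with daughters drawn at random: daughter first-arrival
#' values are permuted across the daughter slots while the mother vector and
#' the daughters-per-mother counts stay fixed, then re-averaged per mother.
#' The one-tailed p-value counts how many permuted datasets give a
#' heritability estimate larger than the observed one.
#'
#' @param records `pheno_data` tibble with mother links.
#' @param n_perm Number of permutations (default 10000; a warning is issued
#'   below 100).
#' @param seed Integer seed.
#' @param plus_one Use the `(count + 1) / (n_perm + 1)` p-value variant
#'   instead of the plain `count / n_perm`.
#' @return One-row tibble: `observed_slope`, `observed_h2`, `n_perm`,
#'   `p_one_tailed`, `null_mean_slope`, `null_ci_low`, `null_ci_high`
#'   (2.5/97.5 percentiles of the null slopes). The null slopes are attached
#'   as attribute `"null_slopes"`.
#' @export
permutation_test <- function(records, n_perm = 10000, seed = 1L,
                             plus_one = FALSE) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null", call. = FALSE)
  dyads <- build_dyads(records)
  if (nrow(dyads) == 0) stop("no observed dyads", call. = FALSE)
  obs <- parent_offspring_h2(dyads)

  # individual daughter values with their mother index, in dyad order
  d <- tibble::as_tibble(records)
  firsts <- d |>
    dplyr::arrange(.data$female_id, .data$year) |>
    dplyr::slice_head(n = 1, by = "female_id")
  dvals <- firsts |>
    dplyr::filter(!is.na(.data$mother_id) &
                    .data$mother_id %in% dyads$mother_id)
  g <- match(dvals$mother_id, dyads$mother_id)
  y <- dvals$arrival
  x <- dyads$mother_arrival
  counts <- as.integer(table(factor(g, levels = seq_len(nrow(dyads)))))
  xc <- x - mean(x)
  ssx <- sum(xc^2)

  withr::local_seed(child_seed(seed, "permutation"))
  null_slopes <- vapply(seq_len(n_perm), function(b) {
    perm <- y[sample.int(length(y))]
    dbar <- rowsum(perm, g)[, 1] / counts
    sum(xc * (dbar - mean(dbar))) / ssx
  }, numeric(1))
  null_h2 <- 2 * null_slopes
  count <- sum(null_h2 > obs$h2)
  p <- if (plus_one) (count + 1) / (n_perm + 1) else count / n_perm
  ci <- unname(quantile(null_slopes, c(0.025, 0.975)))
  structure(
    tibble::tibble(
      observed_slope = obs$slope, observed_h2 = obs$h2,
      n_perm = as.integer(n_perm), p_one_tailed = p,
      null_mean_slope = mean(null_slopes),
      null_ci_low = ci[1], null_ci_high = ci[2]
    ),
    null_slopes = null_slopes
  )
}
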