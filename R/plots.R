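#' Plot individual reaction norms of arrival on moult date
#'
#' Thin lines are the per-female BLUP-shifted linear reaction norms; the
#' thick line is the population-level regression of arrival date on the
#' standardized moult-departure date.
#'
#' @param fit `pheno_lmm` with the female moult random slope.
#' @param range_z Range of standardized moult dates to draw over.
#' @return A ggplot object.
#' @export
plot_reaction_norms <- function(fit, range_z = c(-2.5, 2.5)) {
  rn <- predict_reaction_norms(fit)
  ggplot2::ggplot() +
    ggplot2::geom_abline(
      data = rn$females,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope),
      colour = "mediumpurple", alpha = 0.25, linewidth = 0.2
    ) +
    ggplot2::geom_abline(
      data = rn$population,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope),
      colour = "black", linewidth = 1.2
    ) +
    ggplot2::xlim(range_z) +
    ggplot2::ylim(rn$population$intercept + range_z * rn$population$slope +
                    c(-25, 25)) +
    ggplot2::labs(x = "moult departure date (SD units)",
                  y = "breeding arrival date (days from 1 Sep)",
                  title = "Individual reaction norms") +
    ggplot2::theme_minimal()
}

#' Plot the age/state arrival curve
#'
#' Cell-mean arrival dates with 95% CIs by age, separated by breeding state,
#' with the fitted old-age linear trend overlaid.
#'
#' @param cell_means Output of [age_state_means()].
#' @param trend Optional output of [old_age_trend()].
#' @return A ggplot object.
#' @export
plot_age_curve <- function(cell_means, trend = NULL) {
  d <- dplyr::filter(cell_means, !is.na(.data$estimate))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$estimate,
                                       colour = .data$state)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "age (years, capped at 21)",
                  y = "mean arrival date (days from 1 Sep)",
                  colour = "breeding state",
                  title = "Age- and experience-dependent arrival") +
    ggplot2::theme_minimal()
  if (!is.null(trend)) {
    sub <- dplyr::filter(d, .data$state == "experienced",
                         .data$age >= trend$start_age)
    fit0 <- mean(sub$estimate) - trend$slope * mean(sub$age)
    p <- p + ggplot2::geom_abline(intercept = fit0, slope = trend$slope,
                                  linetype = 2, colour = "grey30")
  }
  p
}

#' Plot mother-daughter dyads with the heritability regression
#'
#' @param dyads Dyad table from [build_dyads()].
#' @param h2 Optional result of [parent_offspring_h2()] used to annotate the
#'   regression line.
#' @return A ggplot object.
#' @export
plot_dyads <- function(dyads, h2 = NULL) {
  p <- ggplot2::ggplot(dyads,
                       ggplot2::aes(x = .data$mother_arrival,
                                    y = .data$daughter_arrival)) +
    ggplot2::geom_point(colour = "firebrick", alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black") +
    ggplot2::labs(x = "mother first-breeding arrival (days from 1 Sep)",
                  y = "daughters' mean first-breeding arrival",
                  title = "Mother-daughter arrival dates") +
    ggplot2::theme_minimal()
  if (!is.null(h2)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("slope = %.2f, h2 = %.2f (n = %d dyads)",
                         h2$slope, h2$h2, h2$n_dyads))
  }
  p
}

#' Histogram of the permutation null with the observed heritability
#'
#' @param perm Output of [permutation_test()].
#' @return A ggplot object.
#' @export
plot_permutation <- function(perm) {
  null_slopes <- attr(perm, "null_slopes")
  ggplot2::ggplot(tibble::tibble(slope = null_slopes),
                  ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = perm$observed_slope,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "null mother-daughter regression slope",
                  y = "permutations",
                  title = "Randomized-dyad null distribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pheno_lmm <- function(object, ...) plot_reaction_norms(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
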