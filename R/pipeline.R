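#' Run the full phenology analysis pipeline
#'
#' Orchestrates the analysis end to end on simulated (or supplied) data:
#' simulate population + environment, test the female random slope by
#' likelihood ratio, rank the candidate fixed-effect structures by ML/AIC,
#' refit the best model by REML, partition variance and compute
#' repeatability with bootstrap CIs, estimate mother-daughter heritability
#' with the permutation test, and summarise the age/state arrival curve.
#' Every table is written as CSV into `out_dir` together with a plain-text
#' summary report; the run is deterministic given the config seed.
#'
#' @param config [sim_config()] describing the synthetic population (also
#'   supplies the master seed).
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param records Optional pre-built `pheno_data` tibble; when supplied the
#'   simulation stage is skipped and `config` only provides seeds.
#' @param env Optional environment table (simulated when absent).
#' @param specs Candidate models for the AIC ranking.
#' @param n_boot Bootstrap replicates for repeatability CIs.
#' @param n_perm Permutations for the heritability test.
#' @return Invisibly, a named list with every stage result: `records`,
#'   `env`, `lrt`, `aic_table`, `fit`, `variance_partition`,
#'   `repeatability`, `first_vs_later`, `dyads`, `heritability`,
#'   `permutation`, `cell_means`, `old_age_trend`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         records = NULL, env = NULL,
                         specs = marion_models(),
                         n_boot = 1000, n_perm = 10000) {
  if (length(specs) == 0) stop("`specs` must not be empty", call. = FALSE)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(env)) env <- simulate_environment(config$years, config$seed)
  if (is.null(records)) {
    records <- stage("simulate", simulate_population(config))
  }
  records <- stage("validate", validate_phenology(records))

  top_spec <- specs[[1]]
  lrt <- stage("lrt_random_slope", {
    full <- fit_lmm(records, top_spec, env, "ML")
    red_spec <- model_spec(top_spec$terms, random_slope = FALSE)
    reduced <- fit_lmm(records, red_spec, env, "ML")
    lrt_random_slope(full, reduced)
  })
  aic_table <- stage("rank_models", rank_models(records, env, specs))
  best_label <- aic_table$label[1]
  best_spec <- specs[[match(best_label, names(specs))]]
  fit <- stage("reml_refit", fit_lmm(records, best_spec, env, "REML"))

  vp <- stage("variance_partition", variance_partition(fit))
  rep_f <- stage("repeatability_female",
                 bootstrap_ci(fit, "female", n_boot, seed = config$seed))
  rep_y <- stage("repeatability_year",
                 bootstrap_ci(fit, "year", n_boot, seed = config$seed))
  fvl <- stage("first_vs_later", first_vs_later_regression(records))
  dyads <- stage("build_dyads", build_dyads(records))
  herit <- if (nrow(dyads) >= 3) {
    stage("heritability", parent_offspring_h2(dyads))
  } else {
    NULL
  }
  perm <- if (nrow(dyads) >= 3) {
    stage("permutation", permutation_test(records, n_perm, config$seed))
  } else {
    NULL
  }
  cm <- if ("age*state" %in% best_spec$terms) {
    stage("age_state_means", age_state_means(fit))
  } else {
    NULL
  }
  trend <- if (!is.null(cm)) stage("old_age_trend", old_age_trend(cm)) else NULL

  res <- list(records = records, env = env, lrt = lrt,
              aic_table = aic_table, fit = fit,
              variance_partition = vp,
              repeatability = dplyr::bind_rows(rep_f, rep_y),
              first_vs_later = fvl, dyads = dyads,
              heritability = herit, permutation = perm,
              cell_means = cm, old_age_trend = trend)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, nm) {
      if (!is.null(x)) write_phenology(x, file.path(out_dir, nm))
    }
    wr(records, "records.csv")
    wr(env, "environment.csv")
    wr(res$lrt, "lrt_random_slope.csv")
    wr(tibble::as_tibble(aic_table), "aic_table.csv")
    wr(tidy(fit), "reml_estimates.csv")
    wr(vp, "variance_partition.csv")
    wr(res$repeatability, "repeatability.csv")
    wr(fvl, "first_vs_later.csv")
    wr(dyads, "dyads.csv")
    wr(herit, "heritability.csv")
    wr(perm, "permutation.csv")
    wr(cm, "age_state_means.csv")
    wr(trend, "old_age_trend.csv")
    writeLines(pipeline_report(res, config), file.path(out_dir, "report.txt"))
  }
  invisible(res)
}

pipeline_report <- function(res, config) {
  f <- res$fit
  lines <- c(
    "phenology analysis pipeline",
    sprintf("seed: %d; %d records, %d females, %d years",
            config$seed, f$n_obs, f$n_females, f$n_years),
    "",
    sprintf("random-slope LRT: chi2 = %.2f, df = %d, p = %.3g",
            res$lrt$chi2, res$lrt$df, res$lrt$p),
    sprintf("best model: %s (n.p. = %d)", res$aic_table$label[1],
            res$aic_table$n_params[1]),
    sprintf("REML components: sigma_i2 = %.2f, sigma_m2 = %.2f, cov = %.3f, sigma_j2 = %.2f, sigma_e2 = %.2f",
            f$sigma_i2, f$sigma_m2, f$cov_im, f$sigma_j2, f$sigma_e2),
    sprintf("variance partition (%%): %s",
            paste(sprintf("%s %.1f", res$variance_partition$component,
                          res$variance_partition$percent), collapse = ", ")),
    sprintf("repeatability: %s",
            paste(sprintf("%s R = %.3f [%.3f, %.3f]",
                          res$repeatability$group, res$repeatability$R,
                          res$repeatability$ci_low,
                          res$repeatability$ci_high), collapse = "; ")),
    sprintf("first-vs-later slope: %.3f [%.3f, %.3f]",
            res$first_vs_later$slope, res$first_vs_later$conf.low,
            res$first_vs_later$conf.high)
  )
  if (!is.null(res$heritability)) {
    lines <- c(lines, sprintf(
      "heritability: slope = %.3f (se %.3f), h2 = %.3f, %d dyads",
      res$heritability$slope, res$heritability$std.error,
      res$heritability$h2, res$heritability$n_dyads))
  }
  if (!is.null(res$permutation)) {
    p <- res$permutation$p_one_tailed
    lines <- c(lines, sprintf(
      "permutation test: one-tailed p %s (null mean slope %.3f [%.3f, %.3f], %d perms)",
      if (p == 0) sprintf("< %.1g", 1 / res$permutation$n_perm)
      else sprintf("= %.4f", p),
      res$permutation$null_mean_slope, res$permutation$null_ci_low,
      res$permutation$null_ci_high, res$permutation$n_perm))
  }
  if (!is.null(res$old_age_trend)) {
    lines <- c(lines, sprintf(
      "old-age trend (age >= %d): %.3f d/yr [%.3f, %.3f]",
      res$old_age_trend$start_age, res$old_age_trend$slope,
      res$old_age_trend$conf.low, res$old_age_trend$conf.high))
  }
  lines
}
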