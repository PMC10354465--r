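# tight optimizer settings for oracle comparisons
oracle_control <- function() {
  lme4::lmerControl(
    calc.derivs = FALSE, check.conv.singular = "ignore",
    optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12)
  )
}

test_that("REML on a balanced one-way layout equals the ANOVA closed form", {
  g <- 5
  k <- 4
  d <- one_way_records(g, k)
  fit <- fit_lmm(d, model_spec("intercept", random_slope = FALSE,
                               year_effect = FALSE),
                 method = "REML", control = oracle_control())
  ybar <- tapply(d$arrival, d$female_id, mean)
  MSB <- k * var(ybar)
  MSW <- sum((d$arrival - ybar[d$female_id])^2) / (g * (k - 1))
  expect_equal(fit$sigma_i2, (MSB - MSW) / k, tolerance = 1e-8)
  expect_equal(fit$sigma_e2, MSW, tolerance = 1e-8)
  b <- lme4::fixef(fit$model)
  expect_equal(unname(b["(Intercept)"]), mean(ybar), tolerance = 1e-8)
})

test_that("log-likelihood equals a dense multivariate-normal evaluation", {
  d <- tiny_crossed_records()
  spec <- model_spec(c("moult", "wean"))
  fit <- fit_lmm(d, spec = spec, method = "ML", control = oracle_control())

  # dense oracle: assemble V = Zf G Zf' + sigma_j2 Zy Zy' + sigma_e2 I
  des <- build_design(d, NULL, spec)
  X <- stats::model.matrix(des$fixed, des$frame)
  n <- nrow(X)
  Zf_int <- stats::model.matrix(~ 0 + female_id, des$frame)
  Zf_slp <- Zf_int * des$frame$moult_z
  Zy <- stats::model.matrix(~ 0 + factor(year), des$frame)
  G <- matrix(c(fit$sigma_i2, fit$cov_im, fit$cov_im, fit$sigma_m2), 2)
  V <- fit$sigma_e2 * diag(n) + fit$sigma_j2 * Zy %*% t(Zy)
  for (f in unique(des$frame$female_id)) {
    Zi <- cbind(Zf_int[, paste0("female_id", f)],
                Zf_slp[, paste0("female_id", f)])
    V <- V + Zi %*% G %*% t(Zi)
  }
  r <- des$frame$arrival - X %*% lme4::fixef(fit$model)
  ll_dense <- -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
                        t(r) %*% solve(V, r))
  expect_equal(fit$loglik, as.numeric(ll_dense), tolerance = 1e-8)
  expect_equal(fit$deviance, -2 * fit$loglik)
})

test_that("constant response collapses to a singular zero-variance fit", {
  d <- one_way_records()
  d$arrival <- 30
  d$year <- rep(2001:2004, 5)
  fit <- fit_lmm(d, model_spec("intercept", random_slope = FALSE),
                 method = "REML")
  expect_true(fit$singular)
  expect_equal(fit$sigma_i2, 0, tolerance = 1e-8)
  expect_equal(unname(lme4::fixef(fit$model)["(Intercept)"]), 30,
               tolerance = 1e-8)
})

test_that("ML deviance is monotone under fixed-effect nesting", {
  d <- small_sim(seed = 21, n = 300)
  f1 <- fit_lmm(d, model_spec("intercept"), method = "ML")
  f2 <- fit_lmm(d, model_spec(c("moult", "wean")), method = "ML")
  f3 <- fit_lmm(d, model_spec(c("age*state", "moult", "wean")), method = "ML")
  expect_gte(f1$deviance, f2$deviance)
  expect_gte(f2$deviance, f3$deviance)
})

test_that("REML criterion is invariant to recoding the fixed design", {
  d <- small_sim(seed = 22, n = 200)
  # same column space, different coding: shift the wean covariate
  d2 <- d
  d2$wean <- d2$wean + 100
  f1 <- fit_lmm(d, model_spec(c("moult", "wean")), method = "REML")
  f2 <- fit_lmm(d2, model_spec(c("moult", "wean")), method = "REML")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$sigma_i2, f2$sigma_i2, tolerance = 1e-5)
})

test_that("aic() follows the deviance + 2 n.p. rule and rejects REML fits", {
  d <- small_sim(seed = 23, n = 150)
  fml <- fit_lmm(d, model_spec("intercept"), method = "ML")
  expect_equal(aic(fml), fml$deviance + 2 * 6)
  expect_equal(aic(fml), AIC(fml$model), tolerance = 1e-10)
  frm <- fit_lmm(d, model_spec("intercept"), method = "REML")
  expect_error(aic(frm), "ML")
})

test_that("reaction norms shrink towards the population line", {
  d <- small_sim(seed = 24, n = 600)
  fit <- fit_lmm(d, model_spec(c("age*state", "moult", "wean")),
                 method = "REML")
  rn <- predict_reaction_norms(fit)
  expect_equal(nrow(rn$females), fit$n_females)
  # BLUP SD is shrunk below the generative intercept SD of 6.5
  expect_lt(rn$blup_sd$sd_intercept, 6.5)
  expect_gt(rn$blup_sd$sd_intercept, 3.0)
  # female lines are centred on the population line
  expect_equal(mean(rn$females$intercept), rn$population$intercept,
               tolerance = 0.5)
  expect_error(
    predict_reaction_norms(
      fit_lmm(d, model_spec("intercept", random_slope = FALSE), method = "ML")
    ),
    "random slope"
  )
})

test_that("study-scale estimates recover the generative components", {
  # single deep replicate; the multi-replicate version is in the
  # acceptance suite
  cfg <- sim_config(seed = 77)
  d <- simulate_population(cfg)
  fit <- fit_lmm(d, model_spec(c("age*state", "moult", "wean")),
                 method = "REML")
  tp <- true_parameters(cfg)
  expect_false(fit$singular)
  expect_true(fit$converged)
  # approximate Monte-Carlo 3-SE bands for one replicate
  expect_equal(fit$sigma_i2, tp$sigma_i2, tolerance = 0.25)
  expect_equal(fit$sigma_e2, tp$sigma_e2, tolerance = 0.10)
  b <- lme4::fixef(fit$model)
  expect_equal(unname(b["moult_z"]), 1.92, tolerance = 0.25)

  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_equal(nrow(dplyr::filter(td, effect == "ran_pars")), 5)
  g <- glance(fit)
  expect_equal(g$n_params, 30L)
  expect_equal(g$nobs, nrow(d))
})
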