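test_that("environment table has the documented structure", {
  env <- simulate_environment(1989:2019, seed = 3)
  expect_equal(nrow(env), 31)
  expect_equal(env$trend, 0:30)
  expect_equal(mean(env$density), 0, tolerance = 1e-12)
  expect_equal(sd(env$density), 1, tolerance = 1e-12)
  expect_equal(sd(env$SAM), 1, tolerance = 1e-12)

  # determinism and seed sensitivity
  expect_identical(env, simulate_environment(1989:2019, seed = 3))
  expect_false(identical(env$SAM, simulate_environment(1989:2019, 4)$SAM))

  one <- simulate_environment(2000, seed = 1)
  expect_equal(one$trend, 0)
  expect_equal(one$density, 0)

  expect_error(simulate_environment(integer(0)), "non-empty")
})

test_that("config validation rejects impossible parameter values", {
  expect_error(sim_config(sigma_i = -1), "SDs")
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(rho_im = 1.5), "rho_im")
  expect_error(sim_config(survival_per_year = 1.1), "survival")
  expect_error(sim_config(n_females = 0))
})

test_that("no-noise population is an exact deterministic function of covariates", {
  cfg <- sim_config(
    n_females = 40, sigma_i = 0, sigma_m = 0, rho_im = 0, sigma_j = 0,
    sigma_e = 0, beta_moult = 0, beta_wean = 0, h2 = 0,
    maternal_wean_link = FALSE, wean_noise_sd = 0, seed = 2
  )
  d <- simulate_population(cfg)
  asm <- cfg$age_state_means
  cell <- as.character(assign_age_state_cell(d$age, d$state))
  expect_equal(d$arrival, asm$mean[match(cell, asm$cell)])
})

test_that("default world reproduces the study dimensions", {
  d <- simulate_population(sim_config(seed = 101))
  n_fem <- dplyr::n_distinct(d$female_id)
  per <- table(d$female_id)
  expect_gt(n_fem, 1550)
  expect_lt(n_fem, 2000)
  expect_gt(nrow(d), 4700)
  expect_lt(nrow(d), 6000)
  expect_true(all(per >= 1 & per <= 16))
  # arrival distribution: ~10 d SD around early October
  expect_equal(mean(d$arrival), 34, tolerance = 0.06)
  expect_gt(sd(d$arrival), 8.5)
  expect_lt(sd(d$arrival), 11.5)
  # ages: raw values may exceed 21 (capped later at analysis), none below 3
  expect_gte(min(d$age), 3)
  # a first record precedes experienced ones for every female
  expect_silent(validate_phenology(d))
})

test_that("same seed reproduces the dataset bitwise; new seed perturbs it", {
  cfg <- sim_config(n_females = 60, seed = 7)
  d1 <- simulate_population(cfg)
  d2 <- simulate_population(cfg)
  expect_identical(tibble::as_tibble(d1), tibble::as_tibble(d2))
  d3 <- simulate_population(sim_config(n_females = 60, seed = 8))
  expect_false(isTRUE(all.equal(d1$arrival[seq_len(50)],
                                d3$arrival[seq_len(50)])))
})

test_that("individual intercepts and transmission match the configured truth", {
  # law of large numbers on u_i at 1e5 females (histories kept trivial)
  cfg <- sim_config(
    n_females = 100000, years = 2000:2001, survival_per_year = 0,
    daughter_recruit_prob = 0, seed = 31
  )
  d <- simulate_population(cfg)
  fem <- attr(d, "females")
  expect_equal(var(fem$u), cfg$sigma_i^2, tolerance = 0.02)
  expect_equal(var(fem$a), true_parameters(cfg)$sigma_a2, tolerance = 0.02)
  # intercept-slope correlation
  expect_equal(cor(fem$u, fem$s), cfg$rho_im, tolerance = 0.02)

  # mother-daughter covariance of genetic values: cov(a_m, a_d) = 0.5 sigma_a2
  cfg2 <- sim_config(n_females = 60000, years = 1989:2019,
                     daughter_recruit_prob = 0.9, seed = 32)
  d2 <- simulate_population(cfg2)
  fem2 <- attr(d2, "females")
  dts <- fem2[!is.na(fem2$mother_id), ]
  a_m <- fem2$a[match(dts$mother_id, fem2$female_id)]
  sigma_a2 <- true_parameters(cfg2)$sigma_a2
  expect_equal(cov(a_m, dts$a), 0.5 * sigma_a2, tolerance = 0.05)
})

test_that("true_parameters maps the config deterministically", {
  tp <- true_parameters(sim_config())
  expect_equal(tp$sigma_i2, 42.25)
  expect_equal(tp$sigma_m2, 2.56)
  expect_equal(tp$cov_im, 0.07)
  expect_equal(tp$slope_true, 0.2)
  expect_equal(tp$h2, 0.4)
  # repeatability truth consistent with its own components
  expect_equal(tp$R_female,
               tp$sigma_i2 / (tp$sigma_i2 + tp$sigma_j2 + tp$sigma_e2 +
                                tp$sigma_f2))

  # degenerate all-zero config is flagged, not silently NaN
  cfg0 <- sim_config(sigma_i = 0, sigma_m = 0, rho_im = 0, sigma_j = 0,
                     sigma_e = 0, beta_moult = 0, beta_wean = 0, h2 = 0,
                     maternal_wean_link = FALSE, wean_noise_sd = 0,
                     age_state_means = dplyr::mutate(
                       marion_age_state_means(), mean = 0))
  expect_warning(tp0 <- true_parameters(cfg0), "undefined")
  expect_true(is.na(tp0$R_female))
})

test_that("heritability calibration hits the phenotypic target", {
  cal <- herit_calibration(sim_config())
  # additive variance must stay inside the individual intercept variance
  expect_gt(cal$sigma_a2, 0)
  expect_lt(cal$sigma_a2, 42.25)
  # with the maternal link off the calibration is the plain phenotypic rule
  cfg_off <- sim_config(maternal_wean_link = FALSE)
  cal_off <- herit_calibration(cfg_off)
  expect_equal(cal_off$sigma_a2, 0.4 * cal_off$var_first)
  # unreachable targets are clamped with a warning
  expect_warning(herit_calibration(sim_config(h2 = 0.05)), "floor")
})
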