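#' Simulation configuration for a synthetic breeding-phenology population
#'
#' Bundles every generative parameter of the individual-based simulator. The
#' defaults describe a population calibrated to the Marion Island southern
#' elephant seal monitoring data: ~1772 breeding females with ~5297
#' analysable female-season records over 1989-2019, individual intercept SD
#' 6.5 d, individual moult-slope SD 1.6, year SD sqrt(3.08) d, residual SD
#' sqrt(44.56) d, population slopes of arrival on (standardized) moult
#' departure and weaning date of 1.92 and 1.26 d per SD, and narrow-sense
#' heritability 0.4 of the individual intercept.
#'
#' Arrival and wean dates are day offsets from 1 September of the breeding
#' year; moult departure dates are day offsets from 1 November of the
#' preceding summer (the moult haulout spans the calendar-year boundary).
#'
#' @param n_females Number of founder females (recruited daughters are
#'   generated on top of these; at the defaults the analysed population
#'   totals ~1772 females).
#' @param years Integer vector of breeding seasons (inclusive range).
#' @param mean_arrival Population reference arrival date, day offset from
#'   1 September (33 = 4 October, the long-term median).
#' @param sigma_i SD of individual arrival-date intercepts (days).
#' @param sigma_m SD of individual moult-date reaction-norm slopes
#'   (days per SD of moult date).
#' @param rho_im Correlation between individual intercepts and slopes.
#' @param sigma_j SD of year intercepts (days).
#' @param sigma_e Residual SD (days).
#' @param beta_moult Population slope of arrival on the standardized moult
#'   departure date (days per SD).
#' @param beta_wean Population slope of arrival on the standardized weaning
#'   date as a pup (days per SD).
#' @param age_state_means Tibble of age-by-state cell mean arrivals with
#'   columns `cell`, `age`, `state`, `mean`; defaults to
#'   [marion_age_state_means()].
#' @param h2 Target narrow-sense heritability of first-breeding arrival
#'   date on the phenotypic scale: the mother-daughter phenotype regression
#'   converges to slope `h2 / 2`. The generator back-solves the additive
#'   genetic variance of the individual intercept from this target,
#'   accounting for the maternal wean pathway when it is active (see
#'   [herit_calibration()]).
#' @param maternal_wean_link If `TRUE` (default) a daughter's weaning date
#'   derives from her mother's arrival in the birth season, creating a
#'   non-genetic maternal pathway of mother-daughter resemblance through
#'   `beta_wean`; if `FALSE` daughter wean dates are exogenous (an
#'   exchangeable null when `h2 = 0`).
#' @param lactation_offset_days Days from a mother's arrival to her pup's
#'   weaning date (birth ~5 d after arrival plus ~23 d of lactation).
#' @param wean_noise_sd SD (days) of the noise around the mother-arrival to
#'   pup-wean-date link.
#' @param moult_mean,moult_between_sd,moult_within_sd Mean, between-female
#'   SD and within-female SD (days) of moult departure dates.
#' @param recruit_age_range Possible ages at first breeding.
#' @param recruit_age_weights Sampling weights for `recruit_age_range`.
#' @param survival_per_year Probability a breeder returns the next season.
#' @param skip_prob Probability an alive female skips a breeding season.
#' @param max_seasons Cap on breeding seasons per female.
#' @param daughter_recruit_prob Probability that a breeding event produces a
#'   daughter that herself recruits into the breeding population.
#' @param obs_error_max Upper bound (days) of a uniform late-shift
#'   observation error applied to arrival dates; 0 (default) disables it.
#'   Weekly resight surveys correspond to ~6.
#' @param seed Master integer seed; child seeds for the environment and
#'   population streams are derived deterministically.
#'
#' @return A validated list of class `pheno_config`.
#' @seealso [simulate_population()], [true_parameters()]
#' @export
sim_config <- function(n_females = 1340,
                       years = 1989:2019,
                       mean_arrival = 33,
                       sigma_i = 6.5,
                       sigma_m = 1.6,
                       rho_im = 0.07 / (6.5 * 1.6),
                       sigma_j = sqrt(3.08),
                       sigma_e = sqrt(44.56),
                       beta_moult = 1.92,
                       beta_wean = 1.26,
                       age_state_means = NULL,
                       h2 = 0.40,
                       maternal_wean_link = TRUE,
                       lactation_offset_days = 28,
                       wean_noise_sd = 5.6,
                       moult_mean = 45,
                       moult_between_sd = 5,
                       moult_within_sd = 4,
                       recruit_age_range = 3:7,
                       recruit_age_weights = c(0.30, 0.30, 0.20, 0.15, 0.05),
                       survival_per_year = 0.73,
                       skip_prob = 0.15,
                       max_seasons = 16,
                       daughter_recruit_prob = 0.12,
                       obs_error_max = 0,
                       seed = 1L) {
  if (is.null(age_state_means)) {
    age_state_means <- marion_age_state_means(mean_arrival)
  }
  cfg <- list(
    n_females = as.integer(n_females), years = as.integer(years),
    mean_arrival = mean_arrival,
    sigma_i = sigma_i, sigma_m = sigma_m, rho_im = rho_im,
    sigma_j = sigma_j, sigma_e = sigma_e,
    beta_moult = beta_moult, beta_wean = beta_wean,
    age_state_means = age_state_means, h2 = h2,
    maternal_wean_link = isTRUE(maternal_wean_link),
    lactation_offset_days = lactation_offset_days,
    wean_noise_sd = wean_noise_sd,
    moult_mean = moult_mean, moult_between_sd = moult_between_sd,
    moult_within_sd = moult_within_sd,
    recruit_age_range = as.integer(recruit_age_range),
    recruit_age_weights = recruit_age_weights,
    survival_per_year = survival_per_year, skip_prob = skip_prob,
    max_seasons = as.integer(max_seasons),
    daughter_recruit_prob = daughter_recruit_prob,
    obs_error_max = obs_error_max,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pheno_config")
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$years) >= 1, cfg$n_females >= 1)
  sds <- c(cfg$sigma_i, cfg$sigma_m, cfg$sigma_j, cfg$sigma_e,
           cfg$wean_noise_sd, cfg$moult_between_sd, cfg$moult_within_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (abs(cfg$rho_im) > 1) stop("|rho_im| must be <= 1", call. = FALSE)
  if (cfg$h2 < 0 || cfg$h2 > 1) stop("h2 must lie in [0, 1]", call. = FALSE)
  if (cfg$survival_per_year < 0 || cfg$survival_per_year > 1) {
    stop("survival_per_year must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$skip_prob < 0 || cfg$skip_prob >= 1) {
    stop("skip_prob must lie in [0, 1)", call. = FALSE)
  }
  if (length(cfg$recruit_age_weights) != length(cfg$recruit_age_range)) {
    stop("recruit_age_weights must match recruit_age_range", call. = FALSE)
  }
  req <- c("cell", "age", "state", "mean")
  if (!all(req %in% names(cfg$age_state_means))) {
    stop("age_state_means needs columns cell, age, state, mean", call. = FALSE)
  }
  invisible(cfg)
}

#' Default age-by-state cell mean arrival dates
#'
#' Cell means on the capped 3-21 age scale: the single age-3 (first-breeder)
#' cell, separate first/experienced cells at ages 4-7, and shared cells from
#' age 8. First-time breeders arrive earlier than experienced breeders of the
#' same age; experienced arrival is latest at prime ages and declines
#' linearly by 0.43 d per year of age from age 8 - the curvilinear pattern
#' seen in the Marion Island data.
#'
#' @param mean_arrival Reference arrival day offset the cell offsets are
#'   anchored to.
#' @return Tibble with columns `cell`, `age`, `state`
#'   (`"first"`/`"experienced"`/`"both"`) and `mean`.
#' @export
marion_age_state_means <- function(mean_arrival = 33) {
  first <- tibble::tibble(
    age = 3:7, state = "first",
    offset = c(-3.0, -2.0, -1.5, -1.0, -0.5)
  )
  exper <- tibble::tibble(
    age = 4:7, state = "experienced",
    offset = c(2.0, 2.5, 2.7, 2.8)
  )
  old <- tibble::tibble(
    age = 8:21, state = "both",
    offset = 2.8 - 0.43 * (8:21 - 8)
  )
  dplyr::bind_rows(first, exper, old) |>
    dplyr::mutate(
      cell = age_state_cell_label(.data$age, .data$state),
      mean = mean_arrival + .data$offset
    ) |>
    dplyr::select("cell", "age", "state", "mean")
}

# internal label rule shared with assign_age_state_cell(); `state` may be
# "both" for the merged cells at ages >= 8
age_state_cell_label <- function(age, state) {
  age <- pmin(age, 21L)
  dplyr::case_when(
    age == 3L ~ "3",
    age >= 8L ~ as.character(age),
    state == "first" ~ paste0(age, "F"),
    state == "experienced" ~ paste0(age, "E"),
    TRUE ~ as.character(age)
  )
}

#' Simulate per-year environmental covariates
#'
#' Generates one row per breeding season: standardized AR(1) series for the
#' Southern Annular Mode (SAM) and Southern Oscillation Index (SOI) annual
#' means, a z-standardized slowly varying breeding-female population size
#' (density), and a linear trend in years since the series start.
#'
#' @param years Integer vector of seasons (non-empty).
#' @param seed Integer seed.
#' @param ar Autoregression coefficient of the climate series.
#' @return Tibble with columns `year`, `SAM`, `SOI`, `density`, `trend`.
#'   `density` has mean 0 and SD 1 over the generated years (a single year
#'   gets 0 by convention).
#' @export
simulate_environment <- function(years, seed = 1L, ar = 0.5) {
  if (length(years) == 0) stop("`years` must be non-empty", call. = FALSE)
  years <- sort(as.integer(years))
  n <- length(years)
  withr::local_seed(child_seed(seed, "environment"))
  ar1 <- function(n) {
    x <- numeric(n)
    x[1] <- rnorm(1)
    if (n > 1) {
      for (t in 2:n) x[t] <- ar * x[t - 1] + rnorm(1, sd = sqrt(1 - ar^2))
    }
    zstd(x)
  }
  # slow logistic-like population growth with AR noise, then z-standardized
  dens_raw <- 1 / (1 + exp(-(seq_len(n) - n / 2) / (n / 6))) + ar1(n) * 0.15
  tibble::tibble(
    year = years,
    SAM = ar1(n),
    SOI = ar1(n),
    density = zstd(dens_raw),
    trend = years - years[1]
  )
}

# z-standardize, mapping zero-variance input to zeros
zstd <- function(x) {
  s <- sd(x)
  if (length(x) < 2 || !is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Heritability calibration of the generative model
#'
#' Deterministically derives the additive genetic variance `sigma_a2` of the
#' individual arrival-date intercept from the configured phenotypic
#' heritability target `h2`, so that the mother-daughter first-breeding
#' phenotype regression converges to slope `h2 / 2`.
#'
#' Two pathways create mother-daughter covariance: genetic transmission of
#' the intercept (a daughter inherits `0.5 * a_mother`, contributing
#' `0.5 * sigma_a2`) and, when `maternal_wean_link` is on, the maternal wean
#' pathway (a daughter's weaning date tracks her mother's arrival in the
#' birth season and feeds back into her own arrival through `beta_wean`).
#' The calibration solves
#' `0.5 * sigma_a2 + maternal_cov = (h2 / 2) * var_first`
#' for `sigma_a2`, where `var_first` is the generative variance of a
#' first-breeding arrival date and `maternal_cov` the covariance contributed
#' by the wean pathway (computed from the configured variances, the
#' between-female share of moult-date variance, and the expected number of
#' breeding seasons under the survival/skip process with calendar
#' truncation). Targets below the maternal floor (or above what
#' `sigma_i^2` allows) are clamped with a warning.
#'
#' @param config A [sim_config()] object.
#' @return List: `sigma_a2`, `var_first` (variance of first-breeding
#'   arrivals), `var_any` (variance of arrivals over all records), `wean_sd`
#'   (SD of pup weaning dates), `kappa` (correlation factor between a
#'   mother's first arrival and her arrival in a random breeding season),
#'   `maternal_cov`, `expected_seasons`.
#' @export
herit_calibration <- function(config) {
  cfg <- config
  asm <- cfg$age_state_means
  # variance of cell means among first-time breeders (recruit-age weighted)
  w_r <- cfg$recruit_age_weights / sum(cfg$recruit_age_weights)
  first_cells <- age_state_cell_label(cfg$recruit_age_range, "first")
  mu_first <- asm$mean[match(first_cells, asm$cell)]
  var_cell_first <- sum(w_r * mu_first^2) - sum(w_r * mu_first)^2
  occ <- cell_occupancy(cfg)
  mu_all <- asm$mean[match(occ$cell, asm$cell)]
  var_cell_all <- sum(occ$prob * mu_all^2) - sum(occ$prob * mu_all)^2

  base <- cfg$sigma_i^2 + cfg$sigma_j^2 + cfg$sigma_e^2 +
    cfg$beta_moult^2 + cfg$sigma_m^2 + cfg$beta_wean^2
  var_first <- base + var_cell_first
  var_any <- base + var_cell_all
  wean_sd <- sqrt(var_any + cfg$wean_noise_sd^2)

  # expected breeding seasons per female, with calendar truncation
  yrs <- seq_along(cfg$years) - 1
  ek_y <- vapply(yrs, function(left) {
    t <- 0:(max(cfg$years) - min(cfg$years) - left)
    sum(cfg$survival_per_year^t * ifelse(t == 0, 1, 1 - cfg$skip_prob))
  }, numeric(1))
  expected_seasons <- mean(ek_y)
  p_first <- 1 / expected_seasons

  mt2 <- cfg$moult_between_sd^2 + cfg$moult_within_sd^2
  rho_b <- if (mt2 > 0) cfg$moult_between_sd^2 / mt2 else 0
  # recruit age shifts the whole age trajectory, so the first-breeding cell
  # mean covaries with later-season cell means
  t_max <- max(length(cfg$years) - 1, 1)
  t_later <- 1:t_max
  w_t <- cfg$survival_per_year^t_later * (1 - cfg$skip_prob)
  grid <- expand.grid(r = seq_along(cfg$recruit_age_range), t = t_later)
  w_rt <- w_r[grid$r] * w_t[grid$t]
  cov_cells <- if (sum(w_rt) > 0) {
    w_rt <- w_rt / sum(w_rt)
    m1 <- mu_first[grid$r]
    age_later <- cfg$recruit_age_range[grid$r] + grid$t
    m2 <- asm$mean[match(age_state_cell_label(age_later, "experienced"),
                         asm$cell)]
    sum(w_rt * m1 * m2) - sum(w_rt * m1) * sum(w_rt * m2)
  } else {
    0
  }
  # covariance between a mother's first arrival and a random breeding season
  cov_other <- cfg$sigma_i^2 + cfg$beta_wean^2 +
    (cfg$beta_moult^2 + cfg$sigma_m^2) * rho_b + cov_cells
  kappa <- if (var_first > 0) {
    p_first + (1 - p_first) * cov_other / var_first
  } else {
    0
  }
  maternal_cov <- if (cfg$maternal_wean_link && wean_sd > 0) {
    cfg$beta_wean * kappa * var_first / wean_sd
  } else {
    0
  }

  sigma_a2 <- cfg$h2 * var_first - 2 * maternal_cov
  if (sigma_a2 < 0) {
    if (cfg$h2 > 0 || maternal_cov > 0) {
      warning("h2 target below the maternal-pathway floor; ",
              "additive genetic variance clamped to 0", call. = FALSE)
    }
    sigma_a2 <- 0
  }
  if (sigma_a2 > cfg$sigma_i^2) {
    warning("h2 target exceeds what sigma_i^2 allows; ",
            "additive genetic variance clamped to sigma_i^2", call. = FALSE)
    sigma_a2 <- cfg$sigma_i^2
  }
  list(sigma_a2 = sigma_a2, var_first = var_first, var_any = var_any,
       wean_sd = wean_sd, kappa = kappa, maternal_cov = maternal_cov,
       expected_seasons = expected_seasons)
}

#' Simulate a longitudinal breeding-phenology population
#'
#' Draws an individual-based population under the generative analogue of the
#' analysis model: for female i in year j,
#' `arrival_ij = cell_mean(age, state) + beta_wean * wean_z_i +
#' (beta_moult + s_i) * moult_z_ij + u_i + v_j + eps_ij`,
#' with `(u_i, s_i)` bivariate normal (SDs `sigma_i`, `sigma_m`, correlation
#' `rho_im`), `v_j ~ N(0, sigma_j^2)` and `eps ~ N(0, sigma_e^2)`.
#' The individual intercept decomposes as `u_i = a_i + e_i` with additive
#' genetic part `a_i` of variance `h2 * sigma_i^2`; a daughter inherits
#' `a_d = 0.5 * a_mother + N(0, 0.75 * sigma_a^2)` (unknown sire), so the
#' mother-daughter covariance of intercepts is `0.5 * sigma_a^2`. A
#' daughter's weaning date is her mother's arrival plus
#' `lactation_offset_days` plus noise, and her `mother_id` is recorded for
#' dyad construction. Breeding histories are runs of seasons governed by
#' `survival_per_year` with random skipped seasons.
#'
#' Moult and wean covariates affect arrival through their z-standardized
#' values (generative standardization uses the configured population mean
#' and SD).
#'
#' @param config A [sim_config()] object.
#' @return A tibble of class `pheno_data` with one row per female x season:
#'   `female_id`, `year`, `age`, `state`, `arrival`, `wean`, `moult`,
#'   `mother_id`. The per-female truth (intercepts `u`, slopes `s`, genetic
#'   values `a`) is attached as attribute `"females"`, the year effects as
#'   `"year_effects"`, and the config as `"config"`.
#' @export
simulate_population <- function(config) {
  cfg <- validate_config(config)
  withr::local_seed(child_seed(cfg$seed, "population"))

  calib <- herit_calibration(cfg)
  sigma_a <- sqrt(calib$sigma_a2)
  sigma_env <- sqrt(max(cfg$sigma_i^2 - sigma_a^2, 0)) # non-genetic part of u
  moult_sd_tot <- sqrt(cfg$moult_between_sd^2 + cfg$moult_within_sd^2)
  # theoretical standardization constants for the wean covariate
  wean_mu <- cfg$mean_arrival + cfg$lactation_offset_days
  wean_sd <- if (calib$wean_sd > 0) calib$wean_sd else 1
  moult_z_denom <- if (moult_sd_tot > 0) moult_sd_tot else 1

  years <- cfg$years
  v_j <- setNames(rnorm(length(years), 0, cfg$sigma_j), years)

  draw_slope <- function(u) {
    # conditional draw of the slope deviation given the intercept
    if (cfg$sigma_i > 0) {
      cfg$rho_im * (cfg$sigma_m / cfg$sigma_i) * u +
        rnorm(length(u), 0, cfg$sigma_m * sqrt(1 - cfg$rho_im^2))
    } else {
      rnorm(length(u), 0, cfg$sigma_m)
    }
  }

  n <- cfg$n_females
  founders <- tibble::tibble(
    female_id = sprintf("F%05d", seq_len(n)),
    recruit_year = sample(years, n, replace = TRUE),
    recruit_age = sample(cfg$recruit_age_range, n, replace = TRUE,
                         prob = cfg$recruit_age_weights),
    a = rnorm(n, 0, sigma_a),
    wean = rnorm(n, wean_mu, wean_sd),
    mother_id = NA_character_
  )
  founders$u <- founders$a + rnorm(n, 0, sigma_env)
  founders$s <- draw_slope(founders$u)

  records <- breeding_records(founders, cfg, v_j, moult_z_denom,
                              wean_mu, wean_sd)

  # second generation: daughters spawned by founder breeding events
  spawn <- records[runif(nrow(records)) < cfg$daughter_recruit_prob, ]
  if (nrow(spawn) > 0) {
    nd <- nrow(spawn)
    d_age <- sample(cfg$recruit_age_range, nd, replace = TRUE,
                    prob = cfg$recruit_age_weights)
    d_recruit <- spawn$year + d_age
    keep <- d_recruit <= max(years)
    spawn <- spawn[keep, ]
    if (nrow(spawn) > 0) {
      nd <- nrow(spawn)
      mother_a <- founders$a[match(spawn$female_id, founders$female_id)]
      daughters <- tibble::tibble(
        female_id = sprintf("D%05d", seq_len(nd)),
        recruit_year = d_recruit[keep],
        recruit_age = d_age[keep],
        a = 0.5 * mother_a + rnorm(nd, 0, sqrt(0.75) * sigma_a),
        wean = if (cfg$maternal_wean_link) {
          spawn$arrival + cfg$lactation_offset_days +
            rnorm(nd, 0, cfg$wean_noise_sd)
        } else {
          rnorm(nd, wean_mu, wean_sd)
        },
        mother_id = spawn$female_id
      )
      daughters$u <- daughters$a + rnorm(nd, 0, sigma_env)
      daughters$s <- draw_slope(daughters$u)
      rec_d <- breeding_records(daughters, cfg, v_j, moult_z_denom,
                                wean_mu, wean_sd)
      records <- dplyr::bind_rows(records, rec_d)
      founders <- dplyr::bind_rows(founders, daughters)
    }
  }

  if (cfg$obs_error_max > 0) {
    records$arrival <- records$arrival +
      runif(nrow(records), 0, cfg$obs_error_max)
  }
  records <- dplyr::arrange(records, .data$female_id, .data$year)
  structure(records,
            females = founders, year_effects = v_j, config = cfg,
            class = c("pheno_data", class(tibble::tibble())))
}

# Generate season rows for a cohort table (female_id, recruit_year,
# recruit_age, u, s, wean, mother_id); shared by founders and daughters.
breeding_records <- function(fem, cfg, v_j, moult_z_denom, wean_mu, wean_sd) {
  years <- cfg$years
  last_year <- max(years)
  n <- nrow(fem)
  # lifespan after recruitment: geometric in survival_per_year
  extra <- if (cfg$survival_per_year > 0 && cfg$survival_per_year < 1) {
    stats::rgeom(n, 1 - cfg$survival_per_year)
  } else if (cfg$survival_per_year == 0) {
    rep(0L, n)
  } else {
    rep(length(years), n)
  }
  per_female <- lapply(seq_len(n), function(i) {
    yrs <- fem$recruit_year[i] + 0:extra[i]
    yrs <- yrs[yrs <= last_year]
    if (length(yrs) > 1) {
      breed <- c(TRUE, runif(length(yrs) - 1) >= cfg$skip_prob)
      yrs <- yrs[breed]
    }
    head(yrs, cfg$max_seasons)
  })
  len <- lengths(per_female)
  idx <- rep(seq_len(n), len)
  yr <- unlist(per_female, use.names = FALSE)
  m <- length(yr)
  if (m == 0) {
    return(tibble::tibble(female_id = character(), year = integer(),
                          age = integer(), state = character(),
                          arrival = numeric(), wean = numeric(),
                          moult = numeric(), mother_id = character()))
  }
  first <- !duplicated(idx)
  age <- fem$recruit_age[idx] + (yr - fem$recruit_year[idx])
  state <- ifelse(first, "first", "experienced")
  moult_between <- rnorm(n, 0, cfg$moult_between_sd)
  moult <- cfg$moult_mean + moult_between[idx] +
    rnorm(m, 0, cfg$moult_within_sd)
  moult_z <- (moult - cfg$moult_mean) / moult_z_denom
  wean_z <- (fem$wean[idx] - wean_mu) / wean_sd

  cells <- age_state_cell_label(age, state)
  asm <- cfg$age_state_means
  cell_mean <- asm$mean[match(cells, asm$cell)]
  if (anyNA(cell_mean)) {
    stop("age_state_means is missing cells: ",
         paste(unique(cells[is.na(cell_mean)]), collapse = ", "),
         call. = FALSE)
  }
  arrival <- cell_mean + cfg$beta_wean * wean_z +
    (cfg$beta_moult + fem$s[idx]) * moult_z +
    fem$u[idx] + v_j[as.character(yr)] + rnorm(m, 0, cfg$sigma_e)

  tibble::tibble(
    female_id = fem$female_id[idx], year = as.integer(yr),
    age = as.integer(age), state = state,
    arrival = as.numeric(arrival), wean = fem$wean[idx],
    moult = moult, mother_id = fem$mother_id[idx]
  )
}

#' Generative truth for every quantity the pipeline estimates
#'
#' Deterministically maps a simulation configuration to the target values
#' used in parameter-recovery tests: variance components, population slopes,
#' the fixed-effect variance of the generative linear predictor, individual
#' and year repeatability, heritability and the implied parent-offspring
#' regression slope.
#'
#' The fixed-effect variance combines the variance of the age/state cell
#' means under a deterministic survival/skip occupancy model (calendar
#' truncation of histories is ignored, a <1 d^2 approximation) with the
#' slope contributions `beta_moult^2 + beta_wean^2` of the standardized
#' covariates. Repeatability excludes the slope variance from the
#' denominator, matching the [repeatability()] default.
#'
#' @param config A [sim_config()] object.
#' @param quiet Suppress the warning for degenerate (all-zero variance)
#'   configurations.
#' @return One-row tibble with `sigma_i2`, `sigma_m2`, `cov_im`, `sigma_j2`,
#'   `sigma_e2`, `sigma_a2`, `sigma_f2`, `phenotypic_var`, `beta_moult`,
#'   `beta_wean`, `R_female`, `R_year`, `h2`, `slope_true`.
#' @export
true_parameters <- function(config, quiet = FALSE) {
  cfg <- validate_config(config)
  occ <- cell_occupancy(cfg)
  asm <- cfg$age_state_means
  mu <- asm$mean[match(occ$cell, asm$cell)]
  w <- occ$prob
  var_cell <- sum(w * mu^2) - sum(w * mu)^2
  sigma_f2 <- var_cell + cfg$beta_moult^2 + cfg$beta_wean^2
  denom <- cfg$sigma_i^2 + cfg$sigma_j^2 + cfg$sigma_e^2 + sigma_f2
  if (denom == 0) {
    if (!quiet) {
      warning("all generative variances are zero; repeatability undefined",
              call. = FALSE)
    }
    R_f <- NA_real_
    R_y <- NA_real_
  } else {
    R_f <- cfg$sigma_i^2 / denom
    R_y <- cfg$sigma_j^2 / denom
  }
  calib <- withCallingHandlers(
    herit_calibration(cfg),
    warning = function(w) if (quiet) invokeRestart("muffleWarning")
  )
  tibble::tibble(
    sigma_i2 = cfg$sigma_i^2, sigma_m2 = cfg$sigma_m^2,
    cov_im = cfg$rho_im * cfg$sigma_i * cfg$sigma_m,
    sigma_j2 = cfg$sigma_j^2, sigma_e2 = cfg$sigma_e^2,
    sigma_a2 = calib$sigma_a2,
    sigma_f2 = sigma_f2,
    phenotypic_var = denom,
    beta_moult = cfg$beta_moult, beta_wean = cfg$beta_wean,
    R_female = R_f, R_year = R_y,
    h2 = cfg$h2, slope_true = cfg$h2 / 2
  )
}

# Deterministic age/state cell occupancy implied by the survival/skip
# process, mixing over recruitment ages. Calendar-window truncation is
# ignored.
cell_occupancy <- function(cfg) {
  t_max <- max(length(cfg$years) - 1, 0)
  t <- 0:t_max
  w_t <- cfg$survival_per_year^t * ifelse(t == 0, 1, 1 - cfg$skip_prob)
  grid <- expand.grid(r = seq_along(cfg$recruit_age_range), t = t)
  p <- cfg$recruit_age_weights[grid$r] / sum(cfg$recruit_age_weights) *
    w_t[grid$t + 1]
  age <- cfg$recruit_age_range[grid$r] + grid$t
  state <- ifelse(grid$t == 0, "first", "experienced")
  tibble::tibble(cell = age_state_cell_label(age, state), p = p) |>
    dplyr::summarise(prob = sum(p), .by = "cell") |>
    dplyr::mutate(prob = .data$prob / sum(.data$prob))
}
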