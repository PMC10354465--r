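# Hand-built record tables (independent of the simulator) used across tests.

# balanced one-way layout: g females x k replicates, no year structure
one_way_records <- function(g = 5, k = 4, sd_b = 6, sd_w = 2, seed = 5) {
  withr::local_seed(seed)
  b <- rnorm(g, 0, sd_b)
  tibble::tibble(
    female_id = rep(sprintf("f%d", seq_len(g)), each = k),
    year = 2000L, age = 5L, state = "experienced",
    arrival = 30 + b[rep(seq_len(g), each = k)] + rnorm(g * k, 0, sd_w),
    wean = 60, moult = 45, mother_id = NA_character_
  )
}

# tiny crossed layout (<= 8 rows): 3 females x years, varying moult
tiny_crossed_records <- function(seed = 11) {
  withr::local_seed(seed)
  tibble::tibble(
    female_id = rep(c("a", "b", "c"), times = c(3, 3, 2)),
    year = c(2001L, 2002L, 2003L, 2001L, 2002L, 2003L, 2002L, 2003L),
    age = c(4L, 5L, 6L, 5L, 6L, 7L, 6L, 7L),
    state = rep(c("first", "experienced", "experienced"), length.out = 8)[
      c(1, 2, 3, 1, 2, 3, 1, 2)],
    arrival = 30 + rnorm(8, 0, 5),
    wean = rep(c(55, 62, 58), times = c(3, 3, 2)),
    moult = 45 + rnorm(8, 0, 4),
    mother_id = NA_character_
  ) |>
    dplyr::mutate(state = ifelse(duplicated(female_id), "experienced",
                                 "first"))
}

# small simulated world for fast end-to-end checks
small_sim <- function(seed = 1, n = 250, ...) {
  simulate_population(sim_config(n_females = n, seed = seed, ...))
}

# reduced-noise config whose truth is exactly known (flat cells, exogenous
# covariates) - used for coverage / calibration checks
flat_config <- function(n = 300, seed = 1, ...) {
  cells <- marion_age_state_means(33)
  cells$mean <- 33
  sim_config(n_females = n, age_state_means = cells, h2 = 0,
             maternal_wean_link = FALSE, daughter_recruit_prob = 0,
             seed = seed, ...)
}
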