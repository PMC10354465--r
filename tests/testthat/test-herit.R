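# build a dyad fixture directly: mothers with known daughter structure
dyad_records <- function(mother_arrivals, daughter_arrivals_by_mother) {
  stopifnot(length(mother_arrivals) == length(daughter_arrivals_by_mother))
  n_m <- length(mother_arrivals)
  mothers <- tibble::tibble(
    female_id = sprintf("M%03d", seq_len(n_m)),
    year = 1990L, age = 4L, state = "first",
    arrival = mother_arrivals, wean = 60, moult = 45,
    mother_id = NA_character_
  )
  kids <- purrr::imap(daughter_arrivals_by_mother, function(arr, i) {
    if (length(arr) == 0) return(NULL)
    tibble::tibble(
      female_id = sprintf("D%03d_%d", i, seq_along(arr)),
      year = 1996L, age = 4L, state = "first",
      arrival = arr, wean = 60, moult = 45,
      mother_id = sprintf("M%03d", i)
    )
  })
  dplyr::bind_rows(mothers, purrr::compact(kids))
}

test_that("dyad construction averages daughters and drops non-recruits", {
  d <- dyad_records(c(30, 35, 40), list(c(10, 14), 20, numeric(0)))
  dy <- build_dyads(d)
  expect_equal(nrow(dy), 2)
  expect_equal(dy$daughter_arrival[dy$mother_id == "M001"], 12)
  expect_equal(dy$n_daughters[dy$mother_id == "M001"], 2L)
  # a daughter whose mother is absent from the records is ignored
  orphan <- d
  orphan$mother_id[orphan$female_id == "D002_1"] <- "M999"
  expect_equal(nrow(build_dyads(orphan)), 1)
  # no links at all: empty table, not an error
  expect_equal(nrow(build_dyads(dyad_records(c(30, 31), list(NULL, NULL)))), 0)
})

test_that("216 mother-daughter instances with 29 repeat mothers give 187 dyads", {
  withr::local_seed(77)
  n_m <- 187
  kids <- lapply(seq_len(n_m), function(i) {
    rnorm(if (i <= 29) 2 else 1, mean = 33, sd = 8)
  })
  d <- dyad_records(rnorm(n_m, 33, 8), kids)
  expect_equal(sum(lengths(kids)), 216)
  dy <- build_dyads(d)
  expect_equal(nrow(dy), 187)
  expect_equal(sum(dy$n_daughters), 216)
})

test_that("parent-offspring regression doubles the slope into h2", {
  withr::local_seed(78)
  x <- rnorm(60, 33, 8)
  d <- dyad_records(x, as.list(0.2 * x + rnorm(60, 26, 5)))
  res <- parent_offspring_h2(build_dyads(d))
  expect_equal(res$h2, 2 * res$slope)
  expect_equal(res$n_dyads, 60)

  # daughters identical to mothers: slope 1, h2 = 2 reported with warning
  # (the exact-fit lm also warns; capture everything)
  d1 <- dyad_records(x, as.list(x))
  w <- capture_warnings(res1 <- parent_offspring_h2(build_dyads(d1)))
  expect_true(any(grepl("outside", w)))
  expect_equal(res1$slope, 1, tolerance = 1e-12)
  expect_equal(res1$h2, 2, tolerance = 1e-12)

  # invariance: shifting all dates leaves the slope unchanged
  d2 <- d
  d2$arrival <- d2$arrival + 50
  expect_equal(parent_offspring_h2(build_dyads(d2))$slope, res$slope,
               tolerance = 1e-10)

  expect_error(parent_offspring_h2(build_dyads(d)[1:2, ]), "3 dyads")
  dd <- dyad_records(rep(33, 5), as.list(rnorm(5)))
  expect_error(parent_offspring_h2(build_dyads(dd)), "identical")
})

test_that("simulated transmission is recovered at large dyad counts", {
  cfg <- sim_config(n_females = 8000, daughter_recruit_prob = 0.6, seed = 79)
  d <- simulate_population(cfg)
  dy <- build_dyads(d)
  expect_gt(nrow(dy), 5000)
  res <- parent_offspring_h2(dy)
  expect_equal(res$h2, 0.40, tolerance = 0.15)
})

test_that("permutation test is seeded and counts correctly", {
  withr::local_seed(80)
  x <- rnorm(80, 33, 8)
  d <- dyad_records(x, as.list(0.5 * x + rnorm(80, 16, 3)))

  # daughters constructed at slope 0.5 give h2 = 1.0ish with noise; the
  # out-of-range warning is possible and irrelevant here
  p1 <- suppressWarnings(permutation_test(d, n_perm = 300, seed = 5))
  p2 <- suppressWarnings(permutation_test(d, n_perm = 300, seed = 5))
  expect_identical(attr(p1, "null_slopes"), attr(p2, "null_slopes"))

  # strong transmission: observed h2 beats every null draw
  expect_equal(p1$p_one_tailed, 0)
  # the null distribution is centred near zero
  se_null <- sd(attr(p1, "null_slopes")) / sqrt(p1$n_perm)
  expect_lt(abs(p1$null_mean_slope), 3 * se_null + 0.01)

  # plus-one variant never returns exactly zero
  p3 <- suppressWarnings(permutation_test(d, n_perm = 300, seed = 5,
                                          plus_one = TRUE))
  expect_equal(p3$p_one_tailed, 1 / 301)

  w2 <- capture_warnings(permutation_test(d, n_perm = 50, seed = 1))
  expect_true(any(grepl("n_perm", w2)))
})

test_that("permutation keeps the multiplicity structure fixed", {
  withr::local_seed(81)
  kids <- lapply(1:40, function(i) rnorm(if (i <= 10) 3 else 1, 33, 6))
  d <- dyad_records(rnorm(40, 33, 6), kids)
  dy <- build_dyads(d)
  p <- suppressWarnings(permutation_test(d, n_perm = 200, seed = 2))
  # the null slopes vary (daughters really are shuffled)
  expect_gt(sd(attr(p, "null_slopes")), 0)
  # observed dyad table is untouched
  expect_equal(build_dyads(d), dy)
})
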