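#' Read a phenology CSV into a validated record table
#'
#' Expects one row per female x breeding season with columns `female_id`,
#' `year`, `age`, `state` (`"first"`/`"experienced"`), `arrival`, `wean`,
#' `moult` and optionally `mother_id` (day offsets as documented in
#' [simulate_population()]). Rows missing `arrival`, `moult` or `wean` are
#' dropped with a message (the analysis uses only females seen breeding and
#' in the preceding moult); configured seasons (by default the
#' poorly surveyed 1998 season) are excluded.
#'
#' @param path CSV file path.
#' @param exclude_years Seasons dropped from the analysis; `NULL` keeps all.
#' @return A validated `pheno_data` tibble.
#' @export
load_phenology <- function(path, exclude_years = 1998L) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_phenology(raw, exclude_years = exclude_years)
}

#' Validate a phenology record table
#'
#' Checks the schema, drops incomplete rows with a message, enforces unique
#' (female, year) keys, monotone ages within females, a time-constant wean
#' date per female, and that a `"first"` record precedes all `"experienced"`
#' records of the same female.
#'
#' @param records Data frame of phenology records.
#' @param exclude_years Seasons to drop before validation checks.
#' @return A `pheno_data` tibble (attributes of simulated input preserved).
#' @export
validate_phenology <- function(records, exclude_years = NULL) {
  req <- c("female_id", "year", "age", "state", "arrival", "wean", "moult")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  att <- attributes(records)
  out <- tibble::as_tibble(records)
  if (!"mother_id" %in% names(out)) out$mother_id <- NA_character_
  if (!is.null(exclude_years)) {
    out <- dplyr::filter(out, !.data$year %in% exclude_years)
  }
  incomplete <- !stats::complete.cases(out[c("arrival", "moult", "wean")])
  if (any(incomplete)) {
    message(sum(incomplete),
            " record(s) missing arrival, moult or wean were excluded")
    out <- out[!incomplete, ]
  }
  if (nrow(out) == 0) stop("no usable records", call. = FALSE)
  dup <- duplicated(out[c("female_id", "year")])
  if (any(dup)) {
    k <- out[dup, c("female_id", "year")][1, ]
    stop("duplicate (female_id, year) key: ", k$female_id, ", ", k$year,
         call. = FALSE)
  }
  if (any(out$age < 3)) stop("ages below 3 are not valid", call. = FALSE)
  bad_state <- setdiff(unique(out$state), c("first", "experienced"))
  if (length(bad_state) > 0) {
    stop("unknown breeding state: ", paste(bad_state, collapse = ", "),
         call. = FALSE)
  }
  chk <- out |>
    dplyr::arrange(.data$female_id, .data$year) |>
    dplyr::summarise(
      mono = all(diff(.data$age) > 0) || dplyr::n() == 1,
      wean_const = dplyr::n_distinct(.data$wean) == 1,
      first_ok = sum(.data$state == "first") <= 1 &&
        (!any(.data$state == "first") || .data$state[1] == "first"),
      .by = "female_id"
    )
  if (any(!chk$mono)) {
    stop("non-monotone ages within female(s): ",
         paste(head(chk$female_id[!chk$mono], 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(!chk$wean_const)) {
    stop("wean date varies within female(s): ",
         paste(head(chk$female_id[!chk$wean_const], 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(!chk$first_ok)) {
    stop("'first' state must occur once and precede 'experienced' records: ",
         paste(head(chk$female_id[!chk$first_ok], 3), collapse = ", "),
         call. = FALSE)
  }
  keep_attr <- c("females", "year_effects", "config")
  for (a in intersect(keep_attr, names(att))) attr(out, a) <- att[[a]]
  class(out) <- unique(c("pheno_data", class(out)))
  out
}

#' Write phenology records or an environment table to CSV
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_phenology <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}

#' Within-subject centring of a time-varying covariate
#'
#' Splits a covariate x into a per-female mean and per-record deviations
#' from that mean, so between-individual and within-individual effects can
#' be estimated separately when the two columns replace the raw covariate in
#' the fixed design.
#'
#' @param records Phenology records (needs `female_id`).
#' @param covariate Name of the covariate column to centre.
#' @return `records` with two extra columns `<covariate>_b` (the subject
#'   mean) and `<covariate>_w` (the within-subject deviation; sums to zero
#'   within each female).
#' @export
within_subject_centre <- function(records, covariate) {
  if (!covariate %in% names(records)) {
    stop("covariate not found: ", covariate, call. = FALSE)
  }
  x <- records[[covariate]]
  if (anyNA(x)) stop("covariate has missing values: ", covariate, call. = FALSE)
  out <- tibble::as_tibble(records)
  xbar <- stats::ave(x, records$female_id)
  out[[paste0(covariate, "_b")]] <- xbar
  out[[paste0(covariate, "_w")]] <- x - xbar
  out
}

#' Assign the age-by-state cell of a record
#'
#' Ages are capped at 21 (all females aged 21-26 are treated as 21);
#' first-time and experienced breeders are separated at ages 4-7; age 3 is a
#' first-breeder-only cell; from age 8 first-time breeders are merged into
#' the common age cell. This yields 23 cells in total.
#'
#' @param age Integer ages (>= 3).
#' @param state `"first"` or `"experienced"` (recycled if length 1).
#' @return Factor with the 23 cell levels
#'   (`"3"`, `"4F"`, `"4E"`, ..., `"7F"`, `"7E"`, `"8"`, ..., `"21"`).
#' @export
assign_age_state_cell <- function(age, state) {
  if (any(age < 3)) stop("ages below 3 are not valid", call. = FALSE)
  if (length(state) == 1) state <- rep(state, length(age))
  factor(age_state_cell_label(age, state), levels = age_state_cell_levels())
}

age_state_cell_levels <- function() {
  c("3", paste0(rep(4:7, each = 2), c("F", "E")), as.character(8:21))
}

#' Specify a fixed-effect model structure
#'
#' A model is an ordered set of term names drawn from `age*state`, `age`,
#' `state`, `moult`, `wean`, `SAM`, `SOI`, `N`, `trend` and `intercept`.
#' Age terms use cell-means coding (`age*state` spans 23 columns, `age`
#' alone 19); climate and density covariates each contribute two
#' within-subject-centred columns; `moult`, `wean` and `trend` contribute
#' one column each. The random structure is a year intercept plus a female
#' intercept with (by default) a correlated moult-date slope: 5 random-effect
#' parameters with the slope, 3 without.
#'
#' @param terms Character vector of term names (`"intercept"` alone gives
#'   the null model).
#' @param label Optional display label; defaults to `terms` joined by " + ".
#' @param random_slope Include the female moult-date random slope.
#' @param year_effect Include the year random intercept (disabled only for
#'   degenerate one-grouping fixtures, e.g. closed-form oracle checks).
#' @return A `pheno_spec` object with the implied fixed column count and
#'   total parameter count `n_params`.
#' @export
model_spec <- function(terms, label = NULL, random_slope = TRUE,
                       year_effect = TRUE) {
  known <- c("age*state", "age", "state", "moult", "wean",
             "SAM", "SOI", "N", "trend", "intercept")
  bad <- setdiff(terms, known)
  if (length(bad) > 0) {
    stop("unknown term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (all(c("age*state", "age") %in% terms)) {
    stop("use either 'age*state' or 'age', not both", call. = FALSE)
  }
  n_fixed <- if ("age*state" %in% terms) {
    23L + ("state" %in% terms) * 0L
  } else if ("age" %in% terms) {
    19L
  } else {
    1L + ("state" %in% terms) * 1L
  }
  n_fixed <- n_fixed +
    sum(c("moult", "wean", "trend") %in% terms) +
    2L * sum(c("SAM", "SOI", "N") %in% terms)
  n_random <- 2L + 2L * random_slope + 1L * year_effect
  structure(
    list(terms = terms,
         label = label %||% paste(terms, collapse = " + "),
         random_slope = random_slope,
         year_effect = isTRUE(year_effect),
         n_fixed = as.integer(n_fixed),
         n_params = as.integer(n_fixed + n_random)),
    class = "pheno_spec"
  )
}

#' @export
#' @method print pheno_spec
print.pheno_spec <- function(x, ...) {
  cat("<pheno_spec> ", x$label, "\n", sep = "")
  cat("  fixed columns: ", x$n_fixed,
      "; random-effect parameters: ", x$n_params - x$n_fixed,
      "; n.p. = ", x$n_params, "\n", sep = "")
  invisible(x)
}

#' Build the fixed design frame for a model specification
#'
#' Joins the environment table, z-standardizes the moult and wean covariates
#' over the analysed rows (so slopes are in days per covariate SD and the
#' random moult slope is centred), applies within-subject centring to SAM,
#' SOI and density, and returns the model frame together with the fixed
#' formula implied by the specification. Cell-means coding is used for the
#' age terms, so the fixed column count plus the random-parameter count
#' reproduces the model's total parameter count n.p.
#'
#' @param records `pheno_data` tibble.
#' @param env Environment table from [simulate_environment()]; required only
#'   when the spec contains environmental terms.
#' @param spec A [model_spec()].
#' @return List with `frame` (model frame tibble), `fixed` (one-sided fixed
#'   formula), `formula` (full mixed-model formula), `n_fixed`, `n_params`
#'   and `spec`.
#' @export
build_design <- function(records, env = NULL, spec = model_spec("intercept")) {
  stopifnot(inherits(spec, "pheno_spec"))
  need_env <- any(c("SAM", "SOI", "N", "trend") %in% spec$terms)
  d <- tibble::as_tibble(records)
  d$moult_z <- zstd(d$moult)
  d$wean_z <- zstd(d$wean)
  d$cell <- assign_age_state_cell(d$age, d$state)
  d$cell <- droplevels(d$cell)
  d$age_f <- factor(pmin(d$age, 21L))
  d$state <- factor(d$state, levels = c("first", "experienced"))
  if (need_env) {
    if (is.null(env)) stop("spec needs an environment table", call. = FALSE)
    missing_years <- setdiff(unique(d$year), env$year)
    if (length(missing_years) > 0) {
      stop("years absent from environment table: ",
           paste(missing_years, collapse = ", "), call. = FALSE)
    }
    d <- dplyr::left_join(d, env, by = "year")
    for (v in intersect(c("SAM", "SOI", "density"), names(env))) {
      d <- within_subject_centre(d, v)
    }
  }

  fx <- character()
  for (term in spec$terms) {
    fx <- c(fx, switch(
      term,
      "age*state" = "0 + cell",
      "age" = "0 + age_f",
      "state" = "state",
      "moult" = "moult_z",
      "wean" = "wean_z",
      "SAM" = c("SAM_b", "SAM_w"),
      "SOI" = c("SOI_b", "SOI_w"),
      "N" = c("density_b", "density_w"),
      "trend" = "trend",
      "intercept" = "1"
    ))
  }
  fixed <- paste(unique(fx), collapse = " + ")
  re_female <- if (spec$random_slope) "(moult_z | female_id)" else
    "(1 | female_id)"
  re <- if (isFALSE(spec$year_effect)) re_female else
    paste("(1 | year) +", re_female)
  full <- paste("arrival ~", fixed, "+", re)
  list(frame = d,
       fixed = as.formula(paste("~", fixed)),
       formula = as.formula(full),
       n_fixed = spec$n_fixed,
       n_params = spec$n_params,
       spec = spec)
}

#' The twelve candidate fixed-effect structures of the Marion Island
#' arrival-date analysis
#'
#' @param random_slope Include the female moult-date random slope in every
#'   spec (the structure retained after the random-slope test).
#' @return Named list of [model_spec()] objects, in the reported ranking
#'   order.
#' @export
marion_models <- function(random_slope = TRUE) {
  tt <- list(
    c("age*state", "moult", "wean"),
    c("age*state", "moult", "wean", "SOI", "N", "trend"),
    c("age*state", "moult", "wean", "SAM", "SOI", "trend"),
    c("age*state", "moult", "wean", "SAM", "SOI", "N"),
    c("age*state", "moult", "wean", "SAM", "N", "trend"),
    c("age*state", "moult", "wean", "SAM", "SOI", "N", "trend"),
    c("age", "moult", "wean", "SAM", "SOI", "N", "trend"),
    c("state", "moult", "wean", "SAM", "SOI", "N", "trend"),
    c("moult", "wean", "SAM", "SOI", "N", "trend"),
    c("age*state", "moult", "SAM", "SOI", "N", "trend"),
    c("age*state", "wean", "SAM", "SOI", "N", "trend"),
    "intercept"
  )
  specs <- lapply(tt, model_spec, random_slope = random_slope)
  names(specs) <- vapply(specs, function(s) s$label, character(1))
  specs
}

#' Reference model-selection table for the Marion Island analysis
#'
#' The fixed-effect structures with their reported parameter counts,
#' delta-AIC values and ML deviances from the long-term Marion Island
#' elephant seal arrival-date analysis (1772 females, 5297 records). Used
#' for design and AIC bookkeeping checks; these are reported values, not
#' quantities this package recomputes from data.
#'
#' @return Tibble with columns `label`, `n_params`, `delta_aic`, `deviance`.
#' @export
marion_model_table <- function() {
  specs <- marion_models()
  tibble::tibble(
    label = names(specs),
    n_params = c(30L, 35L, 35L, 36L, 35L, 37L, 33L, 16L, 15L, 36L, 36L, 6L),
    delta_aic = c(0, 4.30, 4.73, 6.56, 7.91, 8.17, 13.98, 18.97, 34.04,
                  47.42, 161.07, 325.72),
    deviance = c(37483.20, 37477.50, 37477.93, 37477.76, 37481.11, 37477.37,
                 37491.18, 37530.17, 37547.24, 37518.62, 37632.27, 37856.92)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
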