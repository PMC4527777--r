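#' Validate a baseline scenario table
#'
#' A baseline scenario gives, for each of the 70 strata, the expected number
#' of CHD deaths per year under no change in trans-fat intake (typically a
#' forecast, so counts need not be integers) and the resident population.
#'
#' @param baseline A data frame with columns `age_band`, `sex`,
#'   `sec_quintile`, `expected_deaths`, `population`.
#' @return The validated baseline as a tibble (invisibly usable in pipes).
#' @details Validation enforces: all 70 strata present exactly once; counts
#'   finite and non-negative; `population > 0`; and
#'   `expected_deaths <= population` in every stratum. Failure messages name
#'   the offending stratum.
#' @examples
#' baseline <- generate_baseline(synthetic_spec(seed = 1))
#' validate_baseline(baseline)
#' @export
validate_baseline <- function(baseline) {
  baseline <- tibble::as_tibble(baseline)
  check_columns(baseline,
    c("age_band", "sex", "sec_quintile", "expected_deaths", "population"),
    what = "baseline")
  baseline$sec_quintile <- as.integer(baseline$sec_quintile)
  check_full_grid(baseline, what = "baseline")
  check_nonnegative(baseline, "expected_deaths", what = "baseline")
  check_nonnegative(baseline, "population", what = "baseline")
  bad <- baseline[baseline$population <= 0, , drop = FALSE]
  if (nrow(bad) > 0) {
    rlang::abort(
      paste0("baseline: population must be > 0; offending stratum: ",
             fmt_stratum(bad)[1]),
      class = "impacttfa_validation_error")
  }
  bad <- baseline[baseline$expected_deaths > baseline$population, , drop = FALSE]
  if (nrow(bad) > 0) {
    rlang::abort(
      paste0("baseline: expected_deaths exceeds population in stratum ",
             fmt_stratum(bad)[1]),
      class = "impacttfa_validation_error")
  }
  baseline
}

#' Read or write a baseline scenario CSV
#'
#' The CSV dialect is comma-separated UTF-8 with a mandatory header row and
#' age bands written with an ASCII hyphen (`"25-34"` ... `"85+"`). Columns:
#' `age_band, sex, sec_quintile, expected_deaths, population`. Quintile 1 is
#' the most affluent, quintile 5 the most deprived.
#'
#' @param path Path to the CSV file.
#' @param baseline A validated baseline tibble (see [validate_baseline()]).
#' @return `read_baseline()` returns the validated baseline tibble;
#'   `write_baseline()` returns `path` invisibly. Writing then reading is an
#'   identity on the table values.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' baseline <- generate_baseline(synthetic_spec(seed = 1))
#' write_baseline(baseline, tmp)
#' identical_back <- read_baseline(tmp)
#' @export
read_baseline <- function(path) {
  df <- read_model_csv(path, what = "baseline")
  validate_baseline(df)
}

#' @rdname read_baseline
#' @export
write_baseline <- function(baseline, path) {
  baseline <- validate_baseline(baseline)
  readr::write_csv(baseline, path)
  invisible(path)
}

#' Validate an incident-admissions baseline
#'
#' Admissions are modelled for the three incident patient groups only:
#' acute myocardial infarction (`AMI`), unstable angina (`UA`) and heart
#' failure (`HF`) admissions. Community-prevalence groups (angina in the
#' community, heart failure in the community, post-event survivors) are
#' rejected: the model holds case fatality constant, so prevalence pools do
#' not respond to the intervention.
#'
#' @param admissions A data frame with columns `age_band`, `sex`,
#'   `sec_quintile`, `disease_group`, `admissions` (70 strata x 3 groups =
#'   210 rows).
#' @return The validated admissions tibble.
#' @export
validate_admissions <- function(admissions) {
  admissions <- tibble::as_tibble(admissions)
  check_columns(admissions,
    c("age_band", "sex", "sec_quintile", "disease_group", "admissions"),
    what = "admissions")
  admissions$sec_quintile <- as.integer(admissions$sec_quintile)
  bad_group <- setdiff(unique(admissions$disease_group), disease_groups())
  if (length(bad_group) > 0) {
    rlang::abort(
      paste0("admissions: unknown disease_group '", bad_group[1],
             "'; only incident groups are modelled (",
             paste(disease_groups(), collapse = ", "),
             ") because case fatality is held constant"),
      class = "impacttfa_validation_error")
  }
  grid <- tidyr::expand_grid(stratum_grid(), disease_group = disease_groups())
  check_full_grid(admissions, grid = grid, what = "admissions")
  check_nonnegative(admissions, "admissions", what = "admissions")
  admissions
}

#' Read or write an incident-admissions CSV
#'
#' Columns: `age_band, sex, sec_quintile, disease_group, admissions`, with
#' `disease_group` one of `AMI`, `UA`, `HF` (incident groups only).
#'
#' @param path Path to the CSV file.
#' @param admissions A validated admissions tibble.
#' @return `read_admissions()` returns the validated 210-row tibble;
#'   `write_admissions()` returns `path` invisibly.
#' @export
read_admissions <- function(path) {
  df <- read_model_csv(path, what = "admissions")
  validate_admissions(df)
}

#' @rdname read_admissions
#' @export
write_admissions <- function(admissions, path) {
  admissions <- validate_admissions(admissions)
  readr::write_csv(admissions, path)
  invisible(path)
}

#' Construct and validate a survival table
#'
#' A survival table couples (i) median survival in years by age band and CHD
#' state (`diagnosed` CHD, `undiagnosed` CHD, `none` = free of CHD) and (ii)
#' a life-expectancy (LE) index per SEC quintile, anchored so that quintile 3
#' equals exactly 1.0. The LE index rescales survival of the `undiagnosed`
#' and `none` groups by deprivation; diagnosed-CHD survival is deliberately
#' not SEC-indexed (no stratified survival data exist for diagnosed
#' patients, a conservative choice that may understate the true gradient).
#'
#' @param median_survival Data frame with columns `age_band`, `chd_state`,
#'   `years`. The `undiagnosed` state may be omitted; when present it is
#'   checked against the ordering constraints but life-year computations
#'   always use the midpoint of `diagnosed` and `none`.
#' @param le_index Data frame with columns `sec_quintile`, `le_index`.
#' @return An object of class `tfa_survival`: a list with elements
#'   `median_survival` (tibble, all three states filled) and `le_index`
#'   (5-row tibble).
#' @details Invariants enforced: `le_index` equals 1.0 at quintile 3 exactly;
#'   median survival is positive and non-increasing with age within each
#'   state; `none >= diagnosed` within every age band.
#' @examples
#' surv <- generate_survival(synthetic_spec(seed = 1))
#' surv$le_index
#' @export
survival_table <- function(median_survival, le_index) {
  median_survival <- tibble::as_tibble(median_survival)
  check_columns(median_survival, c("age_band", "chd_state", "years"),
                what = "median_survival")
  le_index <- tibble::as_tibble(le_index)
  check_columns(le_index, c("sec_quintile", "le_index"), what = "le_index")
  le_index$sec_quintile <- as.integer(le_index$sec_quintile)

  bad_state <- setdiff(unique(median_survival$chd_state), chd_states())
  if (length(bad_state) > 0) {
    rlang::abort(paste0("survival: unknown chd_state '", bad_state[1], "'"),
                 class = "impacttfa_validation_error")
  }
  states <- intersect(chd_states(), unique(median_survival$chd_state))
  if (!all(c("diagnosed", "none") %in% states)) {
    rlang::abort("survival: states 'diagnosed' and 'none' are required",
                 class = "impacttfa_schema_error")
  }
  grid <- tidyr::expand_grid(age_band = age_bands(), chd_state = states)
  check_full_grid(median_survival, grid = grid, what = "survival")
  bad <- median_survival[!is.finite(median_survival$years) |
                           median_survival$years <= 0, , drop = FALSE]
  if (nrow(bad) > 0) {
    rlang::abort(
      paste0("survival: years must be positive; offending cell: (",
             bad$age_band[1], ", ", bad$chd_state[1], ")"),
      class = "impacttfa_validation_error")
  }

  wide <- tidyr::pivot_wider(median_survival,
                             names_from = "chd_state", values_from = "years")
  wide <- wide[match(age_bands(), wide$age_band), ]
  if (!("undiagnosed" %in% names(wide))) {
    wide$undiagnosed <- (wide$diagnosed + wide$none) / 2
  }
  bad <- wide[wide$diagnosed > wide$none, , drop = FALSE]
  if (nrow(bad) > 0) {
    rlang::abort(
      paste0("survival: diagnosed survival exceeds no-CHD survival in age band ",
             bad$age_band[1]),
      class = "impacttfa_validation_error")
  }
  for (st in chd_states()) {
    v <- wide[[st]]
    if (any(diff(v) > 1e-9)) {
      i <- which(diff(v) > 1e-9)[1]
      rlang::abort(
        paste0("survival: median survival for state '", st,
               "' increases with age between bands ", age_bands()[i],
               " and ", age_bands()[i + 1]),
        class = "impacttfa_validation_error")
    }
  }

  if (!setequal(le_index$sec_quintile, sec_quintiles()) ||
      nrow(le_index) != 5L) {
    rlang::abort("le_index: exactly one row per quintile 1..5 is required",
                 class = "impacttfa_schema_error")
  }
  le_index <- le_index[order(le_index$sec_quintile), ]
  if (any(!is.finite(le_index$le_index) | le_index$le_index <= 0)) {
    rlang::abort("le_index: indices must be positive",
                 class = "impacttfa_validation_error")
  }
  if (abs(le_index$le_index[le_index$sec_quintile == 3L] - 1) > 0) {
    rlang::abort(
      "le_index: quintile 3 must be the anchor, exactly 1.0",
      class = "impacttfa_validation_error")
  }

  out <- list(
    median_survival = tidyr::pivot_longer(wide, -"age_band",
                                          names_to = "chd_state",
                                          values_to = "years"),
    le_index = le_index
  )
  structure(out, class = "tfa_survival")
}

#' Read or write survival tables
#'
#' `read_survival()` reads two CSVs: the median-survival file (columns
#' `age_band, chd_state, years`) and the LE-index file (columns
#' `sec_quintile, le_index`), returning a validated [survival_table()].
#'
#' @param survival_path Path to the median-survival CSV.
#' @param le_index_path Path to the LE-index CSV.
#' @param survival A `tfa_survival` object.
#' @return `read_survival()` returns a `tfa_survival` object;
#'   `write_survival()` writes both files and returns their paths invisibly.
#' @export
read_survival <- function(survival_path, le_index_path) {
  ms <- read_model_csv(survival_path, what = "survival")
  le <- read_model_csv(le_index_path, what = "le_index")
  survival_table(ms, le)
}

#' @rdname read_survival
#' @export
write_survival <- function(survival, survival_path, le_index_path) {
  stopifnot(inherits(survival, "tfa_survival"))
  readr::write_csv(survival$median_survival, survival_path)
  readr::write_csv(survival$le_index, le_index_path)
  invisible(c(survival = survival_path, le_index = le_index_path))
}

#' @export
print.tfa_survival <- function(x, ...) {
  cat("<tfa_survival>\n")
  cat("Median survival (years) by age band and CHD state:\n")
  print(tidyr::pivot_wider(x$median_survival, names_from = "chd_state",
                           values_from = "years"), n = 7)
  cat("\nLife-expectancy index by SEC quintile (anchor: quintile 3 = 1.0):\n")
  print(x$le_index, n = 5)
  invisible(x)
}

read_model_csv <- function(path, what) {
  if (!file.exists(path)) {
    rlang::abort(paste0(what, ": file not found: ", path),
                 class = "impacttfa_schema_error")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      rlang::abort(paste0(what, ": cannot parse CSV at ", path, ": ",
                          conditionMessage(e)),
                   class = "impacttfa_schema_error")
    })
  if (nrow(df) == 0) {
    rlang::abort(paste0(what, ": file ", path, " has no data rows"),
                 class = "impacttfa_schema_error")
  }
  df
}
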