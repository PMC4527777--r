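#' Population strata used throughout the model
#'
#' The model population is stratified into 70 cells: seven ten-year age bands
#' (25-34 up to 85+), two sexes, and five socio-economic circumstance (SEC)
#' quintiles based on area deprivation scores. Quintile 1 is the most
#' affluent and quintile 5 the most deprived; this orientation matches the
#' observed gradient of trans-fat intake (highest in the most deprived
#' quintile) and is used consistently by every table in the package.
#'
#' @return `age_bands()` returns the seven fine age-band labels in order;
#'   `sexes()` the two sex labels; `sec_quintiles()` the integers 1:5;
#'   `stratum_grid()` a 70-row tibble with columns `age_band`, `sex`,
#'   `sec_quintile` enumerating every stratum exactly once.
#' @examples
#' age_bands()
#' nrow(stratum_grid())
#' @export
age_bands <- function() {
  c("25-34", "35-44", "45-54", "55-64", "65-74", "75-84", "85+")
}

#' @rdname age_bands
#' @export
sexes <- function() c("male", "female")

#' @rdname age_bands
#' @export
sec_quintiles <- function() 1:5

#' @rdname age_bands
#' @export
stratum_grid <- function() {
  tidyr::expand_grid(
    age_band = age_bands(),
    sex = sexes(),
    sec_quintile = sec_quintiles()
  )
}

#' Coarse age grouping for reporting
#'
#' Results are reported by three coarse bands: under 55, 55-74 and 75 and
#' over. The middle band is 55-74 inclusive (the bands 55-64 and 65-74); some
#' published table headers print "55-75" for the same grouping, which this
#' package does not follow.
#'
#' @return A tibble with columns `age_band` (fine band) and `coarse_band`
#'   (factor with levels `"<55"`, `"55-74"`, `">=75"`), one row per fine band.
#' @examples
#' age_grouping()
#' @export
age_grouping <- function() {
  tibble::tibble(
    age_band = age_bands(),
    coarse_band = factor(
      c("<55", "<55", "<55", "55-74", "55-74", ">=75", ">=75"),
      levels = c("<55", "55-74", ">=75")
    )
  )
}

#' @rdname age_grouping
#' @export
coarse_bands <- function() c("<55", "55-74", ">=75")

# Disease groups carried by the admissions tables. Only incident-event
# groups are in scope: the policy is assumed not to change case fatality, so
# community-prevalence groups (e.g. angina in the community) are excluded.
#' Incident disease groups in scope
#'
#' Hospital-admission effects are modelled for the three incident patient
#' groups only: acute myocardial infarction (AMI), unstable angina (UA) and
#' heart failure (HF) admissions. Community-prevalence groups are out of
#' scope because case fatality is held constant.
#'
#' @return Character vector `c("AMI", "UA", "HF")`.
#' @export
disease_groups <- function() c("AMI", "UA", "HF")

#' CHD states used for survival weighting
#'
#' Life-years gained weight each prevented death by the median survival of
#' the subgroup in which it was averted: people with diagnosed CHD,
#' symptomatic but undiagnosed CHD, or free of CHD.
#'
#' @return Character vector `c("diagnosed", "undiagnosed", "none")`.
#' @export
chd_states <- function() c("diagnosed", "undiagnosed", "none")

# --- internal validation helpers -------------------------------------------

fmt_stratum <- function(df) {
  paste0("(", df$age_band, ", ", df$sex, ", ", df$sec_quintile, ")")
}

# Checks that `df` contains every stratum of the 70-cell grid exactly once.
# Extra key columns (e.g. disease_group) can be handled by passing the
# expanded grid via `grid`.
check_full_grid <- function(df, grid = stratum_grid(), what = "table") {
  key_cols <- names(grid)
  missing <- dplyr::anti_join(grid, df, by = key_cols)
  if (nrow(missing) > 0) {
    rlang::abort(
      paste0(
        what, " is missing ", nrow(missing), " stratum/strata, e.g. ",
        paste(utils::head(fmt_stratum2(missing, key_cols), 3), collapse = ", ")
      ),
      class = "impacttfa_schema_error"
    )
  }
  dup <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(
      paste0(
        what, " has duplicated stratum/strata, e.g. ",
        paste(utils::head(fmt_stratum2(dup, key_cols), 3), collapse = ", ")
      ),
      class = "impacttfa_schema_error"
    )
  }
  unknown <- dplyr::anti_join(df, grid, by = key_cols)
  if (nrow(unknown) > 0) {
    rlang::abort(
      paste0(
        what, " has rows outside the stratum grid, e.g. ",
        paste(utils::head(fmt_stratum2(unknown, key_cols), 3), collapse = ", ")
      ),
      class = "impacttfa_schema_error"
    )
  }
  invisible(df)
}

fmt_stratum2 <- function(df, key_cols) {
  apply(df[key_cols], 1L, function(r) paste0("(", paste(r, collapse = ", "), ")"))
}

check_nonnegative <- function(df, col, what = "table") {
  bad <- df[!is.finite(df[[col]]) | df[[col]] < 0, , drop = FALSE]
  if (nrow(bad) > 0) {
    keys <- intersect(c("age_band", "sex", "sec_quintile", "disease_group"), names(bad))
    rlang::abort(
      paste0(
        what, ": column '", col, "' must be finite and non-negative; offending ",
        "stratum/strata: ",
        paste(utils::head(fmt_stratum2(bad, keys), 3), collapse = ", ")
      ),
      class = "impacttfa_validation_error"
    )
  }
  invisible(df)
}

check_columns <- function(df, cols, what = "file") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    rlang::abort(
      paste0(what, " is missing required column(s): ", paste(miss, collapse = ", ")),
      class = "impacttfa_schema_error"
    )
  }
  invisible(df)
}
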