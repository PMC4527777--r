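#' Adult age structure used for synthetic populations
#'
#' Fractions of the adult (25+) population in each ten-year age band,
#' loosely shaped like the England-and-Wales adult age pyramid. Shared by
#' the synthetic baseline generator and the default effect-table calibration
#' weights so the package has a single notion of population structure.
#'
#' @return Named numeric vector over [age_bands()], summing to 1.
#' @export
age_population_shares <- function() {
  c("25-34" = 0.19, "35-44" = 0.18, "45-54" = 0.18,
    "55-64" = 0.16, "65-74" = 0.14, "75-84" = 0.10, "85+" = 0.05)
}

#' Specification for a synthetic England-and-Wales-like baseline
#'
#' Describes the statistical structure the generator imposes: CHD mortality
#' rising exponentially with age, a male excess, a monotone deprivation
#' gradient in mortality, admissions proportional to deaths with
#' group-specific age shapes, and survival declining with age with the
#' diagnosed < undiagnosed < no-CHD ordering. Generation is deterministic
#' given the spec (the seed is recorded for provenance and stream
#' derivation); stochastic variation belongs to the sensitivity analysis,
#' not to the fixtures.
#'
#' @param seed Integer seed recorded with the dataset.
#' @param total_population Total adult population (default 35,000,000).
#' @param total_chd_deaths Expected CHD deaths per year over all strata
#'   (default 32,000, the order of magnitude of an England-and-Wales
#'   forecast year; illustrative, not a reproduction of any registry year).
#' @param age_mortality_doubling Years of age per doubling of the CHD death
#'   rate (default 7).
#' @param male_excess Male/female CHD death-rate ratio (default 1.8).
#' @param sec_mortality_ratio Quintile-5 / quintile-1 age-standardised CHD
#'   death-rate ratio (default 1.5); the gradient is log-linear across
#'   quintiles.
#' @param admission_multipliers Named vector `c(AMI=, UA=, HF=)`: incident
#'   admissions per CHD death for each disease group (defaults 0.65, 2.9,
#'   0.75, giving roughly 140,000 admissions per year at the default death
#'   count, with unstable angina the dominant group).
#' @param survival_anchors Named vector `c(diagnosed=, none=)`: median
#'   survival in years at the 65-74 reference band (defaults 9 and 15).
#' @param le_gradient Span of the life-expectancy index across quintiles
#'   (quintile 1 minus quintile 5; default 0.16, giving indices
#'   1.08 ... 0.92 linearly, anchored at 1.0 for quintile 3).
#' @return A list of class `tfa_synth_spec`.
#' @examples
#' spec <- synthetic_spec(seed = 1)
#' baseline <- generate_baseline(spec)
#' @export
synthetic_spec <- function(seed = 1L,
                           total_population = 35e6,
                           total_chd_deaths = 32000,
                           age_mortality_doubling = 7,
                           male_excess = 1.8,
                           sec_mortality_ratio = 1.5,
                           admission_multipliers = c(AMI = 0.65, UA = 2.9, HF = 0.75),
                           survival_anchors = c(diagnosed = 9, none = 15),
                           le_gradient = 0.16) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (total_chd_deaths >= total_population) {
    rlang::abort("total_chd_deaths must be smaller than total_population",
                 class = "impacttfa_validation_error")
  }
  if (age_mortality_doubling <= 0 || male_excess <= 0 ||
      sec_mortality_ratio <= 0) {
    rlang::abort("rates and ratios in the synthetic spec must be positive",
                 class = "impacttfa_validation_error")
  }
  if (!all(disease_groups() %in% names(admission_multipliers))) {
    rlang::abort("admission_multipliers must be named AMI, UA, HF",
                 class = "impacttfa_validation_error")
  }
  if (any(admission_multipliers < 0)) {
    rlang::abort("admission_multipliers must be non-negative",
                 class = "impacttfa_validation_error")
  }
  if (!all(c("diagnosed", "none") %in% names(survival_anchors)) ||
      any(survival_anchors <= 0)) {
    rlang::abort("survival_anchors must give positive years for diagnosed and none",
                 class = "impacttfa_validation_error")
  }
  if (survival_anchors[["diagnosed"]] > survival_anchors[["none"]]) {
    rlang::abort(
      "survival_anchors violate state ordering: diagnosed must not exceed no-CHD survival",
      class = "impacttfa_validation_error")
  }
  if (le_gradient < 0 || le_gradient >= 1) {
    rlang::abort("le_gradient must lie in [0, 1)",
                 class = "impacttfa_validation_error")
  }
  structure(
    list(seed = as.integer(seed),
         total_population = total_population,
         total_chd_deaths = total_chd_deaths,
         age_mortality_doubling = age_mortality_doubling,
         male_excess = male_excess,
         sec_mortality_ratio = sec_mortality_ratio,
         admission_multipliers = admission_multipliers[disease_groups()],
         survival_anchors = survival_anchors,
         le_gradient = le_gradient),
    class = "tfa_synth_spec")
}

# Linear LE index across quintiles, anchored at 1.0 for quintile 3.
synth_le_index <- function(le_gradient) {
  1 + (3 - sec_quintiles()) * le_gradient / 4
}

# Relative survival profile by age band, 65-74 = 1. Applied to both CHD
# states so the none >= diagnosed ordering of the anchors is preserved.
synth_survival_profile <- function() {
  c("25-34" = 3.2, "35-44" = 2.7, "45-54" = 2.1, "55-64" = 1.55,
    "65-74" = 1.0, "75-84" = 0.55, "85+" = 0.28)
}

# Largest-remainder apportionment of `total` (integer) proportional to x.
largest_remainder <- function(x, total) {
  if (sum(x) == 0) return(rep(0, length(x)))
  quota <- x / sum(x) * total
  fl <- floor(quota)
  rem <- round(total - sum(fl))
  add <- rep(0, length(x))
  if (rem > 0) {
    idx <- order(-(quota - fl), seq_along(x))[seq_len(rem)]
    add[idx] <- 1
  }
  fl + add
}

#' Generate a synthetic baseline scenario
#'
#' Deterministically constructs a 70-stratum baseline whose death rates
#' double every `age_mortality_doubling` years of age, exceed in men by
#' `male_excess`, and follow a log-linear deprivation gradient reaching
#' `sec_mortality_ratio` between quintiles 5 and 1. Populations follow the
#' package age structure with a mild female excess at old ages and thinner
#' deprived quintiles in the oldest bands (shorter life expectancy).
#' Stratum death counts are integers summing exactly to
#' `total_chd_deaths` via largest-remainder apportionment.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated baseline tibble (70 rows), with the spec attached as
#'   attribute `"synth_spec"`.
#' @export
generate_baseline <- function(spec) {
  stopifnot(inherits(spec, "tfa_synth_spec"))
  grid <- stratum_grid()
  ai <- match(grid$age_band, age_bands())
  qi <- grid$sec_quintile
  mid_age <- c(29.5, 39.5, 49.5, 59.5, 69.5, 79.5, 90)[ai]

  # population: age shares, female excess at old ages, deprived quintiles
  # thinner in the oldest bands
  female_share <- c(0.50, 0.50, 0.50, 0.51, 0.52, 0.55, 0.62)[ai]
  sex_share <- ifelse(grid$sex == "female", female_share, 1 - female_share)
  li <- synth_le_index(spec$le_gradient)
  old_exponent <- pmax(ai - 5L, 0L)            # 0 below 75, 1 for 75-84, 2 for 85+
  q_weight_raw <- li[qi]^old_exponent
  q_norm <- stats::ave(q_weight_raw, paste(grid$age_band, grid$sex), FUN = sum)
  pop_raw <- age_population_shares()[ai] * sex_share * q_weight_raw / q_norm
  population <- largest_remainder(pop_raw, spec$total_population)

  # death rates: exponential in age, male excess, log-linear SEC gradient
  rate <- 2^(mid_age / spec$age_mortality_doubling) *
    ifelse(grid$sex == "male", spec$male_excess, 1) *
    spec$sec_mortality_ratio^((qi - 1) / 4)
  deaths_raw <- population * rate
  expected_deaths <- largest_remainder(deaths_raw, spec$total_chd_deaths)

  if (any(expected_deaths > population)) {
    bad <- which(expected_deaths > population)[1]
    rlang::abort(
      paste0("infeasible synthetic spec: deaths exceed population in stratum ",
             fmt_stratum(grid[bad, ])),
      class = "impacttfa_validation_error")
  }
  out <- dplyr::mutate(grid,
                       expected_deaths = as.numeric(expected_deaths),
                       population = as.numeric(population))
  out <- validate_baseline(out)
  attr(out, "synth_spec") <- spec
  out
}

#' Generate synthetic incident admissions
#'
#' Admissions per stratum are proportional to that stratum's expected
#' deaths, scaled so each disease group's total equals
#' `admission_multipliers[group] * total deaths`, with age-shape
#' adjustments: AMI and unstable angina peak in middle age, heart failure
#' in old age. Counts are integer via largest-remainder apportionment per
#' group.
#'
#' @param spec The [synthetic_spec()] used for the baseline.
#' @param baseline The baseline generated from the same spec.
#' @return A validated 210-row admissions tibble.
#' @export
generate_admissions <- function(spec, baseline) {
  stopifnot(inherits(spec, "tfa_synth_spec"))
  baseline <- validate_baseline(baseline)
  grid <- stratum_grid()
  ord <- dplyr::left_join(grid, baseline,
                          by = c("age_band", "sex", "sec_quintile"))
  ai <- match(grid$age_band, age_bands())
  shapes <- list(
    AMI = c(0.6, 0.8, 1.1, 1.3, 1.2, 1.0, 0.7),
    UA  = c(0.5, 0.9, 1.3, 1.5, 1.3, 0.9, 0.5),
    HF  = c(0.10, 0.20, 0.35, 0.60, 1.00, 1.60, 2.00)
  )
  total_deaths <- sum(ord$expected_deaths)
  purrr::map_dfr(disease_groups(), function(g) {
    raw <- ord$expected_deaths * shapes[[g]][ai]
    target <- round(total_deaths * spec$admission_multipliers[[g]])
    dplyr::mutate(grid, disease_group = g,
                  admissions = as.numeric(largest_remainder(raw, target)))
  }) |>
    validate_admissions()
}

#' Generate a synthetic survival table
#'
#' Median survival declines with age following a fixed relative profile
#' applied to the 65-74 anchors for the diagnosed-CHD and no-CHD states;
#' undiagnosed-CHD survival is the midpoint of the two. The
#' life-expectancy index is linear across quintiles with span
#' `le_gradient`, anchored at exactly 1.0 for quintile 3.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `tfa_survival` object.
#' @export
generate_survival <- function(spec) {
  stopifnot(inherits(spec, "tfa_synth_spec"))
  prof <- synth_survival_profile()
  diag_y <- spec$survival_anchors[["diagnosed"]] * prof
  none_y <- spec$survival_anchors[["none"]] * prof
  ms <- tibble::tibble(
    age_band = rep(age_bands(), 3L),
    chd_state = rep(chd_states(), each = 7L),
    years = unname(c(diag_y, (diag_y + none_y) / 2, none_y))
  )
  le <- tibble::tibble(sec_quintile = sec_quintiles(),
                       le_index = synth_le_index(spec$le_gradient))
  survival_table(ms, le)
}

#' Age-sex-standardised SEC mortality gradient of a baseline
#'
#' Recomputes, from a baseline table alone, the deprivation gradient in CHD
#' mortality: each quintile's death rate per age-sex cell is weighted by the
#' overall (all-quintile) age-sex population structure, yielding directly
#' standardised rates whose quintile-5 / quintile-1 ratio summarises the
#' gradient. Used to verify that generated baselines carry the configured
#' gradient.
#'
#' @param baseline A validated baseline tibble.
#' @return A list with `rates` (tibble `sec_quintile, std_rate`) and
#'   `ratio_q5_q1` (scalar).
#' @examples
#' baseline <- generate_baseline(synthetic_spec(sec_mortality_ratio = 1.5))
#' standardised_sec_ratio(baseline)$ratio_q5_q1
#' @export
standardised_sec_ratio <- function(baseline) {
  baseline <- validate_baseline(baseline)
  std <- baseline |>
    dplyr::summarise(weight = sum(.data$population), .by = c("age_band", "sex"))
  std$weight <- std$weight / sum(std$weight)
  rates <- baseline |>
    dplyr::mutate(rate = .data$expected_deaths / .data$population) |>
    dplyr::left_join(std, by = c("age_band", "sex")) |>
    dplyr::summarise(std_rate = sum(.data$rate * .data$weight),
                     .by = "sec_quintile") |>
    dplyr::arrange(.data$sec_quintile)
  list(rates = rates,
       ratio_q5_q1 = rates$std_rate[5] / rates$std_rate[1])
}

#' Write a complete synthetic dataset to disk
#'
#' Writes `baseline.csv`, `admissions.csv`, `survival.csv`, `le_index.csv`
#' and a `provenance.json` echo of the generating spec into `dir`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "tfa_synth_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  baseline <- generate_baseline(spec)
  admissions <- generate_admissions(spec, baseline)
  survival <- generate_survival(spec)
  paths <- c(baseline = file.path(dir, "baseline.csv"),
             admissions = file.path(dir, "admissions.csv"),
             survival = file.path(dir, "survival.csv"),
             le_index = file.path(dir, "le_index.csv"),
             provenance = file.path(dir, "provenance.json"))
  write_baseline(baseline, paths[["baseline"]])
  write_admissions(admissions, paths[["admissions"]])
  write_survival(survival, paths[["survival"]], paths[["le_index"]])
  jsonlite::write_json(unclass(spec), paths[["provenance"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
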