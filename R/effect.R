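#' Construct and validate a mortality-reduction effect table
#'
#' The effect table holds, per age band and sex, the relative reduction in
#' CHD mortality produced by a trans-fat intake reduction of 1% of daily
#' energy (`mrf_1pct`, a dimensionless fraction). The effect attenuates with
#' age, mirroring the age gradient observed for cholesterol-related CHD
#' mortality effects. Sensitivity bounds `mrf_low` / `mrf_high` are fixed at
#' 80% and 120% of the central estimate and are always rebuilt by the
#' constructor; externally supplied bounds are checked for consistency.
#'
#' @param mrf A data frame with columns `age_band`, `sex`, `mrf_1pct` and
#'   optionally `mrf_low`, `mrf_high`. Either all seven age bands or the six
#'   bands below 85+ (pending [extrapolate_oldest_band()]) must be present
#'   for both sexes.
#' @return A tibble of class `tfa_effect` with columns `age_band`, `sex`,
#'   `mrf_1pct`, `mrf_low`, `mrf_high`, ordered by sex then age band.
#' @details Invariants enforced: `0 <= 0.8 * mrf_1pct = mrf_low <= mrf_1pct
#'   <= mrf_high = 1.2 * mrf_1pct < 1`, and `mrf_1pct` non-increasing with
#'   age within each sex.
#' @examples
#' eff <- build_default_effect_table()
#' eff
#' @export
effect_table <- function(mrf) {
  mrf <- tibble::as_tibble(mrf)
  check_columns(mrf, c("age_band", "sex", "mrf_1pct"), what = "effect table")

  bands_present <- unique(mrf$age_band)
  if (setequal(bands_present, age_bands())) {
    bands <- age_bands()
  } else if (setequal(bands_present, utils::head(age_bands(), 6L))) {
    bands <- utils::head(age_bands(), 6L)
  } else {
    rlang::abort(
      "effect table must cover all seven age bands, or the six bands below 85+",
      class = "impacttfa_schema_error")
  }
  grid <- tidyr::expand_grid(age_band = bands, sex = sexes())
  check_full_grid(mrf, grid = grid, what = "effect table")

  if (any(!is.finite(mrf$mrf_1pct) | mrf$mrf_1pct < 0 |
            mrf$mrf_1pct * 1.2 >= 1)) {
    rlang::abort(
      "effect table: mrf_1pct must lie in [0, 1) with its 120% bound below 1",
      class = "impacttfa_validation_error")
  }
  if (all(c("mrf_low", "mrf_high") %in% names(mrf))) {
    if (any(abs(mrf$mrf_low - 0.8 * mrf$mrf_1pct) > 1e-9) ||
        any(abs(mrf$mrf_high - 1.2 * mrf$mrf_1pct) > 1e-9)) {
      rlang::abort(
        "effect table: bounds must equal 80% and 120% of mrf_1pct",
        class = "impacttfa_validation_error")
    }
  }

  out <- tidyr::expand_grid(sex = sexes(), age_band = bands) |>
    dplyr::left_join(mrf[c("age_band", "sex", "mrf_1pct")],
                     by = c("age_band", "sex")) |>
    dplyr::mutate(mrf_1pct = unname(.data$mrf_1pct),
                  mrf_low = 0.8 * .data$mrf_1pct,
                  mrf_high = 1.2 * .data$mrf_1pct) |>
    dplyr::relocate("age_band", "sex")

  for (sx in sexes()) {
    v <- out$mrf_1pct[out$sex == sx]
    if (any(diff(v) > 1e-12)) {
      i <- which(diff(v) > 1e-12)[1]
      rlang::abort(
        paste0("effect table: mrf_1pct increases with age for sex '", sx,
               "' between bands ", bands[i], " and ", bands[i + 1],
               " (attenuation with age required)"),
        class = "impacttfa_validation_error")
    }
  }
  class(out) <- c("tfa_effect", class(out))
  out
}

#' Default age-attenuation schedule and population weights
#'
#' The default effect table is parametric: a population-average anchor (12%
#' mortality reduction per 1% of daily energy) spread over age bands by a
#' relative attenuation schedule, identical for both sexes. The schedule
#' below is a package default chosen to decline smoothly with age in the way
#' relative risks for cholesterol-mediated CHD mortality do; any externally
#' estimated table with the same schema overrides it.
#'
#' @return `default_attenuation_schedule()`: a named numeric vector of
#'   relative multipliers over the six age bands below 85+ (the 85+ value is
#'   produced by geometric continuation). `default_population_weights()`: a
#'   tibble `age_band, sex, weight` summing to 1, derived from the synthetic
#'   population age structure with an even sex split.
#' @export
default_attenuation_schedule <- function() {
  c("25-34" = 1.45, "35-44" = 1.35, "45-54" = 1.20,
    "55-64" = 1.05, "65-74" = 0.90, "75-84" = 0.70)
}

#' @rdname default_attenuation_schedule
#' @export
default_population_weights <- function() {
  shares <- age_population_shares()
  tidyr::expand_grid(age_band = age_bands(), sex = sexes()) |>
    dplyr::mutate(weight = shares[.data$age_band] / 2)
}

#' Build the default mortality-reduction effect table
#'
#' Anchors the table so that its population-weighted mean `mrf_1pct` equals
#' `base_reduction` (default 0.12: a 1% of daily energy reduction in
#' trans-fat intake reduces CHD mortality by 12% on average), then spreads
#' the effect over age bands by the attenuation schedule. A six-band
#' schedule is extended to 85+ by geometric continuation of the attenuation
#' ratio before calibration, so the weighted mean holds over the full table.
#'
#' @param base_reduction Population-average mortality reduction per 1% TFA
#'   energy reduction, a fraction in (0, 1). Default `0.12`.
#' @param attenuation_schedule Named positive multipliers per age band,
#'   non-increasing with age; length 6 (85+ extended geometrically) or 7.
#' @param population_weights Tibble `age_band, sex, weight`; weights must be
#'   non-negative and sum to 1.
#' @return A `tfa_effect` table whose population-weighted mean `mrf_1pct`
#'   equals `base_reduction` to within 1e-12.
#' @examples
#' eff <- build_default_effect_table()
#' w <- default_population_weights()
#' sum(dplyr::inner_join(eff, w, by = c("age_band", "sex"))$mrf_1pct *
#'     dplyr::inner_join(eff, w, by = c("age_band", "sex"))$weight)  # 0.12
#' @export
build_default_effect_table <- function(base_reduction = 0.12,
                                       attenuation_schedule = default_attenuation_schedule(),
                                       population_weights = default_population_weights()) {
  if (!is.numeric(base_reduction) || length(base_reduction) != 1 ||
      base_reduction <= 0 || base_reduction >= 1) {
    rlang::abort("base_reduction must be a fraction in (0, 1)",
                 class = "impacttfa_validation_error")
  }
  sched <- attenuation_schedule
  if (is.null(names(sched)) ||
      !(setequal(names(sched), age_bands()) ||
        setequal(names(sched), utils::head(age_bands(), 6L)))) {
    rlang::abort(
      "attenuation_schedule must be named by the age bands (6 bands below 85+, or all 7)",
      class = "impacttfa_validation_error")
  }
  if (any(!is.finite(sched) | sched <= 0)) {
    rlang::abort("attenuation_schedule multipliers must be positive",
                 class = "impacttfa_validation_error")
  }
  sched <- sched[intersect(age_bands(), names(sched))]
  if (any(diff(sched) > 1e-12)) {
    rlang::abort("attenuation_schedule must be non-increasing with age",
                 class = "impacttfa_validation_error")
  }
  if (length(sched) == 6L) {
    # geometric continuation of the last attenuation ratio into 85+
    r <- sched[["75-84"]] / sched[["65-74"]]
    sched <- c(sched, "85+" = unname(sched[["75-84"]] * r))
  }

  w <- tibble::as_tibble(population_weights)
  check_columns(w, c("age_band", "sex", "weight"), what = "population_weights")
  check_full_grid(w, grid = tidyr::expand_grid(age_band = age_bands(),
                                               sex = sexes()),
                  what = "population_weights")
  if (any(w$weight < 0) || abs(sum(w$weight) - 1) > 1e-9) {
    rlang::abort("population_weights must be non-negative and sum to 1",
                 class = "impacttfa_validation_error")
  }

  wmean_sched <- sum(w$weight * sched[w$age_band])
  if (wmean_sched <= 0) {
    rlang::abort(
      "population_weights put no mass on the schedule; weighted mean undefined",
      class = "impacttfa_validation_error")
  }
  scale <- base_reduction / wmean_sched
  effect_table(
    tidyr::expand_grid(age_band = age_bands(), sex = sexes()) |>
      dplyr::mutate(mrf_1pct = scale * sched[.data$age_band])
  )
}

#' Extrapolate the 85+ mortality-reduction factor
#'
#' Meta-analytic effect estimates rarely cover the oldest old, so the 85+
#' cell is extrapolated from the two preceding bands by continuing the
#' attenuation of the relative risk with age. The default continues the
#' geometric ratio: `mrf(85+) = mrf(75-84) * mrf(75-84) / mrf(65-74)` per
#' sex, which carries forward a constant proportional attenuation. A linear
#' continuation (`2 * mrf(75-84) - mrf(65-74)`, clamped at 0) is available
#' for audit.
#'
#' @param effect A `tfa_effect` table without an 85+ row.
#' @param method `"geometric"` (default) or `"linear"`.
#' @return A full seven-band `tfa_effect` table, bounds rebuilt at 80%/120%.
#' @examples
#' six <- build_default_effect_table()
#' six <- effect_table(dplyr::filter(six, age_band != "85+"))
#' full <- extrapolate_oldest_band(six)
#' @export
extrapolate_oldest_band <- function(effect, method = c("geometric", "linear")) {
  method <- rlang::arg_match(method)
  effect <- effect_table(effect)
  if ("85+" %in% effect$age_band) {
    rlang::abort("effect table already has an 85+ row",
                 class = "impacttfa_validation_error")
  }
  need <- c("65-74", "75-84")
  if (!all(need %in% effect$age_band)) {
    rlang::abort("extrapolation requires rows for 65-74 and 75-84",
                 class = "impacttfa_schema_error")
  }
  oldest <- purrr::map_dfr(sexes(), function(sx) {
    m65 <- effect$mrf_1pct[effect$age_band == "65-74" & effect$sex == sx]
    m75 <- effect$mrf_1pct[effect$age_band == "75-84" & effect$sex == sx]
    m85 <- if (method == "geometric") {
      if (m65 == 0 && m75 > 0) {
        rlang::abort(
          paste0("attenuation ratio undefined for sex '", sx,
                 "': mrf(65-74) = 0 with mrf(75-84) > 0"),
          class = "impacttfa_validation_error")
      }
      if (m75 == 0) 0 else m75 * (m75 / m65)
    } else {
      max(2 * m75 - m65, 0)
    }
    tibble::tibble(age_band = "85+", sex = sx, mrf_1pct = m85)
  })
  effect_table(dplyr::bind_rows(
    effect[c("age_band", "sex", "mrf_1pct")], oldest))
}

#' Scale the effect table to a given intake reduction
#'
#' The model assumes a linear dose-response between trans-fat intake and CHD
#' mortality risk: the mortality reduction for an intake reduction of
#' `delta` percent of daily energy is `delta * mrf_1pct` in every cell,
#' capped at 1 (a prevented-death fraction cannot exceed all expected
#' deaths). Intake increases are outside the model's scope.
#'
#' @param effect A `tfa_effect` table.
#' @param delta Intake reduction in percent of daily energy, `>= 0`.
#' @return A tibble `age_band, sex, mrf, mrf_low, mrf_high` with the scaled
#'   factors (central and sensitivity bounds).
#' @examples
#' eff <- build_default_effect_table()
#' half <- scale_effect(eff, 0.5)   # exactly half the 1% factors
#' @export
scale_effect <- function(effect, delta) {
  effect <- effect_table(effect)
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) ||
      delta < 0) {
    rlang::abort(
      "delta must be a single non-negative intake reduction (% daily energy); increases are out of scope",
      class = "impacttfa_validation_error")
  }
  tibble::tibble(
    age_band = effect$age_band,
    sex = effect$sex,
    mrf = pmin(delta * effect$mrf_1pct, 1),
    mrf_low = pmin(delta * effect$mrf_low, 1),
    mrf_high = pmin(delta * effect$mrf_high, 1)
  )
}

#' Build a trans-fat intake scenario by SEC quintile
#'
#' Two stock scenarios reflect how baseline trans-fat intake is distributed
#' over deprivation quintiles:
#' \describe{
#'   \item{`TFAsec1_equal`}{conservative: every quintile consumes the UK
#'     population mean, 1.3% of daily energy.}
#'   \item{`TFAsec2_unequal`}{survey-based gradient: quintile 1 (most
#'     affluent) 0.75%, then 0.87%, 1.0%, 1.25%, and 1.5% in quintile 5
#'     (most deprived), reflecting the higher intake of processed foods in
#'     deprived groups.}
#' }
#' The per-quintile reduction is `delta = max(baseline - target, 0)`:
#' quintiles already below the target see no change.
#'
#' @param kind One of `"TFAsec1_equal"`, `"TFAsec2_unequal"`, `"custom"`.
#' @param target_intake Post-policy intake, % of daily energy, `>= 0`.
#'   Default 0 (full elimination).
#' @param baseline_intake Optional numeric vector of length 5 (quintiles
#'   1..5) overriding the stock baselines; required when `kind = "custom"`.
#' @param equal_baseline Common baseline used by the equal scenario
#'   (default 1.3).
#' @return A tibble of class `tfa_scenario` with columns `name`,
#'   `sec_quintile`, `baseline_intake`, `target_intake`, `delta`.
#' @examples
#' build_intake_scenario("TFAsec2_unequal", target_intake = 0.5)
#' @export
build_intake_scenario <- function(kind = c("TFAsec1_equal", "TFAsec2_unequal",
                                           "custom"),
                                  target_intake = 0,
                                  baseline_intake = NULL,
                                  equal_baseline = 1.3) {
  kind <- rlang::arg_match(kind)
  if (!is.numeric(target_intake) || length(target_intake) != 1 ||
      !is.finite(target_intake) || target_intake < 0) {
    rlang::abort("target_intake must be a single non-negative % of daily energy",
                 class = "impacttfa_validation_error")
  }
  baseline <- switch(kind,
    TFAsec1_equal = rep(equal_baseline, 5L),
    TFAsec2_unequal = c(0.75, 0.87, 1.0, 1.25, 1.5),
    custom = baseline_intake
  )
  if (kind == "custom") {
    if (is.null(baseline) || length(baseline) != 5L ||
        any(!is.finite(baseline)) || any(baseline < 0)) {
      rlang::abort(
        "custom scenario requires baseline_intake with one non-negative value per quintile 1..5",
        class = "impacttfa_validation_error")
    }
  }
  out <- tibble::tibble(
    name = kind,
    sec_quintile = sec_quintiles(),
    baseline_intake = baseline,
    target_intake = target_intake,
    delta = pmax(baseline - target_intake, 0)
  )
  class(out) <- c("tfa_scenario", class(out))
  out
}

#' A uniform intake-reduction scenario
#'
#' Convenience wrapper for "every quintile reduces intake by `reduction`
#' percent of daily energy": an equal-intake scenario whose target is the
#' common baseline minus the reduction.
#'
#' @param reduction Reduction in % of daily energy, between 0 and
#'   `equal_baseline`.
#' @inheritParams build_intake_scenario
#' @return A `tfa_scenario` tibble with `delta = reduction` in every
#'   quintile.
#' @examples
#' uniform_reduction_scenario(1.0)
#' @export
uniform_reduction_scenario <- function(reduction, equal_baseline = 1.3) {
  if (!is.numeric(reduction) || length(reduction) != 1 ||
      !is.finite(reduction) || reduction < 0 || reduction > equal_baseline) {
    rlang::abort("reduction must lie between 0 and the common baseline intake",
                 class = "impacttfa_validation_error")
  }
  build_intake_scenario("TFAsec1_equal",
                        target_intake = equal_baseline - reduction,
                        equal_baseline = equal_baseline)
}

validate_scenario <- function(scenario) {
  scenario <- tibble::as_tibble(scenario)
  check_columns(scenario, c("sec_quintile", "delta"), what = "scenario")
  scenario$sec_quintile <- as.integer(scenario$sec_quintile)
  if (!setequal(scenario$sec_quintile, sec_quintiles()) ||
      nrow(scenario) != 5L) {
    rlang::abort("scenario must define delta for each quintile 1..5 exactly once",
                 class = "impacttfa_schema_error")
  }
  if (any(!is.finite(scenario$delta) | scenario$delta < 0)) {
    rlang::abort("scenario deltas must be non-negative",
                 class = "impacttfa_validation_error")
  }
  scenario[order(scenario$sec_quintile), ]
}
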