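#' Default apportionment of prevented deaths over CHD states
#'
#' Published sources do not state how deaths averted by an intake reduction
#' split across people with diagnosed CHD, undiagnosed CHD, and no CHD, yet
#' the split drives life-year weighting. The package therefore makes the
#' apportionment an explicit input. The default is a package fixture chosen
#' to be epidemiologically plausible: the diagnosed share rises with age
#' (prevalent disease accumulates), the undiagnosed share is roughly flat,
#' and the remainder are event deaths in people free of recognised CHD.
#' Sensitivity to this input should be explored by supplying alternatives.
#'
#' @return A tibble `age_band, chd_state, share` with shares in `[0, 1]`
#'   summing to 1 within each age band.
#' @examples
#' default_subgroup_shares()
#' @export
default_subgroup_shares <- function() {
  diagnosed <- c(0.30, 0.35, 0.42, 0.50, 0.57, 0.62, 0.65)
  undiagnosed <- c(0.25, 0.25, 0.25, 0.25, 0.24, 0.23, 0.22)
  tibble::tibble(
    age_band = rep(age_bands(), times = 3L),
    chd_state = rep(chd_states(), each = 7L),
    share = c(diagnosed, undiagnosed, 1 - diagnosed - undiagnosed)
  )
}

validate_shares <- function(shares) {
  shares <- tibble::as_tibble(shares)
  check_columns(shares, c("age_band", "chd_state", "share"), what = "shares")
  grid <- tidyr::expand_grid(age_band = age_bands(), chd_state = chd_states())
  check_full_grid(shares, grid = grid, what = "shares")
  if (any(!is.finite(shares$share) | shares$share < 0 | shares$share > 1)) {
    rlang::abort("shares must lie in [0, 1]",
                 class = "impacttfa_validation_error")
  }
  sums <- shares |>
    dplyr::summarise(s = sum(.data$share), .by = "age_band")
  bad <- sums[abs(sums$s - 1) > 1e-9, , drop = FALSE]
  if (nrow(bad) > 0) {
    rlang::abort(
      paste0("shares must sum to 1 within each age band; band ",
             bad$age_band[1], " sums to ", format(bad$s[1])),
      class = "impacttfa_validation_error")
  }
  shares
}

# --- internal aligned-vector core ------------------------------------------
# All outcome arithmetic runs through this context so the point pipeline and
# the Monte Carlo resampling are guaranteed to share one code path. Strata
# are aligned to stratum_grid() order; effect cells to (sex x age) order.

build_model_context <- function(baseline = NULL, admissions = NULL,
                                survival = NULL, effect = NULL,
                                scenario = NULL, shares = NULL) {
  grid <- stratum_grid()
  ctx <- list(grid = grid,
              ai = match(grid$age_band, age_bands()),
              qi = grid$sec_quintile,
              eff_key = paste(grid$sex, grid$age_band))

  if (!is.null(baseline)) {
    baseline <- validate_baseline(baseline)
    ord <- dplyr::left_join(grid, baseline,
                            by = c("age_band", "sex", "sec_quintile"))
    ctx$deaths <- ord$expected_deaths
    ctx$population <- ord$population
  }
  if (!is.null(admissions)) {
    admissions <- validate_admissions(admissions)
    wide <- tidyr::pivot_wider(admissions, names_from = "disease_group",
                               values_from = "admissions")
    wide <- dplyr::left_join(grid, wide,
                             by = c("age_band", "sex", "sec_quintile"))
    ctx$adm <- as.matrix(wide[disease_groups()])
  }
  if (!is.null(effect)) {
    effect <- effect_table(effect)
    if (!all(age_bands() %in% effect$age_band)) {
      rlang::abort(
        "effect table lacks the 85+ band required by the baseline strata; extrapolate_oldest_band() first",
        class = "impacttfa_schema_error")
    }
    ctx$mrf1 <- stats::setNames(effect$mrf_1pct,
                                paste(effect$sex, effect$age_band))
    ctx$eff_idx <- match(ctx$eff_key, names(ctx$mrf1))
  }
  if (!is.null(scenario)) {
    scenario <- validate_scenario(scenario)
    ctx$delta_q <- scenario$delta
  }
  if (!is.null(survival)) {
    stopifnot(inherits(survival, "tfa_survival"))
    wide <- tidyr::pivot_wider(survival$median_survival,
                               names_from = "chd_state", values_from = "years")
    wide <- wide[match(age_bands(), wide$age_band), ]
    ctx$surv_diag <- wide$diagnosed
    ctx$surv_none <- wide$none
    ctx$le_index <- survival$le_index$le_index
  }
  if (!is.null(shares)) {
    shares <- validate_shares(shares)
    sw <- tidyr::pivot_wider(shares, names_from = "chd_state",
                             values_from = "share")
    sw <- sw[match(age_bands(), sw$age_band), ]
    ctx$sh_diag <- sw$diagnosed
    ctx$sh_undiag <- sw$undiagnosed
    ctx$sh_none <- sw$none
  }
  ctx
}

# Per-stratum mortality-reduction fraction for the scenario deltas, given a
# vector of per-(sex, age) 1%-factors. Linear dose response, capped at 1.
core_mrf <- function(ctx, mrf1_cells) {
  unname(pmin(ctx$delta_q[ctx$qi] * mrf1_cells[ctx$eff_idx], 1))
}

# Effective survival (years) per stratum: share-weighted over CHD states.
# Undiagnosed survival is the diagnosed/none midpoint before indexing; the
# LE index scales the undiagnosed and no-CHD groups only.
core_effective_survival <- function(ctx, surv_diag, surv_none) {
  surv_undiag <- (surv_diag + surv_none) / 2
  li <- ctx$le_index[ctx$qi]
  ctx$sh_diag[ctx$ai] * surv_diag[ctx$ai] +
    li * (ctx$sh_undiag[ctx$ai] * surv_undiag[ctx$ai] +
            ctx$sh_none[ctx$ai] * surv_none[ctx$ai])
}

core_outcomes <- function(ctx, mrf1_cells = ctx$mrf1,
                          surv_diag = ctx$surv_diag,
                          surv_none = ctx$surv_none) {
  mrf_s <- core_mrf(ctx, mrf1_cells)
  dpp <- ctx$deaths * mrf_s
  out <- list(dpp = dpp)
  if (!is.null(ctx$adm)) {
    out$adm <- ctx$adm * mrf_s
  }
  if (!is.null(surv_diag)) {
    out$lyg <- dpp * core_effective_survival(ctx, surv_diag, surv_none)
  }
  out
}

# --- public per-stratum operations -----------------------------------------

#' Deaths prevented or postponed per stratum
#'
#' Applies the counterfactual: for each stratum, expected CHD deaths under
#' no change in intake are multiplied by the mortality-reduction fraction
#' implied by that stratum's quintile-specific intake reduction,
#' `dpp = expected_deaths * min(delta_q * mrf_1pct(age, sex), 1)`.
#'
#' @param baseline A validated baseline (see [validate_baseline()]).
#' @param effect A full seven-band `tfa_effect` table.
#' @param scenario A `tfa_scenario` (see [build_intake_scenario()]).
#' @return A 70-row tibble `age_band, sex, sec_quintile, dpp`.
#' @examples
#' spec <- synthetic_spec(seed = 1)
#' dpp <- compute_dpp(generate_baseline(spec), build_default_effect_table(),
#'                    uniform_reduction_scenario(1.0))
#' sum(dpp$dpp)
#' @export
compute_dpp <- function(baseline, effect, scenario) {
  ctx <- build_model_context(baseline = baseline, effect = effect,
                             scenario = scenario)
  dplyr::mutate(ctx$grid, dpp = core_outcomes(ctx)$dpp)
}

#' Life-years gained per stratum
#'
#' Each prevented death is weighted by the median survival of the subgroup
#' in which it was averted. Per stratum the effective survival is the
#' share-weighted mean over CHD states, where undiagnosed-CHD survival is
#' the midpoint of the diagnosed and no-CHD medians, and the quintile
#' life-expectancy index rescales the undiagnosed and no-CHD survivals
#' (diagnosed-CHD survival is not SEC-indexed). Then
#' `lyg = dpp * effective_survival`.
#'
#' @param dpp A per-stratum DPP tibble from [compute_dpp()].
#' @param survival A `tfa_survival` object.
#' @param shares Apportionment of prevented deaths over CHD states per age
#'   band; defaults to [default_subgroup_shares()].
#' @return A 70-row tibble `age_band, sex, sec_quintile, lyg`.
#' @export
compute_lyg <- function(dpp, survival, shares = default_subgroup_shares()) {
  dpp <- tibble::as_tibble(dpp)
  check_columns(dpp, c("age_band", "sex", "sec_quintile", "dpp"), what = "dpp")
  dpp$sec_quintile <- as.integer(dpp$sec_quintile)
  check_full_grid(dpp, what = "dpp")
  check_nonnegative(dpp, "dpp", what = "dpp")
  ctx <- build_model_context(survival = survival, shares = shares)
  ord <- dplyr::left_join(ctx$grid, dpp,
                          by = c("age_band", "sex", "sec_quintile"))
  eff_surv <- core_effective_survival(ctx, ctx$surv_diag, ctx$surv_none)
  dplyr::mutate(ctx$grid, lyg = ord$dpp * eff_surv)
}

#' Incident hospital admissions avoided per stratum and disease group
#'
#' The same stratum-level mortality-reduction fraction is applied to the
#' baseline incident admissions of each disease group (AMI, unstable
#' angina, heart failure), so within a stratum the avoided counts preserve
#' the baseline AMI:UA:HF ratios exactly.
#'
#' @param admissions A validated incident-admissions table.
#' @inheritParams compute_dpp
#' @return A 210-row tibble `age_band, sex, sec_quintile, disease_group,
#'   avoided`.
#' @export
compute_admissions_avoided <- function(admissions, effect, scenario) {
  ctx <- build_model_context(admissions = admissions, effect = effect,
                             scenario = scenario)
  mrf_s <- core_mrf(ctx, ctx$mrf1)
  avoided <- ctx$adm * mrf_s
  tidyr::expand_grid(ctx$grid, disease_group = disease_groups()) |>
    dplyr::mutate(avoided = as.vector(t(avoided)))
}

# --- aggregation and indices -----------------------------------------------

#' Round totals for display
#'
#' Presentation rounding for headline totals: nearest 100, switching to the
#' nearest 1,000 above 10,000. Machine outputs always retain the unrounded
#' values; rounded companions are for display only.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @examples
#' round_display(c(3871, 37213, 94))  # 3900, 37000, 100
#' @export
round_display <- function(x) {
  ifelse(abs(x) >= 10000, round(x / 1000) * 1000, round(x / 100) * 100)
}

#' Aggregate per-stratum results into reporting tables
#'
#' Sums a long per-stratum results table into the three reporting layouts
#' (sex by coarse age band; sex by quintile; sex by quintile by coarse age
#' band) plus grand totals per metric. Unrounded sums are retained alongside
#' display-rounded companions.
#'
#' @param results Long tibble with columns `age_band`, `sex`,
#'   `sec_quintile`, `metric`, `value` covering all 70 strata per metric.
#' @param grouping Fine-to-coarse age-band map; defaults to
#'   [age_grouping()]. Must cover every fine band.
#' @return A list of tibbles `by_age_sex`, `by_sec_sex`, `by_sec_age_sex`,
#'   `totals`, each with `value` and `value_display` columns.
#' @export
aggregate_results <- function(results, grouping = age_grouping()) {
  results <- tibble::as_tibble(results)
  check_columns(results, c("age_band", "sex", "sec_quintile", "metric", "value"),
                what = "results")
  grouping <- tibble::as_tibble(grouping)
  check_columns(grouping, c("age_band", "coarse_band"), what = "grouping")
  if (!all(age_bands() %in% grouping$age_band)) {
    rlang::abort("grouping must map every fine age band to a coarse band",
                 class = "impacttfa_schema_error")
  }
  res <- dplyr::left_join(results, grouping, by = "age_band")
  agg <- function(df, ...) {
    df |>
      dplyr::summarise(value = sum(.data$value), .by = c("metric", ...)) |>
      dplyr::mutate(value_display = round_display(.data$value))
  }
  list(
    by_age_sex = agg(res, "sex", "coarse_band"),
    by_sec_sex = agg(res, "sex", "sec_quintile"),
    by_sec_age_sex = agg(res, "sex", "sec_quintile", "coarse_band"),
    totals = agg(res)
  )
}

#' Socio-economic rate index for an outcome
#'
#' Crude per-quintile totals mislead when quintile populations differ
#' (deprived quintiles are thinner at old ages because of shorter life
#' expectancy), so inequality is reported on rates: the outcome per person
#' per year within each quintile, optionally restricted to an age-sex
#' group. The index divides each quintile's rate by the quintile-3 rate, so
#' quintile 3 is exactly 1.0 by construction.
#'
#' @param results Long per-stratum results tibble (as for
#'   [aggregate_results()]), or a per-stratum tibble with a single value
#'   column named by `metric`.
#' @param baseline Validated baseline providing stratum populations.
#' @param metric Which metric to index (default `"dpp"`).
#' @param sex Optional: restrict to `"male"` or `"female"`.
#' @param coarse_band Optional: restrict to one of [coarse_bands()].
#' @param grouping Fine-to-coarse age map, used when `coarse_band` is given.
#' @return A tibble `sec_quintile, rate, index` with `index[3] == 1`.
#' @export
compute_rate_index <- function(results, baseline, metric = "dpp",
                               sex = NULL, coarse_band = NULL,
                               grouping = age_grouping()) {
  results <- tibble::as_tibble(results)
  if (!("metric" %in% names(results)) && metric %in% names(results)) {
    results <- results |>
      dplyr::mutate(metric = .env$metric, value = .data[[.env$metric]])
  }
  check_columns(results, c("age_band", "sex", "sec_quintile", "metric", "value"),
                what = "results")
  baseline <- validate_baseline(baseline)
  res <- results |>
    dplyr::filter(.data$metric == .env$metric) |>
    dplyr::left_join(baseline[c("age_band", "sex", "sec_quintile", "population")],
                     by = c("age_band", "sex", "sec_quintile")) |>
    dplyr::left_join(grouping, by = "age_band")
  if (!is.null(sex)) {
    res <- res[res$sex == sex, , drop = FALSE]
  }
  if (!is.null(coarse_band)) {
    res <- res[res$coarse_band == coarse_band, , drop = FALSE]
  }
  if (nrow(res) == 0) {
    rlang::abort("no strata left after filtering; check sex/coarse_band",
                 class = "impacttfa_validation_error")
  }
  rates <- res |>
    dplyr::summarise(rate = sum(.data$value) / sum(.data$population),
                     .by = "sec_quintile") |>
    dplyr::arrange(.data$sec_quintile)
  anchor <- rates$rate[rates$sec_quintile == 3L]
  if (anchor == 0) {
    rlang::abort("rate index undefined: quintile-3 rate is zero",
                 class = "impacttfa_validation_error")
  }
  dplyr::mutate(rates, index = .data$rate / anchor)
}
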