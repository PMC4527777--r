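#' Estimate the CHD impact of a trans-fat intake reduction scenario
#'
#' One-call front end to the counterfactual pipeline: per-stratum deaths
#' prevented or postponed, life-years gained and incident admissions
#' avoided, aggregated into the standard reporting layouts, with optional
#' Monte Carlo confidence intervals.
#'
#' @param baseline A validated baseline (expected CHD deaths and population
#'   per stratum).
#' @param scenario A `tfa_scenario` from [build_intake_scenario()] or
#'   [uniform_reduction_scenario()].
#' @param admissions Optional incident-admissions table; when `NULL`,
#'   admissions outcomes are omitted.
#' @param survival Optional `tfa_survival`; when `NULL`, life-years are
#'   omitted.
#' @param effect Effect table; defaults to [build_default_effect_table()].
#' @param shares Apportionment of prevented deaths over CHD states;
#'   defaults to [default_subgroup_shares()].
#' @param psa Optional [psa_config()]; when supplied, percentile confidence
#'   intervals are attached to strata and totals. When absent, results
#'   carry no interval columns (intervals are never fabricated).
#' @return An object of class `tfa_impact`: a list with `strata` (long
#'   tibble `age_band, sex, sec_quintile, metric, value` plus `low`/`high`
#'   when PSA ran), `aggregates` (see [aggregate_results()]), `totals`,
#'   `scenario`, `baseline`, and `psa` (the `tfa_psa` object or `NULL`).
#' @examples
#' spec <- synthetic_spec(seed = 1)
#' imp <- estimate_impact(
#'   baseline = generate_baseline(spec),
#'   scenario = uniform_reduction_scenario(1.0),
#'   admissions = generate_admissions(spec, generate_baseline(spec)),
#'   survival = generate_survival(spec)
#' )
#' glance(imp)
#' @export
estimate_impact <- function(baseline, scenario,
                            admissions = NULL, survival = NULL,
                            effect = build_default_effect_table(),
                            shares = default_subgroup_shares(),
                            psa = NULL) {
  dpp <- compute_dpp(baseline, effect, scenario)
  strata <- dpp |>
    dplyr::mutate(metric = "dpp", value = .data$dpp) |>
    dplyr::select(-"dpp")
  if (!is.null(survival)) {
    lyg <- compute_lyg(dpp, survival, shares)
    strata <- dplyr::bind_rows(strata,
      lyg |>
        dplyr::mutate(metric = "lyg", value = .data$lyg) |>
        dplyr::select(-"lyg"))
  }
  if (!is.null(admissions)) {
    adm <- compute_admissions_avoided(admissions, effect, scenario)
    strata <- dplyr::bind_rows(strata,
      adm |>
        dplyr::mutate(metric = paste0("adm_", .data$disease_group),
                      value = .data$avoided) |>
        dplyr::select(-"disease_group", -"avoided"))
  }

  psa_res <- NULL
  if (!is.null(psa)) {
    if (is.null(survival)) {
      rlang::abort("PSA requires a survival table (life-year draws)",
                   class = "impacttfa_validation_error")
    }
    psa_res <- run_psa(psa, baseline = baseline, admissions = admissions,
                       survival = survival, effect = effect,
                       scenario = scenario, shares = shares)
    strata <- dplyr::left_join(
      strata,
      psa_res$strata_ci[c("age_band", "sex", "sec_quintile", "metric",
                          "low", "high")],
      by = c("age_band", "sex", "sec_quintile", "metric"))
  }

  aggregates <- aggregate_results(strata)
  totals <- aggregates$totals
  if (!is.null(psa_res)) {
    totals <- dplyr::left_join(totals,
                               psa_res$totals[c("metric", "low", "high")],
                               by = "metric")
  }
  structure(
    list(strata = strata, aggregates = aggregates, totals = totals,
         scenario = scenario, baseline = validate_baseline(baseline),
         psa = psa_res),
    class = "tfa_impact")
}

#' @export
print.tfa_impact <- function(x, ...) {
  cat("<tfa_impact> scenario '", x$scenario$name[1], "' (delta by quintile: ",
      paste(format(x$scenario$delta, trim = TRUE), collapse = ", "),
      " % daily energy)\n", sep = "")
  cat("Totals per year:\n")
  print(x$totals)
  if (is.null(x$psa)) {
    cat("(no PSA run; intervals absent)\n")
  }
  invisible(x)
}

#' Tidy per-stratum results of a fitted impact object
#'
#' @param x A `tfa_impact` object.
#' @param ... Unused.
#' @return A long tibble with one row per stratum and metric: `age_band`,
#'   `sex`, `sec_quintile`, `metric`, `value`, and `low`/`high` when a
#'   sensitivity analysis was run.
#' @method tidy tfa_impact
#' @export
tidy.tfa_impact <- function(x, ...) {
  x$strata
}

#' One-row summary of a fitted impact object
#'
#' @param x A `tfa_impact` object.
#' @param ... Unused.
#' @return A one-row tibble of per-year totals (one column per metric, plus
#'   `adm_total` when admissions were modelled) and, when PSA ran,
#'   `n_draws` and `seed`.
#' @method glance tfa_impact
#' @export
glance.tfa_impact <- function(x, ...) {
  out <- tidyr::pivot_wider(x$totals[c("metric", "value")],
                            names_from = "metric", values_from = "value")
  adm_cols <- grep("^adm_", names(out), value = TRUE)
  if (length(adm_cols) > 0) {
    out$adm_total <- rowSums(out[adm_cols])
  }
  if (!is.null(x$psa)) {
    out$n_draws <- x$psa$config$n_draws
    out$seed <- x$psa$config$seed
  }
  out
}

#' Plot per-year gains by coarse age band and sex
#'
#' A simple presentation of one metric of a fitted impact object as a
#' grouped bar chart over the three coarse age bands, split by sex.
#'
#' @param object A `tfa_impact` object.
#' @param metric Metric to plot (default `"dpp"`).
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot tfa_impact
#' @export
autoplot.tfa_impact <- function(object, metric = "dpp", ...) {
  df <- object$aggregates$by_age_sex
  df <- df[df$metric == metric, , drop = FALSE]
  if (nrow(df) == 0) {
    rlang::abort(paste0("metric '", metric, "' not present in this object"),
                 class = "impacttfa_validation_error")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coarse_band, y = .data$value,
                                   fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Age band", y = paste0(metric, " per year"),
                  fill = "Sex",
                  title = paste0("Scenario '", object$scenario$name[1],
                                 "': ", metric, " by age and sex")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tfa_impact
#' @param x A `tfa_impact` object.
#' @param y Unused.
#' @export
plot.tfa_impact <- function(x, y, ...) {
  print(autoplot.tfa_impact(x, ...))
  invisible(x)
}
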