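#' Run a full scenario from a configuration and write all artefacts
#'
#' Orchestrates one end-to-end model run: load (or synthesise) the
#' baseline tables, build the scenario, run the point pipeline and — when a
#' `psa` block is present — the Monte Carlo sensitivity analysis, then
#' write `results.csv` (long per-stratum output), the three reporting
#' tables, `summary.json` and `run.log` into the output directory. With no
#' `psa` block the summary marks intervals as absent rather than inventing
#' them. Identical configurations produce byte-identical `summary.json`.
#'
#' @param config A named list (or path to a JSON file holding one) with
#'   elements:
#'   \describe{
#'     \item{`input_dir`}{directory holding `baseline.csv`,
#'       `admissions.csv`, `survival.csv`, `le_index.csv`; mutually
#'       exclusive with `synth`.}
#'     \item{`synth`}{list of [synthetic_spec()] arguments; mutually
#'       exclusive with `input_dir`.}
#'     \item{`scenario`}{list with `kind` (see [build_intake_scenario()])
#'       and either `target_intake` or, for the equal scenario,
#'       `reduction`.}
#'     \item{`psa`}{optional list of [psa_config()] arguments.}
#'     \item{`out_dir`}{output directory, created if absent.}
#'   }
#' @return Invisibly, the fitted `tfa_impact` object.
#' @examples
#' out <- tempfile()
#' imp <- run_scenario(list(
#'   synth = list(seed = 1),
#'   scenario = list(kind = "TFAsec1_equal", reduction = 1.0),
#'   out_dir = out
#' ))
#' list.files(out)
#' @export
run_scenario <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    rlang::abort("config must be a named list or a path to a JSON file",
                 class = "impacttfa_validation_error")
  }
  has_inputs <- !is.null(config$input_dir)
  has_synth <- !is.null(config$synth)
  if (has_inputs == has_synth) {
    rlang::abort("config must provide exactly one of input_dir or synth",
                 class = "impacttfa_validation_error")
  }
  if (is.null(config$out_dir)) {
    rlang::abort("config must provide out_dir",
                 class = "impacttfa_validation_error")
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }

  if (has_synth) {
    spec <- do.call(synthetic_spec, as.list(config$synth))
    baseline <- generate_baseline(spec)
    admissions <- generate_admissions(spec, baseline)
    survival <- generate_survival(spec)
    log_add("INFO inputs: synthetic, seed ", spec$seed)
  } else {
    paths <- file.path(config$input_dir,
                       c("baseline.csv", "admissions.csv",
                         "survival.csv", "le_index.csv"))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      rlang::abort(paste0("input file not found: ", missing[1]),
                   class = "impacttfa_schema_error")
    }
    baseline <- read_baseline(paths[1])
    admissions <- read_admissions(paths[2])
    survival <- read_survival(paths[3], paths[4])
    log_add("INFO inputs: read from ", config$input_dir)
  }
  log_add("INFO baseline rows: ", nrow(baseline),
          "; admissions rows: ", nrow(admissions))

  sc <- config$scenario
  if (is.null(sc$kind)) {
    rlang::abort("config$scenario$kind is required",
                 class = "impacttfa_validation_error")
  }
  scenario <- if (!is.null(sc$reduction)) {
    uniform_reduction_scenario(sc$reduction)
  } else {
    build_intake_scenario(sc$kind,
                          target_intake = sc$target_intake %||% 0,
                          baseline_intake = sc$baseline_intake)
  }
  log_add("INFO scenario: ", scenario$name[1], ", deltas ",
          paste(scenario$delta, collapse = ","))

  psa <- if (!is.null(config$psa)) do.call(psa_config, as.list(config$psa))
  imp <- estimate_impact(baseline = baseline, scenario = scenario,
                         admissions = admissions, survival = survival,
                         psa = psa)
  log_add("INFO totals: ",
          paste(imp$totals$metric, round(imp$totals$value, 2),
                sep = "=", collapse = " "))

  readr::write_csv(imp$strata, file.path(config$out_dir, "results.csv"))
  export_tables(imp, config$out_dir)

  totals_list <- purrr::map(seq_len(nrow(imp$totals)), function(i) {
    row <- imp$totals[i, ]
    entry <- list(value = row$value, display = row$value_display)
    if (!is.null(imp$psa)) {
      entry$low <- row$low
      entry$high <- row$high
    }
    entry
  })
  names(totals_list) <- imp$totals$metric
  summary_obj <- list(
    scenario = list(name = scenario$name[1],
                    baseline_intake = scenario$baseline_intake,
                    target_intake = scenario$target_intake[1],
                    delta = scenario$delta),
    totals = totals_list,
    ci = if (is.null(imp$psa)) {
      list(present = FALSE)
    } else {
      list(present = TRUE, n_draws = imp$psa$config$n_draws,
           seed = imp$psa$config$seed,
           percentiles = imp$psa$config$percentiles)
    },
    config_echo = config[setdiff(names(config), "out_dir")]
  )
  jsonlite::write_json(summary_obj, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(imp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export reporting tables of a fitted impact object
#'
#' Writes the three standard layouts as CSV: `table1.csv` (metrics by sex
#' and coarse age band), `table2.csv` (metrics by sex and SEC quintile,
#' plus per-metric rate-index rows anchored at quintile 3 = 1.0) and
#' `table3.csv` (as table2, split by coarse age band). Every table carries
#' unrounded values; `value_display` columns apply [round_display()] to
#' row totals only at the presentation layer.
#'
#' @param impact A `tfa_impact` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
export_tables <- function(impact, dir) {
  stopifnot(inherits(impact, "tfa_impact"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  agg <- impact$aggregates
  if (is.null(agg$by_age_sex) || is.null(agg$by_sec_sex) ||
      is.null(agg$by_sec_age_sex)) {
    rlang::abort("impact object is missing aggregates",
                 class = "impacttfa_schema_error")
  }

  t1 <- agg$by_age_sex |>
    dplyr::select("metric", "sex", "coarse_band", "value") |>
    tidyr::pivot_wider(names_from = "coarse_band", values_from = "value") |>
    dplyr::mutate(total = rowSums(dplyr::pick(dplyr::all_of(coarse_bands()))),
                  total_display = round_display(.data$total))

  t2 <- agg$by_sec_sex |>
    dplyr::select("metric", "sex", "sec_quintile", "value") |>
    tidyr::pivot_wider(names_from = "sec_quintile", values_from = "value",
                       names_prefix = "SEC") |>
    dplyr::mutate(
      total = rowSums(dplyr::pick(dplyr::starts_with("SEC"))),
      total_display = round_display(.data$total))
  idx_rows <- purrr::map_dfr(unique(impact$strata$metric), function(m) {
    # an all-zero scenario has no defined rate index; report NA, not an error
    idx <- tryCatch(
      compute_rate_index(impact$strata, impact$baseline, metric = m),
      impacttfa_validation_error = function(e) {
        tibble::tibble(sec_quintile = sec_quintiles(), rate = NA_real_,
                       index = NA_real_)
      })
    tibble::tibble(metric = m, sex = "rate_index",
                   SEC1 = idx$index[1], SEC2 = idx$index[2],
                   SEC3 = idx$index[3], SEC4 = idx$index[4],
                   SEC5 = idx$index[5], total = NA_real_,
                   total_display = NA_real_)
  })
  t2 <- dplyr::bind_rows(t2, idx_rows)

  t3 <- agg$by_sec_age_sex |>
    dplyr::select("metric", "sex", "coarse_band", "sec_quintile", "value") |>
    tidyr::pivot_wider(names_from = "sec_quintile", values_from = "value",
                       names_prefix = "SEC") |>
    dplyr::mutate(
      total = rowSums(dplyr::pick(dplyr::starts_with("SEC"))),
      total_display = round_display(.data$total)) |>
    dplyr::arrange(.data$coarse_band, .data$metric, .data$sex)

  paths <- c(table1 = file.path(dir, "table1.csv"),
             table2 = file.path(dir, "table2.csv"),
             table3 = file.path(dir, "table3.csv"))
  readr::write_csv(t1, paths[["table1"]])
  readr::write_csv(t2, paths[["table2"]])
  readr::write_csv(t3, paths[["table3"]])
  invisible(paths)
}
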