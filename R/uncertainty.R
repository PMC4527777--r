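#' Configuration for the probabilistic sensitivity analysis
#'
#' Parameter uncertainty is propagated by Monte Carlo simulation: the model
#' is re-evaluated over seeded parameter draws and empirical percentiles of
#' the simulated outputs form the confidence intervals. The default is
#' 5,000 draws summarised at the 2.5th and 97.5th percentiles; a
#' 10,000-draw run summarised at the 5th/95th centiles is an equally
#' documented alternative (`n_draws = 10000, percentiles = c(5, 95)`).
#'
#' @param n_draws Number of Monte Carlo draws (default 5000, minimum 2).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param percentiles Ordered pair in (0, 100), default `c(2.5, 97.5)`.
#' @param effect_family Sampling family for the effect factors:
#'   `"normal-truncated"` (default; mean at the point estimate, sd =
#'   (high - low) / (2 * 1.96), truncated at 0) or `"uniform"` on
#'   (low, high).
#' @param survival_family Sampling family for median survival; default
#'   `"uniform"`.
#' @param effect_draw `"shared"` (default) draws one scale factor per
#'   iteration applied to the whole effect table — the uncertain quantity
#'   is the single pooled effect estimate, with the age/sex gradient held
#'   fixed; `"cellwise"` draws every (age, sex) cell independently.
#' @param effect_bounds,survival_bounds Relative low/high bounds as
#'   fractions of the point estimate; default `c(0.8, 1.2)`, matching the
#'   80%/120% sensitivity bounds. `c(1, 1)` makes a parameter class
#'   degenerate (no uncertainty).
#' @return A list of class `tfa_psa_config`.
#' @examples
#' psa_config(n_draws = 1000, seed = 42)
#' @export
psa_config <- function(n_draws = 5000, seed = 1L,
                       percentiles = c(2.5, 97.5),
                       effect_family = c("normal-truncated", "uniform"),
                       survival_family = c("uniform", "normal-truncated"),
                       effect_draw = c("shared", "cellwise"),
                       effect_bounds = c(0.8, 1.2),
                       survival_bounds = c(0.8, 1.2)) {
  effect_family <- rlang::arg_match(effect_family)
  survival_family <- rlang::arg_match(survival_family)
  effect_draw <- rlang::arg_match(effect_draw)
  if (!is.numeric(n_draws) || length(n_draws) != 1 || n_draws < 2) {
    rlang::abort("n_draws must be at least 2",
                 class = "impacttfa_validation_error")
  }
  if (length(percentiles) != 2 || any(!is.finite(percentiles)) ||
      percentiles[1] >= percentiles[2] ||
      any(percentiles <= 0) || any(percentiles >= 100)) {
    rlang::abort("percentiles must be an ordered pair inside (0, 100)",
                 class = "impacttfa_validation_error")
  }
  check_bounds <- function(b, nm) {
    if (length(b) != 2 || any(!is.finite(b)) || b[1] > b[2] || b[1] < 0) {
      rlang::abort(paste0(nm, " must be an ordered non-negative pair"),
                   class = "impacttfa_validation_error")
    }
  }
  check_bounds(effect_bounds, "effect_bounds")
  check_bounds(survival_bounds, "survival_bounds")
  structure(
    list(n_draws = as.integer(n_draws), seed = as.integer(seed),
         percentiles = as.numeric(percentiles),
         effect_family = effect_family, survival_family = survival_family,
         effect_draw = effect_draw,
         effect_bounds = as.numeric(effect_bounds),
         survival_bounds = as.numeric(survival_bounds)),
    class = "tfa_psa_config")
}

# Deterministic per-(seed, draw, stream) RNG seed via a Lehmer-style mix;
# all arithmetic stays below 2^53 so it is exact in doubles.
mix_seed <- function(seed, draw_id, stream) {
  m <- 2147483647
  h <- (abs(as.double(seed)) %% m)
  h <- (h * 48271) %% m
  h <- (h + as.double(draw_id)) %% m
  h <- (h * 48271) %% m
  h <- (h + as.double(stream)) %% m
  h <- (h * 48271) %% m
  as.integer(h)
}

# Draw n values with the given family around point estimates. Bounds are
# relative factors of the point. Uniform samples U(low, high); truncated
# normal has mean = point, sd = (high - low) / (2 * 1.96), resampled at 0.
draw_values <- function(point, family, rel_bounds, n = length(point)) {
  lo <- rel_bounds[1] * point
  hi <- rel_bounds[2] * point
  if (identical(rel_bounds[1], rel_bounds[2])) return(rep_len(point, n))
  if (family == "uniform") {
    stats::runif(n, lo, hi)
  } else {
    sd <- (hi - lo) / (2 * 1.96)
    x <- stats::rnorm(n, point, sd)
    while (any(neg <- x < 0)) {
      x[neg] <- stats::rnorm(sum(neg), point[neg], sd[neg])
    }
    x
  }
}

# Internal: one draw of the raw parameter vectors given aligned points.
draw_vectors <- function(config, points, draw_id) {
  set.seed(mix_seed(config$seed, draw_id, 1L))
  mrf1 <- if (config$effect_draw == "shared") {
    points$mrf1 * draw_values(1, config$effect_family, config$effect_bounds, 1L)
  } else {
    draw_values(points$mrf1, config$effect_family, config$effect_bounds)
  }
  set.seed(mix_seed(config$seed, draw_id, 2L))
  surv <- draw_values(c(points$surv_diag, points$surv_none),
                      config$survival_family, config$survival_bounds)
  list(mrf1 = mrf1,
       surv_diag = surv[1:7],
       surv_none = surv[8:14])
}

effect_points <- function(effect) {
  effect <- effect_table(effect)
  stats::setNames(effect$mrf_1pct, paste(effect$sex, effect$age_band))
}

survival_points <- function(survival) {
  stopifnot(inherits(survival, "tfa_survival"))
  wide <- tidyr::pivot_wider(survival$median_survival,
                             names_from = "chd_state", values_from = "years")
  wide <- wide[match(age_bands(), wide$age_band), ]
  list(surv_diag = wide$diagnosed, surv_none = wide$none)
}

#' Draw one parameter set for the sensitivity analysis
#'
#' A deterministic function of `(config$seed, draw_id)`: the same pair
#' always yields the identical draw, and the effect and survival streams
#' are seeded separately so adding parameters to one class does not shift
#' the other. Drawn survival for the undiagnosed state is the midpoint of
#' the drawn diagnosed and no-CHD values, mirroring the point pipeline.
#'
#' @param config A [psa_config()].
#' @param effect A `tfa_effect` table (point estimates and bounds).
#' @param survival A `tfa_survival` object.
#' @param draw_id Positive integer index of the draw.
#' @return A list with `effect` (tibble `age_band, sex, mrf_1pct`),
#'   `survival` (tibble `age_band, chd_state, years`) and `draw_id`.
#' @export
draw_parameter_set <- function(config, effect, survival, draw_id) {
  stopifnot(inherits(config, "tfa_psa_config"))
  points <- c(list(mrf1 = effect_points(effect)), survival_points(survival))
  d <- draw_vectors(config, points, draw_id)
  eff <- tidyr::expand_grid(sex = sexes(), age_band = age_bands()) |>
    dplyr::mutate(mrf_1pct = unname(d$mrf1))
  surv <- tibble::tibble(
    age_band = rep(age_bands(), 3L),
    chd_state = rep(chd_states(), each = 7L),
    years = c(d$surv_diag, (d$surv_diag + d$surv_none) / 2, d$surv_none)
  )
  list(effect = eff, survival = surv, draw_id = draw_id)
}

#' Percentile confidence interval of simulated draws
#'
#' Empirical percentiles with linear interpolation between order statistics
#' (the type-7 estimator). Intervals may be asymmetric around the point
#' estimate since input distributions need not be normal.
#'
#' @param draws Numeric vector of simulated values (at least 2 finite).
#' @param percentiles Ordered pair in (0, 100), default `c(2.5, 97.5)`.
#' @return Named numeric `c(low, high)`.
#' @examples
#' summarize_ci(1:100)                      # 3.475, 97.525
#' summarize_ci(1:100, c(5, 95))            # 5.95, 95.05
#' @export
summarize_ci <- function(draws, percentiles = c(2.5, 97.5)) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 2) {
    rlang::abort("summarize_ci needs at least two finite draws",
                 class = "impacttfa_validation_error")
  }
  if (length(percentiles) != 2 || percentiles[1] > percentiles[2]) {
    rlang::abort("percentiles must be an ordered pair",
                 class = "impacttfa_validation_error")
  }
  q <- stats::quantile(draws, percentiles / 100, names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' Point estimates come from the mean parameters; for every output cell
#' (per-stratum and totals of deaths prevented or postponed, life-years
#' gained, and admissions avoided per disease group) the confidence
#' interval is the pair of configured percentiles over `n_draws` simulated
#' values. Reruns with the same config are bit-identical.
#'
#' @param config A [psa_config()].
#' @param baseline,admissions,survival,effect,scenario,shares Validated
#'   model inputs as for the point pipeline; `admissions` may be `NULL` to
#'   skip admissions outcomes.
#' @return A list of class `tfa_psa` with elements `strata_ci` (long tibble
#'   `age_band, sex, sec_quintile, metric, low, high`), `totals` (tibble
#'   `metric, point, low, high`), `draw_totals` (tibble of per-draw totals
#'   for audit), `config`.
#' @export
run_psa <- function(config, baseline, admissions = NULL, survival, effect,
                    scenario, shares = default_subgroup_shares()) {
  stopifnot(inherits(config, "tfa_psa_config"))
  ctx <- build_model_context(baseline = baseline, admissions = admissions,
                             survival = survival, effect = effect,
                             scenario = scenario, shares = shares)
  points <- list(mrf1 = ctx$mrf1, surv_diag = ctx$surv_diag,
                 surv_none = ctx$surv_none)
  n <- config$n_draws
  point <- core_outcomes(ctx)

  has_adm <- !is.null(ctx$adm)
  dpp_draws <- matrix(NA_real_, n, 70L)
  lyg_draws <- matrix(NA_real_, n, 70L)
  adm_draws <- if (has_adm) matrix(NA_real_, n, 210L) else NULL
  for (i in seq_len(n)) {
    d <- draw_vectors(config, points, i)
    o <- core_outcomes(ctx, mrf1_cells = d$mrf1,
                       surv_diag = d$surv_diag, surv_none = d$surv_none)
    dpp_draws[i, ] <- o$dpp
    lyg_draws[i, ] <- o$lyg
    if (has_adm) adm_draws[i, ] <- as.vector(o$adm)
  }
  bad <- which(!is.finite(rowSums(dpp_draws) + rowSums(lyg_draws)))
  if (has_adm) bad <- union(bad, which(!is.finite(rowSums(adm_draws))))
  if (length(bad) > 0) {
    rlang::abort(paste0("non-finite simulated value in draw ", min(bad)),
                 class = "impacttfa_validation_error")
  }

  p <- config$percentiles / 100
  col_ci <- function(m) {
    t(apply(m, 2L, stats::quantile, probs = p, names = FALSE, type = 7))
  }
  grid <- ctx$grid
  strata_ci <- dplyr::bind_rows(
    dplyr::mutate(grid, metric = "dpp",
                  point = point$dpp,
                  low = col_ci(dpp_draws)[, 1], high = col_ci(dpp_draws)[, 2]),
    dplyr::mutate(grid, metric = "lyg",
                  point = point$lyg,
                  low = col_ci(lyg_draws)[, 1], high = col_ci(lyg_draws)[, 2])
  )
  if (has_adm) {
    adm_ci <- col_ci(adm_draws)
    adm_strata <- purrr::map_dfr(seq_along(disease_groups()), function(k) {
      cols <- (k - 1L) * 70L + seq_len(70L)
      dplyr::mutate(grid, metric = paste0("adm_", disease_groups()[k]),
                    point = point$adm[, k],
                    low = adm_ci[cols, 1], high = adm_ci[cols, 2])
    })
    strata_ci <- dplyr::bind_rows(strata_ci, adm_strata)
  }

  draw_totals <- tibble::tibble(
    draw_id = seq_len(n),
    dpp = rowSums(dpp_draws),
    lyg = rowSums(lyg_draws)
  )
  totals <- tibble::tibble(
    metric = c("dpp", "lyg"),
    point = c(sum(point$dpp), sum(point$lyg)),
    low = c(summarize_ci(draw_totals$dpp, config$percentiles)[["low"]],
            summarize_ci(draw_totals$lyg, config$percentiles)[["low"]]),
    high = c(summarize_ci(draw_totals$dpp, config$percentiles)[["high"]],
             summarize_ci(draw_totals$lyg, config$percentiles)[["high"]])
  )
  if (has_adm) {
    for (k in seq_along(disease_groups())) {
      cols <- (k - 1L) * 70L + seq_len(70L)
      tot <- rowSums(adm_draws[, cols, drop = FALSE])
      draw_totals[[paste0("adm_", disease_groups()[k])]] <- tot
      ci <- summarize_ci(tot, config$percentiles)
      totals <- dplyr::bind_rows(totals, tibble::tibble(
        metric = paste0("adm_", disease_groups()[k]),
        point = sum(point$adm[, k]), low = ci[["low"]], high = ci[["high"]]))
    }
    adm_tot <- rowSums(adm_draws)
    draw_totals$adm_total <- adm_tot
    ci <- summarize_ci(adm_tot, config$percentiles)
    totals <- dplyr::bind_rows(totals, tibble::tibble(
      metric = "adm_total", point = sum(point$adm),
      low = ci[["low"]], high = ci[["high"]]))
  }

  structure(list(strata_ci = strata_ci, totals = totals,
                 draw_totals = draw_totals, config = config),
            class = "tfa_psa")
}

#' @export
print.tfa_psa <- function(x, ...) {
  cat("<tfa_psa> ", x$config$n_draws, " draws, seed ", x$config$seed,
      ", percentiles ", paste(x$config$percentiles, collapse = "/"), "\n",
      sep = "")
  print(x$totals)
  invisible(x)
}
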