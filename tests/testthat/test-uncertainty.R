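psa_inputs <- function(seed = 5) {
  spec <- synthetic_spec(seed = seed)
  b <- generate_baseline(spec)
  list(spec = spec, baseline = b,
       admissions = generate_admissions(spec, b),
       survival = generate_survival(spec),
       effect = build_default_effect_table(),
       scenario = uniform_reduction_scenario(1.0))
}

test_that("parameter draws are deterministic in (seed, draw_id) and respect support", {
  inp <- psa_inputs()
  cfg <- psa_config(n_draws = 10, seed = 99, effect_family = "uniform")
  d1 <- draw_parameter_set(cfg, inp$effect, inp$survival, 7)
  d2 <- draw_parameter_set(cfg, inp$effect, inp$survival, 7)
  expect_identical(d1, d2)
  d3 <- draw_parameter_set(cfg, inp$effect, inp$survival, 8)
  expect_false(identical(d1$effect, d3$effect))

  # uniform draws stay inside the 80%/120% envelope
  eff_join <- dplyr::inner_join(
    d1$effect, inp$effect[c("age_band", "sex", "mrf_low", "mrf_high")],
    by = c("age_band", "sex"))
  expect_true(all(eff_join$mrf_1pct >= eff_join$mrf_low - 1e-12))
  expect_true(all(eff_join$mrf_1pct <= eff_join$mrf_high + 1e-12))
  expect_true(all(d1$survival$years >= 0))

  # degenerate bounds reproduce the point estimates exactly
  cfg0 <- psa_config(n_draws = 10, seed = 99,
                     effect_bounds = c(1, 1), survival_bounds = c(1, 1))
  d0 <- draw_parameter_set(cfg0, inp$effect, inp$survival, 3)
  expect_equal(d0$effect$mrf_1pct, inp$effect$mrf_1pct)
  expect_equal(
    d0$survival$years[d0$survival$chd_state == "none"],
    inp$survival$median_survival$years[
      inp$survival$median_survival$chd_state == "none"])
})

test_that("uniform draws have the closed-form mean", {
  # point 0.10 with bounds (0.08, 0.12): mean 0.10, sd 0.04/sqrt(12)
  cfg <- psa_config(n_draws = 2, seed = 123, effect_family = "uniform",
                    effect_bounds = c(0.8, 1.2), effect_draw = "cellwise")
  points <- list(mrf1 = rep(0.10, 14),
                 surv_diag = rep(5, 7), surv_none = rep(10, 7))
  n_calls <- 7200L  # 14 effect cells per call ~ 1e5 scalar draws
  draws <- unlist(lapply(seq_len(n_calls), function(i) {
    impacttfa:::draw_vectors(cfg, points, i)$mrf1
  }))
  n <- length(draws)
  se <- (0.04 / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(draws) - 0.10), 3 * se)
  expect_true(all(draws >= 0.08 & draws <= 0.12))
})

test_that("percentile summaries use linear interpolation", {
  expect_equal(summarize_ci(1:100, c(2.5, 97.5)),
               c(low = 3.475, high = 97.525))
  expect_equal(summarize_ci(1:100, c(5, 95)),
               c(low = 5.95, high = 95.05))
  expect_equal(summarize_ci(rep(7, 10)), c(low = 7, high = 7))
  expect_error(summarize_ci(numeric(0)), "two finite")
  expect_error(summarize_ci(c(NA, 1)), "two finite")
  # widening the percentile pair never narrows the interval
  set.seed(2)
  x <- rnorm(500)
  narrow <- summarize_ci(x, c(10, 90))
  wide <- summarize_ci(x, c(2.5, 97.5))
  expect_lte(wide[["low"]], narrow[["low"]])
  expect_gte(wide[["high"]], narrow[["high"]])
})

test_that("degenerate distributions collapse intervals onto the point estimates", {
  inp <- psa_inputs()
  cfg <- psa_config(n_draws = 50, seed = 4,
                    effect_bounds = c(1, 1), survival_bounds = c(1, 1))
  psa <- run_psa(cfg, inp$baseline, inp$admissions, inp$survival,
                 inp$effect, inp$scenario)
  expect_equal(psa$totals$low, psa$totals$point)
  expect_equal(psa$totals$high, psa$totals$point)
  expect_equal(psa$strata_ci$low, psa$strata_ci$point)
  expect_equal(psa$strata_ci$high, psa$strata_ci$point)
})

test_that("PSA reruns with the same seed are bit-identical and CIs bracket the point", {
  inp <- psa_inputs()
  cfg <- psa_config(n_draws = 400, seed = 31)
  p1 <- run_psa(cfg, inp$baseline, inp$admissions, inp$survival,
                inp$effect, inp$scenario)
  p2 <- run_psa(cfg, inp$baseline, inp$admissions, inp$survival,
                inp$effect, inp$scenario)
  expect_identical(p1$totals, p2$totals)
  expect_identical(p1$strata_ci, p2$strata_ci)
  # symmetric families at default settings bracket the point estimate
  expect_true(all(p1$totals$low <= p1$totals$point))
  expect_true(all(p1$totals$high >= p1$totals$point))
  # interval width shrinks as the bounds narrow
  cfg_narrow <- psa_config(n_draws = 400, seed = 31,
                           effect_bounds = c(0.95, 1.05),
                           survival_bounds = c(0.95, 1.05))
  pn <- run_psa(cfg_narrow, inp$baseline, inp$admissions, inp$survival,
                inp$effect, inp$scenario)
  expect_true(all(pn$totals$high - pn$totals$low <
                    p1$totals$high - p1$totals$low))
})

test_that("PSA config validation rejects malformed settings", {
  expect_error(psa_config(n_draws = 1), "at least 2")
  expect_error(psa_config(percentiles = c(97.5, 2.5)), "ordered")
  expect_error(psa_config(percentiles = c(0, 50)), "ordered pair inside")
  expect_error(psa_config(effect_family = "lognormal"))
})
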