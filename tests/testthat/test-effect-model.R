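test_that("default effect table is calibrated to the population-average effect", {
  eff <- build_default_effect_table()
  w <- default_population_weights()
  joined <- dplyr::inner_join(eff, w, by = c("age_band", "sex"))
  expect_equal(sum(joined$mrf_1pct * joined$weight), 0.12, tolerance = 1e-12)
  # bounds at 80% / 120% everywhere
  expect_equal(eff$mrf_low, 0.8 * eff$mrf_1pct, tolerance = 1e-12)
  expect_equal(eff$mrf_high, 1.2 * eff$mrf_1pct, tolerance = 1e-12)
  # attenuation with age within each sex
  for (sx in sexes()) {
    expect_true(all(diff(eff$mrf_1pct[eff$sex == sx]) <= 1e-12))
  }
})

test_that("a flat schedule with uniform weights yields the anchor in every cell", {
  flat <- setNames(rep(1, 7), age_bands())
  w <- tidyr::expand_grid(age_band = age_bands(), sex = sexes())
  w$weight <- 1 / 14
  eff <- build_default_effect_table(0.12, flat, w)
  expect_equal(eff$mrf_1pct, rep(0.12, 14), tolerance = 1e-12)
})

test_that("effect-table construction rejects invalid inputs", {
  increasing <- setNames(c(1, 1.1, 1.2, 1.3, 1.4, 1.5), head(age_bands(), 6))
  expect_error(build_default_effect_table(0.12, increasing),
               "non-increasing")
  w0 <- default_population_weights()
  w0$weight <- 0
  expect_error(build_default_effect_table(0.12, population_weights = w0),
               "sum to 1")
  expect_error(build_default_effect_table(1.2), "fraction")
  # supplied bounds must match the 80/120 rule
  eff <- build_default_effect_table()
  bad <- dplyr::mutate(eff, mrf_low = 0.7 * mrf_1pct)
  expect_error(effect_table(bad), "80%")
})

test_that("85+ extrapolation continues the geometric attenuation", {
  base6 <- tidyr::expand_grid(age_band = head(age_bands(), 6), sex = sexes())
  mrf_by_band <- c("25-34" = 0.20, "35-44" = 0.18, "45-54" = 0.15,
                   "55-64" = 0.12, "65-74" = 0.10, "75-84" = 0.08)
  eff6 <- effect_table(dplyr::mutate(base6,
                                     mrf_1pct = mrf_by_band[age_band]))
  full <- extrapolate_oldest_band(eff6)
  expect_equal(full$mrf_1pct[full$age_band == "85+"], rep(0.064, 2),
               tolerance = 1e-12)
  expect_equal(full$mrf_low[full$age_band == "85+"], rep(0.8 * 0.064, 2),
               tolerance = 1e-12)

  # no attenuation continues as identity
  flat6 <- effect_table(dplyr::mutate(base6, mrf_1pct = 0.10))
  fullf <- extrapolate_oldest_band(flat6)
  expect_equal(fullf$mrf_1pct[fullf$age_band == "85+"], rep(0.10, 2))

  # zero propagates
  zero_band <- mrf_by_band
  zero_band["75-84"] <- 0
  effz <- effect_table(dplyr::mutate(base6, mrf_1pct = zero_band[age_band]))
  fullz <- extrapolate_oldest_band(effz)
  expect_equal(fullz$mrf_1pct[fullz$age_band == "85+"], rep(0, 2))

  # an undefined ratio (zero at 65-74, positive at 75-84) cannot arise:
  # the constructor already rejects effects that increase with age
  undef <- mrf_by_band
  undef["65-74"] <- 0
  undef["75-84"] <- 0.05
  expect_error(effect_table(dplyr::mutate(base6,
                                          mrf_1pct = undef[age_band])),
               "increases with age")

  # a table that already has 85+ is rejected
  expect_error(extrapolate_oldest_band(build_default_effect_table()),
               "already")
})

test_that("extrapolation commutes with dose scaling and matches the builder's ratios", {
  base6 <- tidyr::expand_grid(age_band = head(age_bands(), 6), sex = sexes())
  mrf_by_band <- c("25-34" = 0.20, "35-44" = 0.18, "45-54" = 0.15,
                   "55-64" = 0.12, "65-74" = 0.10, "75-84" = 0.08)
  eff6 <- effect_table(dplyr::mutate(base6,
                                     mrf_1pct = mrf_by_band[age_band]))
  full <- extrapolate_oldest_band(eff6)
  # scale-then-extrapolate equals extrapolate-then-scale (delta = 0.5 keeps
  # everything below the cap)
  half6 <- dplyr::mutate(eff6[c("age_band", "sex", "mrf_1pct")],
                         mrf_1pct = 0.5 * mrf_1pct)
  scaled_then <- extrapolate_oldest_band(effect_table(half6))
  then_scaled <- scale_effect(full, 0.5)
  expect_equal(scaled_then$mrf_1pct, then_scaled$mrf, tolerance = 1e-14)

  # default builder's calibrated 85+ cell obeys the same continuation rule
  eff <- build_default_effect_table()
  for (sx in sexes()) {
    m65 <- eff$mrf_1pct[eff$age_band == "65-74" & eff$sex == sx]
    m75 <- eff$mrf_1pct[eff$age_band == "75-84" & eff$sex == sx]
    m85 <- eff$mrf_1pct[eff$age_band == "85+" & eff$sex == sx]
    expect_equal(m85, m75^2 / m65, tolerance = 1e-12)
  }
})

test_that("dose scaling is linear, capped and rejects increases", {
  eff <- build_default_effect_table()
  expect_equal(scale_effect(eff, 1)$mrf, eff$mrf_1pct)
  expect_identical(scale_effect(eff, 0.5)$mrf, 0.5 * eff$mrf_1pct)
  expect_equal(scale_effect(eff, 0)$mrf, rep(0, 14))
  expect_error(scale_effect(eff, -0.1), "non-negative")
  # additivity below the cap, over random dose pairs
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1, 0, 2)
    b <- runif(1, 0, 2)
    expect_equal(scale_effect(eff, a + b)$mrf,
                 scale_effect(eff, a)$mrf + scale_effect(eff, b)$mrf,
                 tolerance = 1e-12)
  }
  # the cap binds for absurd doses
  expect_true(all(scale_effect(eff, 1e4)$mrf <= 1))
})

test_that("intake scenarios carry the documented baselines and floor rule", {
  uneq <- build_intake_scenario("TFAsec2_unequal")
  expect_equal(uneq$baseline_intake, c(0.75, 0.87, 1.0, 1.25, 1.5))
  expect_equal(uneq$delta, c(0.75, 0.87, 1.0, 1.25, 1.5))

  uneq05 <- build_intake_scenario("TFAsec2_unequal", target_intake = 0.5)
  expect_equal(uneq05$delta, c(0.25, 0.37, 0.5, 0.75, 1.0),
               tolerance = 1e-12)

  eq <- build_intake_scenario("TFAsec1_equal")
  expect_equal(eq$baseline_intake, rep(1.3, 5))

  # floor at zero when a quintile is already below the target
  low <- build_intake_scenario("custom", target_intake = 0.5,
                               baseline_intake = rep(0.4, 5))
  expect_equal(low$delta, rep(0, 5))

  expect_error(build_intake_scenario("custom", baseline_intake = rep(1, 4)),
               "quintile")
  expect_error(build_intake_scenario("TFAsec1_equal", target_intake = -1),
               "non-negative")

  unif <- uniform_reduction_scenario(1.0)
  expect_equal(unif$delta, rep(1.0, 5))
})
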