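make_flat_effect <- function(m = 0.12) {
  effect_table(dplyr::mutate(tidyr::expand_grid(age_band = age_bands(),
                                                sex = sexes()),
                             mrf_1pct = m))
}

one_stratum_baseline <- function(deaths, age = "55-64", sx = "male", q = 3L) {
  grid <- stratum_grid()
  grid$expected_deaths <- ifelse(grid$age_band == age & grid$sex == sx &
                                   grid$sec_quintile == q, deaths, 0)
  grid$population <- 1e6
  grid
}

test_that("DPP is the product of expected deaths and the scaled effect", {
  eff <- make_flat_effect(0.12)
  sc <- uniform_reduction_scenario(1.0)
  dpp <- compute_dpp(one_stratum_baseline(1000), eff, sc)
  expect_equal(sum(dpp$dpp), 120)

  # null scenario gives zero everywhere
  dpp0 <- compute_dpp(one_stratum_baseline(1000), eff,
                      uniform_reduction_scenario(0))
  expect_equal(dpp0$dpp, rep(0, 70))

  # two strata with different effects sum by brute force
  grid <- stratum_grid()
  grid$expected_deaths <- 0
  grid$expected_deaths[grid$age_band == "55-64" & grid$sex == "male" &
                         grid$sec_quintile == 1] <- 500
  grid$expected_deaths[grid$age_band == "65-74" & grid$sex == "male" &
                         grid$sec_quintile == 1] <- 500
  grid$population <- 1e6
  eff2 <- effect_table(dplyr::mutate(
    tidyr::expand_grid(age_band = age_bands(), sex = sexes()),
    mrf_1pct = ifelse(age_band %in% c("65-74", "75-84", "85+"), 0.1, 0.2)))
  dpp2 <- compute_dpp(grid, eff2, uniform_reduction_scenario(1.0))
  expect_equal(sum(dpp2$dpp), 500 * 0.2 + 500 * 0.1)
})

test_that("LYG follows the midpoint and LE-index rules", {
  le1 <- data.frame(sec_quintile = 1:5, le_index = rep(1, 5))
  wide <- data.frame(age_band = age_bands(), diagnosed = 4, none = 8)
  surv <- survival_from_wide(wide, le1)
  dpp <- dplyr::mutate(stratum_grid(), dpp = 0)
  dpp$dpp[dpp$age_band == "55-64" & dpp$sex == "male" &
            dpp$sec_quintile == 3] <- 10

  # all mass on undiagnosed: survival is the 6-year midpoint
  sh_undiag <- data.frame(age_band = rep(age_bands(), 3),
                          chd_state = rep(chd_states(), each = 7),
                          share = rep(c(0, 1, 0), each = 7))
  lyg <- compute_lyg(dpp, surv, sh_undiag)
  expect_equal(sum(lyg$lyg), 60)

  # zero DPP propagates to zero LYG
  dpp0 <- dplyr::mutate(stratum_grid(), dpp = 0)
  expect_equal(compute_lyg(dpp0, surv, sh_undiag)$lyg, rep(0, 70))

  # LE index scales the no-CHD group
  le <- data.frame(sec_quintile = 1:5, le_index = c(1, 1, 1, 1, 1.2))
  wide <- data.frame(age_band = age_bands(), diagnosed = 4, none = 10)
  surv2 <- survival_from_wide(wide, le)
  dpp5 <- dplyr::mutate(stratum_grid(), dpp = 0)
  dpp5$dpp[dpp5$age_band == "55-64" & dpp5$sex == "male" &
             dpp5$sec_quintile == 5] <- 10
  sh_none <- data.frame(age_band = rep(age_bands(), 3),
                        chd_state = rep(chd_states(), each = 7),
                        share = rep(c(0, 0, 1), each = 7))
  expect_equal(sum(compute_lyg(dpp5, surv2, sh_none)$lyg), 120)

  # degenerate shares: all mass on diagnosed with unit index gives
  # lyg = dpp * diagnosed survival exactly
  sh_diag <- data.frame(age_band = rep(age_bands(), 3),
                        chd_state = rep(chd_states(), each = 7),
                        share = rep(c(1, 0, 0), each = 7))
  expect_equal(sum(compute_lyg(dpp5, surv2, sh_diag)$lyg), 10 * 4)

  # shares that do not sum to one are rejected
  bad <- sh_diag
  bad$share[1] <- 0.5
  expect_error(compute_lyg(dpp5, surv2, bad), "sum to 1")
})

test_that("avoided admissions preserve within-stratum disease-group ratios", {
  eff <- make_flat_effect(0.1)
  sc <- uniform_reduction_scenario(1.0)
  grid <- tidyr::expand_grid(stratum_grid(), disease_group = disease_groups())
  grid$admissions <- 0
  pick <- grid$age_band == "55-64" & grid$sex == "male" & grid$sec_quintile == 2
  grid$admissions[pick] <- c(1000, 4000, 1000)  # AMI:UA:HF = 1:4:1
  avoided <- compute_admissions_avoided(grid, eff, sc)
  got <- avoided$avoided[avoided$age_band == "55-64" &
                           avoided$sex == "male" &
                           avoided$sec_quintile == 2]
  expect_equal(got, c(100, 400, 100))
  expect_equal(got / got[1], c(1, 4, 1))

  # null scenario
  z <- compute_admissions_avoided(grid, eff, uniform_reduction_scenario(0))
  expect_equal(z$avoided, rep(0, 210))
})

test_that("aggregates conserve stratum sums across all groupings", {
  spec <- synthetic_spec(seed = 11)
  b <- generate_baseline(spec)
  a <- generate_admissions(spec, b)
  s <- generate_survival(spec)
  imp <- estimate_impact(b, build_intake_scenario("TFAsec2_unequal"),
                         admissions = a, survival = s)
  agg <- imp$aggregates
  for (m in unique(imp$strata$metric)) {
    tot <- sum(imp$strata$value[imp$strata$metric == m])
    expect_equal(sum(agg$by_age_sex$value[agg$by_age_sex$metric == m]), tot,
                 tolerance = 1e-9)
    expect_equal(sum(agg$by_sec_sex$value[agg$by_sec_sex$metric == m]), tot,
                 tolerance = 1e-9)
    expect_equal(sum(agg$by_sec_age_sex$value[agg$by_sec_age_sex$metric == m]),
                 tot, tolerance = 1e-9)
    expect_equal(agg$totals$value[agg$totals$metric == m], tot,
                 tolerance = 1e-9)
  }
  # incomplete grouping is rejected
  expect_error(aggregate_results(imp$strata, grouping = age_grouping()[1:5, ]),
               "every fine age band")
})

test_that("display rounding uses hundreds then thousands", {
  expect_equal(round_display(3871), 3900)
  expect_equal(round_display(c(94, 12345, 9950, 37213)),
               c(100, 12000, 10000, 37000))
})

test_that("rate indices anchor at quintile 3 and scale as rate ratios", {
  # identical rates across quintiles: all indices 1
  grid <- stratum_grid()
  base <- dplyr::mutate(grid, expected_deaths = 100, population = 1e5)
  res <- dplyr::mutate(grid, metric = "dpp", value = 10)
  idx <- compute_rate_index(res, base, metric = "dpp")
  expect_equal(idx$index, rep(1, 5))

  # quintile 5 outcome rate twice quintile 3's
  res2 <- dplyr::mutate(grid, metric = "dpp",
                        value = ifelse(sec_quintile == 5, 20, 10))
  idx2 <- compute_rate_index(res2, base, metric = "dpp")
  expect_equal(idx2$index[idx2$sec_quintile == 5], 2)
  expect_identical(idx2$index[idx2$sec_quintile == 3], 1)

  # undefined when the anchor rate is zero
  res0 <- dplyr::mutate(grid, metric = "dpp", value = 0)
  expect_error(compute_rate_index(res0, base), "quintile-3")
})

test_that("pipeline matches the brute-force oracle on random toy tables", {
  set.seed(101)
  for (rep in 1:25) {
    b <- random_toy_baseline()
    a <- random_toy_admissions()
    eff_df <- random_effect_df()
    sc <- random_scenario_df()
    st <- random_survival_tables()
    sh <- random_shares_df()
    eff <- effect_table(eff_df)
    surv <- survival_from_wide(st$wide, st$le)

    dpp <- compute_dpp(b, eff, sc)
    expect_equal(dpp$dpp, oracle_dpp(b, eff_df, sc),
                 tolerance = 0)
    lyg <- compute_lyg(dpp, surv, sh)
    expect_equal(lyg$lyg,
                 oracle_lyg(b, eff_df, sc, st$wide, st$le, sh),
                 tolerance = 0)
    adm <- compute_admissions_avoided(a, eff, sc)
    expect_equal(adm$avoided,
                 oracle_admissions(a, eff_df, sc),
                 tolerance = 0)
  }
})
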