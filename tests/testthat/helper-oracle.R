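# Independent brute-force oracle: plain base-R row loops over the input
# data frames, sharing no code with the package internals. Used to check
# the vectorised pipeline cell by cell.

oracle_mrf <- function(effect_df, scenario_df, age, sx, q, cap = 1) {
  delta <- scenario_df$delta[scenario_df$sec_quintile == q]
  m1 <- effect_df$mrf_1pct[effect_df$age_band == age & effect_df$sex == sx]
  min(delta * m1, cap)
}

oracle_dpp <- function(baseline_df, effect_df, scenario_df) {
  out <- numeric(nrow(baseline_df))
  for (i in seq_len(nrow(baseline_df))) {
    r <- baseline_df[i, ]
    out[i] <- r$expected_deaths *
      oracle_mrf(effect_df, scenario_df, r$age_band, r$sex, r$sec_quintile)
  }
  out
}

# survival_df: age_band, diagnosed, none (wide); le_df: sec_quintile, le_index
oracle_lyg <- function(baseline_df, effect_df, scenario_df, survival_df,
                       le_df, shares_df) {
  out <- numeric(nrow(baseline_df))
  for (i in seq_len(nrow(baseline_df))) {
    r <- baseline_df[i, ]
    dpp <- r$expected_deaths *
      oracle_mrf(effect_df, scenario_df, r$age_band, r$sex, r$sec_quintile)
    srow <- survival_df[survival_df$age_band == r$age_band, ]
    sd <- srow$diagnosed
    sn <- srow$none
    su <- (sd + sn) / 2
    li <- le_df$le_index[le_df$sec_quintile == r$sec_quintile]
    shd <- shares_df$share[shares_df$age_band == r$age_band &
                             shares_df$chd_state == "diagnosed"]
    shu <- shares_df$share[shares_df$age_band == r$age_band &
                             shares_df$chd_state == "undiagnosed"]
    shn <- shares_df$share[shares_df$age_band == r$age_band &
                             shares_df$chd_state == "none"]
    out[i] <- dpp * (shd * sd + li * (shu * su + shn * sn))
  }
  out
}

oracle_admissions <- function(admissions_df, effect_df, scenario_df) {
  out <- numeric(nrow(admissions_df))
  for (i in seq_len(nrow(admissions_df))) {
    r <- admissions_df[i, ]
    out[i] <- r$admissions *
      oracle_mrf(effect_df, scenario_df, r$age_band, r$sex, r$sec_quintile)
  }
  out
}

# --- random full-grid fixtures ---------------------------------------------
# Tables cover the whole 70-stratum grid; "toy" cases carry non-zero deaths
# in a handful of randomly chosen strata only.

random_effect_df <- function() {
  # non-increasing with age within each sex, in [0, 0.3]
  per_sex <- function() sort(runif(7, 0.01, 0.3), decreasing = TRUE)
  rbind(
    data.frame(age_band = age_bands(), sex = "male", mrf_1pct = per_sex()),
    data.frame(age_band = age_bands(), sex = "female", mrf_1pct = per_sex())
  )
}

random_scenario_df <- function() {
  sc <- build_intake_scenario("custom", target_intake = 0,
                              baseline_intake = runif(5, 0, 2))
  sc
}

random_survival_tables <- function() {
  diagnosed <- sort(runif(7, 1, 20), decreasing = TRUE)
  none <- diagnosed + sort(runif(7, 0.5, 10), decreasing = TRUE)
  wide <- data.frame(age_band = age_bands(), diagnosed = diagnosed,
                     none = none)
  le <- data.frame(sec_quintile = 1:5,
                   le_index = c(runif(2, 0.9, 1.2), 1, runif(2, 0.8, 1.1)))
  list(wide = wide, le = le)
}

random_shares_df <- function() {
  raw <- matrix(runif(21, 0.05, 1), nrow = 7)
  raw <- raw / rowSums(raw)
  data.frame(
    age_band = rep(age_bands(), 3),
    chd_state = rep(c("diagnosed", "undiagnosed", "none"), each = 7),
    share = c(raw[, 1], raw[, 2], raw[, 3])
  )
}

random_toy_baseline <- function(n_nonzero = 4) {
  grid <- as.data.frame(stratum_grid())
  grid$expected_deaths <- 0
  idx <- sample(nrow(grid), n_nonzero)
  grid$expected_deaths[idx] <- round(runif(n_nonzero, 10, 2000), 1)
  grid$population <- grid$expected_deaths + round(runif(nrow(grid), 1e4, 1e6))
  grid
}

random_toy_admissions <- function() {
  grid <- as.data.frame(tidyr::expand_grid(stratum_grid(),
                                           disease_group = disease_groups()))
  grid$admissions <- 0
  idx <- sample(nrow(grid), 12)
  grid$admissions[idx] <- round(runif(12, 5, 5000))
  grid
}

# survival object from the wide/le pair
survival_from_wide <- function(wide, le) {
  ms <- rbind(
    data.frame(age_band = wide$age_band, chd_state = "diagnosed",
               years = wide$diagnosed),
    data.frame(age_band = wide$age_band, chd_state = "none",
               years = wide$none)
  )
  survival_table(ms, le)
}
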