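test_that("config invariants are enforced", {
  expect_error(sim_config(census_days = c(100, 100, 200)), "increasing")
  expect_error(sim_config(true_beta = 1.2), "0, 1")
  expect_error(sim_config(tradeoff_corr = 1.5), "-1, 1")
  expect_error(sim_config(wd_loading = -1.5), "-1, 1")
  expect_error(sim_config(openness_range = c(0, 30)), "0, 100")
  expect_error(sim_config(m0_sd = -1), "SD")
})

test_that("noise-free populations follow the analytic trajectory exactly", {
  sim <- simulate_population(noise_free_config())
  truth <- sim$truth
  joined <- sim$census |>
    dplyr::left_join(truth$individuals, by = c("individual_id", "species_id"))
  expected <- predict_size(joined$m0, exp(joined$log_alpha_i), joined$beta_i,
                           joined$census_day)
  expect_equal(joined$diameter_mm, expected, tolerance = 1e-12)
  expect_true(all(sim$census$alive == 1L))
})

test_that("interval death fractions match the binomial cloglog oracle", {
  # constant annual hazard with p(death | 1 yr) = 0.1, four 1-year censuses
  p_true <- 0.1
  cfg <- sim_config(
    n_species = 1, n_individuals = 10000, census_days = 365 * (1:4),
    mort_eta_mean = cloglog_eta(p_true), mort_eta_sd = 0,
    mort_light_slope = 0, mort_size_slope = 0,
    mort_individual_re_sd = 0, mort_census_re_sd = 0, seed = 31
  )
  sim <- simulate_population(cfg)
  iv <- build_intervals(sim$census)
  frac <- iv |>
    dplyr::group_by(census_index) |>
    dplyr::summarise(p = mean(died), n = dplyr::n())
  se <- sqrt(p_true * (1 - p_true) / frac$n)
  expect_true(all(abs(frac$p - p_true) < 3 * se))
  expect_true(all(abs(frac$p - p_true) < 0.01))
})

test_that("default trajectories bracket the slowest and fastest species", {
  sim <- simulate_population(sim_config(seed = 8))
  t_final <- max(sim$census$census_day)
  final_means <- sim$census |>
    dplyr::filter(census_day == t_final, !is.na(diameter_mm)) |>
    dplyr::group_by(species_id) |>
    dplyr::summarise(m = mean(diameter_mm))
  # deterministic envelope: slowest species at deepest shade, fastest in the
  # brightest gap (log-alpha light multipliers at the openness extremes)
  lo <- predict_size(4.12, 4.27e-4 * exp(0.092 * log(0.5)), 0.86, t_final)
  hi <- predict_size(4.12, 9.08e-4 * exp(0.092 * log(26)), 0.86, t_final)
  expect_true(all(final_means$m > lo * 0.8))
  expect_true(all(final_means$m < hi * 1.2))
  # species alpha truths span roughly the configured range
  expect_true(min(sim$truth$species$alpha) > 2e-4)
  expect_true(max(sim$truth$species$alpha) < 1.5e-3)
})

test_that("simulation is reproducible by seed and varies across seeds", {
  cfg <- sim_config(n_species = 3, n_individuals = 8, seed = 5)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  s3 <- simulate_population(cfg, seed = 6)
  expect_identical(s1$census, s2$census)
  expect_identical(s1$traits$observations, s2$traits$observations)
  expect_false(identical(s1$census, s3$census))
})

test_that("census tables satisfy their structural invariants", {
  sim <- simulate_population(sim_config(n_species = 5, n_individuals = 30,
                                        mort_eta_mean = -1.2, seed = 12))
  census <- sim$census
  by_ind <- census |> dplyr::group_by(individual_id)
  expect_true(all((by_ind |> dplyr::summarise(ok = !is.unsorted(census_day)))$ok))
  # one species per individual
  expect_true(all((by_ind |> dplyr::summarise(k = dplyr::n_distinct(species_id)))$k == 1))
  # no resurrection, nothing after the death census
  expect_true(all((by_ind |> dplyr::summarise(ok = all(diff(alive) <= 0)))$ok))
  after_death <- by_ind |>
    dplyr::summarise(extra = sum(cumsum(alive == 0L) > 1))
  expect_true(all(after_death$extra == 0))
  expect_true(all(census$diameter_mm > 0, na.rm = TRUE))
  expect_true(all(is.na(census$diameter_mm[census$alive == 0L])))
  expect_true(all(census$canopy_openness_pct > 0 & census$canopy_openness_pct <= 100))
})

test_that("per-census openness jitter is available but off by default", {
  static <- simulate_population(sim_config(n_species = 2, n_individuals = 5, seed = 4))
  n_per_ind <- static$census |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(k = dplyr::n_distinct(canopy_openness_pct))
  expect_true(all(n_per_ind$k == 1))
  jit <- simulate_population(sim_config(n_species = 2, n_individuals = 5,
                                        openness_jitter_sd = 0.2, seed = 4))
  n_per_ind <- jit$census |>
    dplyr::filter(alive == 1) |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(k = dplyr::n_distinct(canopy_openness_pct), n = dplyr::n())
  expect_true(all(n_per_ind$k[n_per_ind$n > 1] > 1))
})

test_that("wood density carries the configured demographic loading", {
  # independence when the loading is zero
  cfg0 <- sim_config(n_species = 200, n_individuals = 1, wd_loading = 0, seed = 21)
  sim0 <- simulate_population(cfg0)
  r0 <- cor(sim0$traits$species$wood_density, sim0$truth$species$log_alpha)
  expect_lt(abs(r0), 0.2)

  # deterministic linear map at loading -1 with no trait noise
  cfgd <- sim_config(n_species = 30, n_individuals = 1, wd_loading = -1, seed = 22)
  simd <- simulate_population(cfgd)
  traits <- simulate_traits(cfgd, simd$truth, wd_noise_sd = 0)
  expect_equal(cor(traits$species$wood_density, simd$truth$species$log_alpha), -1,
               tolerance = 1e-12)

  # default loading reproduces a strong negative wood-density-SGR correlation
  cfg <- sim_config(n_species = 200, n_individuals = 1, wd_loading = -0.74, seed = 23)
  sim <- simulate_population(cfg)
  sgr_sp <- sgr(sim$truth$species$alpha, cfg$true_beta, 10, annualize = TRUE)
  r <- cor(sim$traits$species$wood_density, sgr_sp)
  expect_equal(r, -0.74, tolerance = 0.05)
  # and, through the trade-off coupling, a negative mortality correlation
  expect_lt(cor(sim$traits$species$wood_density,
                sim$truth$species$annual_mortality_ref), -0.2)
})

test_that("other traits are independent of demography", {
  cfg <- sim_config(n_species = 200, n_individuals = 1, seed = 24)
  sim <- simulate_population(cfg)
  for (tr in c("sla", "seed_mass", "leaf_cn")) {
    expect_lt(abs(cor(sim$traits$species[[tr]], sim$truth$species$log_alpha)), 0.2)
  }
})
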