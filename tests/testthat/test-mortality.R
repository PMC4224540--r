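test_that("cloglog link, inverse and offset identities hold", {
  # link limits
  expect_equal(cloglog_prob(-50), 0, tolerance = 1e-15)
  expect_equal(cloglog_prob(50), 1)
  # proportional-hazards property: doubling exposure compounds survival
  eta <- cloglog_eta(0.1)
  expect_equal(cloglog_prob(eta, delta_t = 2), 1 - 0.9^2, tolerance = 1e-12)
  # closed-form inversion at the fastest species' annual rate
  expect_equal(cloglog_eta(0.182), -1.605, tolerance = 1e-3)
  expect_equal(cloglog_prob(cloglog_eta(0.182)), 0.182, tolerance = 1e-12)
  # round trip across the probability range
  p <- c(1e-8, 1e-4, 0.05, 0.5, 0.95, 1 - 1e-8)
  expect_equal(cloglog_prob(cloglog_eta(p)), p, tolerance = 1e-12)
  expect_error(cloglog_prob(0, delta_t = 0), "positive")
  expect_error(cloglog_eta(1), "0, 1")
})

test_that("interval splitting is exactly consistent under the offset", {
  withr::with_seed(11, {
    for (i in 1:20) {
      eta <- rnorm(1, -2, 1); d1 <- runif(1, 0.1, 2); d2 <- runif(1, 0.1, 2)
      whole <- cloglog_prob(eta, d1 + d2)
      split <- 1 - (1 - cloglog_prob(eta, d1)) * (1 - cloglog_prob(eta, d2))
      expect_equal(whole, split, tolerance = 1e-12)
    }
  })
})

test_that("interval records are built per consecutive census pair", {
  iv <- build_intervals(tiny_census())
  # three individuals, three censuses, one death at the last census
  expect_equal(nrow(iv), 6)
  expect_equal(sum(iv$died), 1)
  expect_equal(iv$died[iv$individual_id == "c" & iv$census_index == 3], 1L)
  # census-day gaps in years
  expect_equal(sort(unique(iv$delta_t)), c(239, 576) / 365, tolerance = 1e-12)
  expect_equal(576 / 365, 1.578, tolerance = 1e-3)
  expect_equal(239 / 365, 0.655, tolerance = 1e-3)
  # initial diameter is the first recorded measure
  expect_equal(unique(iv$initial_diameter_mm[iv$individual_id == "b"]), 4.5)
})

test_that("degenerate interval inputs are handled", {
  # dead at the first recorded census: no intervals
  dead_first <- tibble::tibble(
    individual_id = "x", species_id = "sp1", census_day = c(0, 576),
    diameter_mm = c(NA, NA), height_cm = c(NA, NA),
    canopy_openness_pct = c(5, 5), alive = c(0L, 0L)
  )
  expect_equal(nrow(build_intervals(dead_first)), 0)
  # a single census contributes nothing
  single <- tiny_census()[1, ]
  expect_equal(nrow(build_intervals(single)), 0)
  # resurrection is a hard error
  res <- tiny_census()
  res$alive <- c(1L, 0L, 1L, rep(1L, 6))
  expect_error(build_intervals(res), "alive after being dead")
})

test_that("per-census light uses the interval-start reading", {
  iv <- build_intervals(tiny_census(), light = "per_census")
  expect_equal(iv$canopy_openness_pct[iv$individual_id == "a"], c(4, 6))
  iv_avg <- build_intervals(tiny_census(), light = "averaged")
  expect_equal(unique(iv_avg$canopy_openness_pct[iv_avg$individual_id == "a"]), 5)
})

test_that("the GLMM degenerates to an ordinary cloglog GLM", {
  cfg <- sim_config(n_species = 1, n_individuals = 400,
                    mort_eta_mean = -1.5, mort_eta_sd = 0,
                    mort_individual_re_sd = 0, mort_census_re_sd = 0, seed = 41)
  iv <- build_intervals(simulate_population(cfg)$census)
  fit_none <- fit_mortality(iv, random_effects = "none")
  ref <- stats::glm(
    died ~ canopy_openness_pct + initial_diameter_mm + offset(log(delta_t)),
    family = binomial("cloglog"), data = iv
  )
  co <- setNames(fit_none$coefficients$estimate, fit_none$coefficients$term)
  expect_equal(unname(co["light"]), unname(coef(ref)["canopy_openness_pct"]),
               tolerance = 1e-6)
  expect_equal(unname(co["initial_diameter_mm"]),
               unname(coef(ref)["initial_diameter_mm"]), tolerance = 1e-6)
  expect_equal(fit_none$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  # with REs requested on RE-free data the variance collapses and fixed
  # effects agree with the GLM closely
  fit_re <- suppressMessages(fit_mortality(iv))
  co_re <- setNames(fit_re$coefficients$estimate, fit_re$coefficients$term)
  expect_equal(unname(co_re["light"]), unname(coef(ref)["canopy_openness_pct"]),
               tolerance = 0.05)
})

test_that("annual mortality predictions behave with light and species", {
  cfg <- sim_config(n_species = 4, n_individuals = 60, seed = 43)
  iv <- build_intervals(simulate_population(cfg)$census)
  fit <- fit_mortality(iv)
  grid <- seq(1, 25, by = 2)
  am <- annual_mortality(fit, light = grid, size = 4.12)
  # light slope negative: mortality decreases with openness for each species
  by_sp <- split(am, am$species_id)
  for (d in by_sp) expect_true(all(diff(d$annual_mortality[order(d$light)]) < 0))
  # no interaction: species ranking identical at every openness
  ranks <- am |>
    dplyr::group_by(light) |>
    dplyr::summarise(r = paste(order(annual_mortality), collapse = ","))
  expect_equal(length(unique(ranks$r)), 1)
  expect_true(all(am$annual_mortality > 0 & am$annual_mortality < 1))
  expect_error(annual_mortality(fit, species = "nope"), "not in the fitted")
})

test_that("zero-death species trigger a boundary warning", {
  cfg <- sim_config(n_species = 3, n_individuals = 25,
                    mort_eta_mean = -2, mort_eta_sd = 0, seed = 44)
  sim <- simulate_population(cfg)
  iv <- build_intervals(sim$census)
  # force one species to have no deaths
  iv$died[iv$species_id == "sp01"] <- 0L
  expect_warning(fit_mortality(iv, random_effects = "none"), "zero deaths")
})
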