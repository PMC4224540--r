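make_obs <- function(species_means, experiments = "exp1", offsets = 0,
                     n_per = 5, noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    tidyr::expand_grid(
      species_id = names(species_means),
      experiment = experiments,
      rep = seq_len(n_per)
    ) |>
      dplyr::mutate(
        trait = "wood_density",
        value = unname(species_means[species_id]) +
          offsets[match(experiment, experiments)] +
          rnorm(dplyr::n(), 0, noise_sd)
      )
  })
}

test_that("noise-free single-experiment estimates equal arithmetic means", {
  mu <- c(sp1 = 0.4, sp2 = 0.55, sp3 = 0.7)
  obs <- make_obs(mu, noise_sd = 0)
  est <- suppressMessages(estimate_trait_means(obs))
  expect_equal(setNames(est$wood_density, est$species_id), mu, tolerance = 1e-6)
})

test_that("balanced experiment offsets are absorbed by the experiment intercept", {
  mu <- c(sp1 = 0.4, sp2 = 0.55, sp3 = 0.7, sp4 = 0.62)
  plain <- make_obs(mu, experiments = c("exp1", "exp2"), offsets = c(0, 0),
                    noise_sd = 0.01, seed = 2)
  shifted <- make_obs(mu, experiments = c("exp1", "exp2"), offsets = c(0, 0.3),
                      noise_sd = 0.01, seed = 2)
  e1 <- suppressMessages(estimate_trait_means(plain))
  e2 <- suppressMessages(estimate_trait_means(shifted))
  # same within-species contrasts: the offset moves only the grand mean split
  expect_equal(e1$wood_density - mean(e1$wood_density),
               e2$wood_density - mean(e2$wood_density), tolerance = 1e-2)
})

test_that("shrinkage beats raw means in an unbalanced noisy design", {
  withr::with_seed(31, {
    mu <- setNames(rnorm(20, 0.55, 0.05), sprintf("sp%02d", 1:20))
    n_per_sp <- sample(c(2, 2, 3, 3, 30), 20, replace = TRUE)
    obs <- purrr::map2_dfr(names(mu), n_per_sp, function(s, n) {
      tibble::tibble(species_id = s, experiment = "exp1", trait = "wood_density",
                     value = mu[[s]] + rnorm(n, 0, 0.08))
    })
  })
  est <- suppressMessages(estimate_trait_means(obs))
  raw <- obs |>
    dplyr::group_by(species_id) |>
    dplyr::summarise(raw = mean(value))
  joined <- dplyr::left_join(est, raw, by = "species_id")
  rmse <- function(x) sqrt(mean((x - mu[joined$species_id])^2))
  expect_lte(rmse(joined$wood_density), rmse(joined$raw))
})

test_that("correlation matrix matches the t-distribution oracle", {
  # exact-correlation fixtures at the study's species count
  d54 <- make_exact_cor(0.54, 15, seed = 5)
  d74 <- make_exact_cor(-0.74, 15, seed = 6)
  p_oracle <- function(r, n) 2 * pt(abs(r) * sqrt(n - 2) / sqrt(1 - r^2),
                                    df = n - 2, lower.tail = FALSE)
  cm54 <- correlation_matrix(tibble::tibble(a = d54$x, b = d54$y))
  expect_equal(cm54$r["a", "b"], 0.54, tolerance = 1e-10)
  expect_equal(cm54$p["a", "b"], p_oracle(0.54, 15), tolerance = 1e-12)
  expect_equal(cm54$p["a", "b"], 0.038, tolerance = 1e-2)
  cm74 <- correlation_matrix(tibble::tibble(a = d74$x, b = d74$y))
  expect_equal(cm74$r["a", "b"], -0.74, tolerance = 1e-10)
  expect_equal(cm74$p["a", "b"], p_oracle(-0.74, 15), tolerance = 1e-12)
  expect_lt(cm74$p["a", "b"], 0.01)
  # significance labels
  expect_equal(cm54$pairs$signif, "*")
  expect_equal(cm74$pairs$signif, "**")
})

test_that("correlation matrix is symmetric with unit diagonal", {
  withr::with_seed(7, {
    tbl <- tibble::tibble(w = rnorm(12), x = rnorm(12), y = rnorm(12),
                          z = rnorm(12))
  })
  cm <- correlation_matrix(tbl)
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(cm$r) <= 1))
  # y = x exactly
  cm2 <- correlation_matrix(tibble::tibble(x = 1:5, y = 1:5 * 2))
  expect_equal(cm2$r["x", "y"], 1)
  expect_lt(cm2$p["x", "y"], 1e-10)
  # zero variance flagged
  expect_warning(cm3 <- correlation_matrix(tibble::tibble(x = 1:5, y = rep(1, 5))),
                 "zero variance")
  expect_true(is.na(cm3$r["x", "y"]))
})

test_that("SMA line matches the closed-form oracle", {
  # exact line
  x <- c(1, 2, 3, 4); fit <- sma_fit(x = x, y = 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  # hand-computed variance/covariance arithmetic
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  slope_o <- sign(sum((x - mean(x)) * (y - mean(y)))) *
    sqrt(sum((y - mean(y))^2) / sum((x - mean(x))^2))
  fit <- sma_fit(x = x, y = y)
  expect_equal(fit$slope, slope_o, tolerance = 1e-12)
  expect_equal(fit$slope, 1.3229, tolerance = 1e-4)
  expect_equal(fit$intercept, -0.5572, tolerance = 1e-4)
  expect_equal(fit$r, 0.8315, tolerance = 1e-4)
  expect_error(sma_fit(x = rep(1, 4), y = y), "zero variance")
})

test_that("SMA satisfies symmetry, centroid and equivariance properties", {
  withr::with_seed(13, {
    for (i in 1:10) {
      n <- sample(5:40, 1)
      x <- rnorm(n); y <- 0.5 * x + rnorm(n)
      fxy <- sma_fit(x = x, y = y); fyx <- sma_fit(x = y, y = x)
      expect_equal(fxy$slope * fyx$slope, 1, tolerance = 1e-10)
      expect_equal(fxy$r_squared, cor(x, y)^2, tolerance = 1e-12)
      # line passes through the centroid
      expect_equal(fxy$intercept + fxy$slope * mean(x), mean(y), tolerance = 1e-10)
      # scale equivariance
      f2 <- sma_fit(x = x, y = 3 * y)
      expect_equal(f2$slope, 3 * fxy$slope, tolerance = 1e-10)
      # sign(slope) = sign(r)
      expect_equal(sign(fxy$slope), sign(fxy$r))
    }
  })
})

test_that("SMA r-squared is bit-consistent with the correlation matrix", {
  withr::with_seed(17, {
    tbl <- tibble::tibble(x = rnorm(15), y = rnorm(15))
  })
  cm <- correlation_matrix(tbl)
  fit <- sma_fit(tbl, x = x, y = y)
  expect_identical(fit$r_squared, cm$r["x", "y"]^2)
  expect_identical(fit$p_value, cm$p["x", "y"])
})

test_that("trade-off summary converts the SMA slope to percentage points", {
  sgr_vals <- seq(0.1, 0.35, length.out = 8)
  demog <- tibble::tibble(species_id = sprintf("s%d", 1:8),
                          sgr_yr = sgr_vals,
                          annual_mortality = 0.433 * sgr_vals + 0.01)
  ts <- tradeoff_summary(demog)
  expect_equal(ts$slope, 0.433, tolerance = 1e-12)
  expect_equal(ts$mortality_increase_pp_per_0.1_sgr, 4.33, tolerance = 1e-10)
  expect_error(tradeoff_summary(demog[1:2, ]), "3 species")
})

test_that("an uncorrelated demography shows no trade-off", {
  withr::with_seed(19, {
    demog <- tibble::tibble(species_id = sprintf("s%d", 1:200),
                            sgr_yr = runif(200, 0.1, 0.4),
                            annual_mortality = runif(200, 0.05, 0.2))
  })
  ts <- tradeoff_summary(demog)
  expect_gt(ts$sma$p_value, 0.05)
})

test_that("a latent positive trade-off is recovered from generator truth", {
  signs <- sapply(1:20, function(i) {
    cfg <- sim_config(n_species = 25, n_individuals = 1, seed = 100 + i)
    truth <- simulate_population(cfg)$truth
    demog <- tibble::tibble(
      species_id = truth$species$species_id,
      sgr_yr = sgr(truth$species$alpha, cfg$true_beta, 10, annualize = TRUE),
      annual_mortality = truth$species$annual_mortality_ref
    )
    sign(tradeoff_summary(demog)$slope)
  })
  expect_gte(mean(signs > 0), 0.95)
})
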