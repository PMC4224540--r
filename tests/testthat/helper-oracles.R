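# Independent oracles and fixture builders used across the suite.

# Classical fixed-step 4th-order Runge-Kutta integration of the growth ODE
# dM/dt = alpha * M^beta, written directly from the Butcher tableau so it
# shares no code with predict_size().
rk4_grow <- function(m0, alpha, beta, t_end, n_steps = max(200L, ceiling(t_end))) {
  if (t_end == 0) return(m0)
  h <- t_end / n_steps
  f <- function(m) alpha * m^beta
  m <- m0
  for (i in seq_len(n_steps)) {
    k1 <- f(m)
    k2 <- f(m + h / 2 * k1)
    k3 <- f(m + h / 2 * k2)
    k4 <- f(m + h * k3)
    m <- m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  m
}

# Builds (x, y) vectors of length n whose sample Pearson correlation is
# exactly `r`, by orthogonalizing a noise vector against x.
make_exact_cor <- function(r, n, seed = 1) {
  withr::with_seed(seed, {
    x <- scale(rnorm(n))[, 1]
    e <- rnorm(n)
    e <- scale(residuals(lm(e ~ x)))[, 1]
    y <- r * x + sqrt(1 - r^2) * e
  })
  list(x = x, y = y)
}

# A tiny hand-written census table: three individuals, three censuses, one
# death in the second interval.
tiny_census <- function() {
  tibble::tibble(
    individual_id = rep(c("a", "b", "c"), each = 3),
    species_id = rep(c("sp1", "sp1", "sp2"), each = 3),
    census_day = rep(c(0, 576, 815), 3),
    diameter_mm = c(4, 5, 6, 4.5, 5.5, 6.5, 4, 5, NA),
    height_cm = c(50, 120, 200, 60, 130, 210, 50, 110, NA),
    canopy_openness_pct = rep(c(4, 6, 8), 3),
    alive = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L)
  )
}

noise_free_config <- function(n_species = 3, n_individuals = 6, seed = 99) {
  sim_config(
    n_species = n_species, n_individuals = n_individuals, seed = seed,
    individual_re_sd = c(0, 0, 0), m0_sd = 0,
    residual_sd_by_species = 0,
    mort_eta_mean = -30, mort_eta_sd = 0,
    mort_individual_re_sd = 0, mort_census_re_sd = 0,
    species_log_alpha_sd = 0.2
  )
}
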