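#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a growth fit
#'
#' One row per fixed effect on the sampling scale (species log-alpha
#' intercepts, the log-openness slope, logit beta, log M0), with a
#' `natural` column giving back-transformed estimates where the transform
#' is one-to-one.
#'
#' @param x A `growmort_growth_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `natural`.
#' @export
tidy.growmort_growth_fit <- function(x, ...) {
  fe <- x$fixed_effects
  se <- sqrt(diag(x$vcov_fixed))
  natural <- dplyr::case_when(
    grepl("^lalpha\\.species_id", names(fe)) ~ exp(unname(fe)),
    names(fe) == "tbeta" ~ stats::plogis(unname(fe)),
    names(fe) == "lm0" ~ exp(unname(fe)),
    TRUE ~ unname(fe)
  )
  tibble::tibble(
    term = names(fe),
    estimate = unname(fe),
    std.error = unname(se),
    statistic = unname(fe / se),
    natural = natural
  )
}

#' One-row summary of a growth fit
#'
#' @param x A `growmort_growth_fit`.
#' @param ... Unused.
#' @return A tibble with the scaling exponent and its Wald CI, the light
#'   slope, common M0, fit statistics and convergence flag.
#' @export
glance.growmort_growth_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$params$beta,
    beta_low = x$params$beta_ci[1],
    beta_high = x$params$beta_ci[2],
    light_slope = if (x$species_light_interaction) NA_real_ else x$params$light_slope,
    m0 = x$params$m0,
    sigma = x$params$sigma,
    logLik = x$loglik,
    BIC = x$bic,
    pseudo_r2 = x$pseudo_r2,
    n_obs = x$n_obs,
    n_individuals = x$n_individuals,
    n_params = x$n_params,
    method = x$method,
    converged = x$converged
  )
}

#' @export
print.growmort_growth_fit <- function(x, ...) {
  cat("Power-law growth NLME fit (", x$method, ")\n", sep = "")
  cat(sprintf("  beta = %.3f [%.3f, %.3f], M0 = %.2f mm\n",
              x$params$beta, x$params$beta_ci[1], x$params$beta_ci[2], x$params$m0))
  if (!x$species_light_interaction) {
    cat(sprintf("  log-openness slope on log(alpha) = %.3f\n", x$params$light_slope))
  }
  cat(sprintf("  alpha range: %.3g - %.3g mm mm^-1 day^-1 over %d species\n",
              min(x$params$alpha_by_species$alpha),
              max(x$params$alpha_by_species$alpha),
              nrow(x$params$alpha_by_species)))
  cat(sprintf("  pseudo-R2 = %.3f, BIC = %.1f, n = %d obs / %d individuals\n",
              x$pseudo_r2, x$bic, x$n_obs, x$n_individuals))
  if (!x$converged) cat("  NOTE: full random-effects structure did not converge; partial fit\n")
  invisible(x)
}

#' Tidy mortality-fit coefficients
#'
#' @param x A `growmort_mortality_fit`.
#' @param ... Unused.
#' @return Tibble of fixed effects with standard errors; species intercepts
#'   also as annual mortality probabilities (at zero covariates).
#' @export
tidy.growmort_mortality_fit <- function(x, ...) {
  m <- x$model
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  x$coefficients |>
    dplyr::mutate(std.error = unname(se),  # same order as the model matrix
                  statistic = .data$estimate / .data$std.error)
}

#' One-row summary of a mortality fit
#'
#' @param x A `growmort_mortality_fit`.
#' @param ... Unused.
#' @return Tibble with slopes, random-intercept variances and fit
#'   statistics.
#' @export
glance.growmort_mortality_fit <- function(x, ...) {
  co <- stats::setNames(x$coefficients$estimate, x$coefficients$term)
  tibble::tibble(
    light_slope = unname(co["light"]),
    size_slope = unname(co["initial_diameter_mm"]),
    var_individual = unname(x$re_var["individual"]),
    var_census = unname(x$re_var["census"]),
    logLik = x$loglik,
    BIC = x$bic,
    n_obs = x$n_obs,
    deaths = x$deaths,
    n_params = x$n_params,
    converged = x$converged
  )
}

#' @export
print.growmort_mortality_fit <- function(x, ...) {
  g <- glance(x)
  cat("Interval-censored cloglog mortality GLMM\n")
  cat(sprintf("  light slope = %.3f per %% openness, size slope = %.3f per mm\n",
              g$light_slope, g$size_slope))
  cat(sprintf("  random-intercept variances: individual %.3f, census %.3f\n",
              g$var_individual, g$var_census))
  cat(sprintf("  %d deaths over %d intervals, BIC = %.1f\n", g$deaths, g$n_obs, g$BIC))
  if (length(x$zero_death_species) > 0) {
    cat("  zero-death species (boundary intercepts): ",
        paste(x$zero_death_species, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.growmort_sma <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf.low = c(x$slope_ci[1], NA_real_),
    conf.high = c(x$slope_ci[2], NA_real_)
  )
}

#' @export
glance.growmort_sma <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r_squared, p.value = x$p_value, n = x$n)
}

#' @export
tidy.growmort_cormat <- function(x, ...) x$pairs

#' Table-layout correlation matrix
#'
#' Lower-triangular character rendering of a [correlation_matrix()] with
#' significance asterisks (* p < 0.05, ** p < 0.01), the layout used for
#' species trait-demography correlation tables.
#'
#' @param x A `growmort_cormat`.
#' @param digits Decimal places.
#' @return A character matrix (invisibly a data.frame for writing).
#' @export
format_cor_table <- function(x, digits = 2) {
  stopifnot(inherits(x, "growmort_cormat"))
  vars <- rownames(x$r)
  out <- matrix("", length(vars), length(vars), dimnames = list(vars, vars))
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j >= i) next
      star <- with(list(p = x$p[i, j]),
                   ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
      out[i, j] <- paste0(formatC(x$r[i, j], digits = digits, format = "f"), star)
    }
  }
  out
}

#' @export
print.growmort_cormat <- function(x, ...) {
  cat("Pearson correlations (",
      nrow(x$pairs), " pairs; * p<0.05, ** p<0.01)\n", sep = "")
  print(format_cor_table(x), quote = FALSE)
  invisible(x)
}
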