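#' Shrunken species trait means from multi-experiment observations
#'
#' Trait observations pooled from several experiments are combined with a
#' random-intercept model per trait: `value ~ 1 + (1 | species) +
#' (1 | experiment)` via [lme4::lmer()]. The species estimate is the grand
#' mean plus the species random effect (a shrinkage estimator), so
#' experiment-level offsets are absorbed rather than biasing species means.
#'
#' @param observations Long tibble with `species_id`, `experiment`, `trait`,
#'   `value` (as produced by [simulate_traits()]).
#' @return A wide tibble: one row per species, one column per trait.
#' @export
estimate_trait_means <- function(observations) {
  stopifnot(all(c("species_id", "experiment", "trait", "value") %in% names(observations)))
  if (dplyr::n_distinct(observations$species_id) < 2) {
    stop("need at least two species", call. = FALSE)
  }
  one_trait <- function(df) {
    if (dplyr::n_distinct(df$experiment) > 1) {
      fit <- lme4::lmer(value ~ 1 + (1 | species_id) + (1 | experiment),
                        data = df,
                        control = trait_lmer_control())
    } else {
      fit <- lme4::lmer(value ~ 1 + (1 | species_id), data = df,
                        control = trait_lmer_control())
    }
    re <- lme4::ranef(fit)$species_id
    tibble::tibble(
      species_id = rownames(re),
      estimate = unname(lme4::fixef(fit)[["(Intercept)"]] + re[["(Intercept)"]])
    )
  }
  observations |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(~one_trait(.x)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "trait", values_from = "estimate") |>
    dplyr::arrange(.data$species_id)
}

#' Pairwise Pearson correlations with significance tests
#'
#' Correlation matrix over species-level traits and demographic rates, with
#' two-sided p-values from the t statistic \eqn{r\sqrt{n-2}/\sqrt{1-r^2}} on
#' n-2 degrees of freedom. No multiple-testing adjustment is applied by
#' default; `p_adjust = "holm"` is available. Pairs are complete-case:
#' rows with missing values are dropped per pair with a warning.
#'
#' @param species_table Tibble with one row per species; `species_id` plus
#'   numeric columns.
#' @param vars Columns to correlate (default: all numeric columns).
#' @param p_adjust Method passed to [stats::p.adjust()] (default "none").
#' @return A list of class `growmort_cormat` with matrices `r`, `p` and
#'   `n`, plus a tidy tibble `pairs`.
#' @export
correlation_matrix <- function(species_table, vars = NULL, p_adjust = "none") {
  if (is.null(vars)) {
    vars <- names(species_table)[vapply(species_table, is.numeric, logical(1))]
  }
  stopifnot(length(vars) >= 2)
  x <- as.data.frame(species_table[vars])
  if (nrow(x) < 3) stop("need at least 3 species", call. = FALSE)
  if (anyNA(x)) warning("missing values: pairwise complete cases used", call. = FALSE)
  k <- length(vars)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); nmat <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(nmat) <- list(vars, vars)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(x[[i]], x[[j]])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (stats::sd(x[[i]][ok]) == 0 || stats::sd(x[[j]][ok]) == 0) {
        warning("zero variance in ", vars[i], " or ", vars[j],
                "; correlation undefined", call. = FALSE)
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      ct <- cor_test_pearson(x[[i]][ok], x[[j]][ok])
      r[i, j] <- r[j, i] <- ct$r
      p[i, j] <- p[j, i] <- ct$p
    }
  }
  upper <- upper.tri(p)
  p[upper] <- stats::p.adjust(p[upper], method = p_adjust)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  pairs <- tidyr::expand_grid(var1 = vars, var2 = vars) |>
    dplyr::filter(match(.data$var1, vars) < match(.data$var2, vars)) |>
    dplyr::mutate(
      r = r[cbind(.data$var1, .data$var2)],
      p_value = p[cbind(.data$var1, .data$var2)],
      n = nmat[cbind(.data$var1, .data$var2)],
      signif = dplyr::case_when(
        is.na(.data$p_value) ~ "",
        .data$p_value < 0.01 ~ "**",
        .data$p_value < 0.05 ~ "*",
        TRUE ~ ""
      )
    )
  structure(list(r = r, p = p, n = nmat, pairs = pairs),
            class = "growmort_cormat")
}

cor_test_pearson <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE))
}

#' Standardized major axis regression
#'
#' Symmetric line fit appropriate when both axes carry error:
#' slope = sign(r) * sd(y) / sd(x), intercept through the centroid, with the
#' p-value of the associated Pearson correlation and the standard
#' likelihood-based slope interval
#' \eqn{b (\sqrt{B + 1} \pm \sqrt{B})} where
#' \eqn{B = F_{1-\alpha;1,n-2} (1 - r^2)/(n - 2)}.
#'
#' @param data A data frame (evaluated for `x` and `y`), or omitted when
#'   `x`/`y` are vectors.
#' @param x,y Column names (unquoted) or numeric vectors.
#' @param level Confidence level for the slope interval.
#' @return An object of class `growmort_sma`: tibble-backed list with
#'   `slope`, `intercept`, `r`, `r_squared`, `p_value`, `n`, `slope_ci`,
#'   and the centroid.
#' @examples
#' sma_fit(x = c(1, 2, 3, 4), y = c(1, 3, 2, 5))
#' @export
sma_fit <- function(data = NULL, x, y, level = 0.95) {
  if (!is.null(data)) {
    xv <- rlang::eval_tidy(rlang::enquo(x), data)
    yv <- rlang::eval_tidy(rlang::enquo(y), data)
  } else {
    xv <- x; yv <- y
  }
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) stop("SMA needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(xv) == 0) stop("`x` has zero variance", call. = FALSE)
  if (stats::sd(yv) == 0) stop("`y` has zero variance", call. = FALSE)
  r <- stats::cor(xv, yv)
  slope <- sign(r + (r == 0)) * stats::sd(yv) / stats::sd(xv)
  intercept <- mean(yv) - slope * mean(xv)
  p <- cor_test_pearson(xv, yv)$p
  B <- stats::qf(level, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B))
  if (slope < 0) ci <- rev(ci)
  structure(list(
    slope = slope, intercept = intercept,
    r = r, r_squared = r^2, p_value = p, n = n,
    slope_ci = ci, x_mean = mean(xv), y_mean = mean(yv),
    data = tibble::tibble(x = xv, y = yv)
  ), class = "growmort_sma")
}

#' @export
print.growmort_sma <- function(x, ...) {
  cat("Standardized major axis regression (n =", x$n, ")\n")
  cat(sprintf("  slope     %.4f  [%.4f, %.4f]\n", x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.4f\n", x$intercept))
  cat(sprintf("  r = %.3f, R2 = %.3f, p = %.4g\n", x$r, x$r_squared, x$p_value))
  invisible(x)
}

#' Growth-mortality trade-off summary
#'
#' SMA regression of annual mortality probability on annualized SGR across
#' species (both at the same reference size and light), plus the implied
#' change in annual mortality, in percentage points, per 0.1 yr^-1 increase
#' in SGR.
#'
#' @param demography A species demography table from [species_demography()]
#'   (columns `sgr_yr` and `annual_mortality`).
#' @return A `growmort_tradeoff`: the `growmort_sma` fit plus
#'   `mortality_increase_pp_per_0.1_sgr`.
#' @export
tradeoff_summary <- function(demography) {
  stopifnot(all(c("sgr_yr", "annual_mortality") %in% names(demography)))
  if (nrow(demography) < 3) stop("need at least 3 species", call. = FALSE)
  fit <- sma_fit(demography, x = sgr_yr, y = annual_mortality)
  structure(list(
    sma = fit,
    slope = fit$slope,
    mortality_increase_pp_per_0.1_sgr = fit$slope * 0.1 * 100
  ), class = "growmort_tradeoff")
}

#' @export
print.growmort_tradeoff <- function(x, ...) {
  print(x$sma)
  cat(sprintf(
    "  an SGR increase of 0.1 yr^-1 implies a %.1f percentage-point change in annual mortality\n",
    x$mortality_increase_pp_per_0.1_sgr))
  invisible(x)
}

#' Species demography at a common reference size and light
#'
#' Combines a growth fit and a mortality fit into per-species demographic
#' rates at shared reference conditions: annualized SGR at reference size
#' `ref_size` and canopy openness `ref_light`, and annual mortality
#' probability for a seedling of that initial diameter under that openness.
#'
#' @param growth_fit A `growmort_growth_fit`.
#' @param mortality_fit A `growmort_mortality_fit` (optional; omit for
#'   growth-only output).
#' @param ref_size Reference size M_c in mm (default 10).
#' @param ref_light Reference canopy openness in % (default 4.5).
#' @return Tibble with `species_id`, `alpha_at_ref`, `sgr_yr`, and (when a
#'   mortality fit is given) `annual_mortality`, plus the reference values
#'   as columns.
#' @export
species_demography <- function(growth_fit, mortality_fit = NULL,
                               ref_size = 10, ref_light = 4.5) {
  stopifnot(inherits(growth_fit, "growmort_growth_fit"))
  p <- growth_fit$params
  slope <- if (growth_fit$species_light_interaction) p$light_slope else
    rep(p$light_slope, nrow(p$alpha_by_species))
  out <- p$alpha_by_species |>
    dplyr::mutate(
      alpha_at_ref = exp(.data$log_alpha + slope * log(ref_light)),
      sgr_yr = sgr(.data$alpha_at_ref, p$beta, ref_size, annualize = TRUE),
      reference_size = ref_size,
      reference_light = ref_light
    ) |>
    dplyr::select("species_id", "alpha_at_ref", "sgr_yr",
                  "reference_size", "reference_light")
  if (!is.null(mortality_fit)) {
    am <- annual_mortality(mortality_fit, light = ref_light, size = ref_size)
    out <- out |>
      dplyr::left_join(am |> dplyr::select("species_id", "annual_mortality"),
                       by = "species_id")
  }
  out
}

# near-zero residual variance is legitimate here (exact species means), so
# the usual convergence chatter is silenced
trait_lmer_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore",
                    calc.derivs = FALSE)
}
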