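#' Plot fitted growth trajectories with parametric confidence bands
#'
#' One panel per species: the model-predicted diameter trajectory at a
#' common reference openness (so species are compared free of light and
#' size confounding), with pointwise bands from [trajectory_ci()].
#'
#' @param object A `growmort_growth_fit`.
#' @param light Reference canopy openness in % (default 4.5).
#' @param t_grid Days at which to evaluate (default: 12 points over the
#'   observed span).
#' @param n_draws Parameter draws per species for the bands.
#' @param seed RNG seed for the draws.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growmort_growth_fit <- function(object, light = 4.5, t_grid = NULL,
                                         n_draws = 400, seed = 1L, ...) {
  if (is.null(t_grid)) {
    t_grid <- seq(0, max(object$data$census_day), length.out = 12)
  }
  sp <- object$params$alpha_by_species$species_id
  bands <- purrr::map_dfr(sp, function(s) {
    trajectory_ci(object, s, light = light, t_grid = t_grid,
                  n_draws = n_draws, seed = seed) |>
      dplyr::mutate(species_id = s)
  })
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$census_day, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species_id) +
    ggplot2::labs(x = "Days since planting", y = "Basal diameter (mm)",
                  title = sprintf("Predicted growth at %.1f%% canopy openness", light)) +
    ggplot2::theme_minimal()
}

#' Plot annual mortality against canopy openness per species
#'
#' Population-level annual mortality probability curves over a canopy
#' openness range at a common initial diameter; without a species-light
#' interaction the curves are vertically ordered identically at every
#' openness.
#'
#' @param object A `growmort_mortality_fit`.
#' @param light_range Openness range in % to span.
#' @param size Common initial diameter in mm.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growmort_mortality_fit <- function(object, light_range = c(0.5, 26),
                                            size = 4.12, ...) {
  grid <- seq(light_range[1], light_range[2], length.out = 50)
  curves <- annual_mortality(object, light = grid, size = size)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$light, y = .data$annual_mortality)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species_id) +
    ggplot2::labs(x = "Canopy openness (%)",
                  y = expression(Annual ~ mortality ~ probability ~ (yr^-1)),
                  title = sprintf("Mortality at a common size (%.1f mm)", size)) +
    ggplot2::theme_minimal()
}

#' Scatterplot with the standardized major axis line
#'
#' @param object A `growmort_sma` (or `growmort_tradeoff`).
#' @param xlab,ylab Axis labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growmort_sma <- function(object, xlab = "x", ylab = "y", ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(
      x = xlab, y = ylab,
      subtitle = sprintf("SMA slope %.3f, R2 = %.2f, p = %.3g",
                         object$slope, object$r_squared, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.growmort_sma
#' @export
autoplot.growmort_tradeoff <- function(object, ...) {
  autoplot.growmort_sma(object$sma,
                        xlab = expression(SGR ~ (mm ~ mm^-1 ~ yr^-1)),
                        ylab = expression(Annual ~ mortality ~ probability)) +
    ggplot2::labs(title = "Growth-mortality trade-off across species")
}
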