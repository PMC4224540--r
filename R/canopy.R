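#' Average canopy openness below a height threshold
#'
#' Densiometer readings taken above a sapling stop reflecting the light the
#' plant experiences once the plant overtops the instrument, so the light
#' covariate for each individual is the mean canopy openness over the
#' censuses at which its height was at or below `threshold_cm`; the same
#' average is carried forward for all later censuses. When an individual has
#' no reading at or below the threshold the earliest census reading is used.
#'
#' @param census A census table (data frame) with at least
#'   `individual_id`, `census_day`, `canopy_openness_pct` and `height_cm`.
#' @param threshold_cm Height threshold in cm (default 160).
#' @return A tibble with one row per individual: `individual_id`,
#'   `mean_openness_pct` and `n_readings_used`.
#' @examples
#' census <- tibble::tibble(
#'   individual_id = "a", census_day = c(1, 2, 3),
#'   canopy_openness_pct = c(4, 6, 8), height_cm = c(50, 120, 200)
#' )
#' average_canopy(census)  # mean of 4 and 6 = 5
#' @export
average_canopy <- function(census, threshold_cm = 160) {
  required <- c("individual_id", "census_day", "canopy_openness_pct", "height_cm")
  missing_cols <- setdiff(required, names(census))
  if (length(missing_cols) > 0) {
    stop("`census` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(census) == 0) stop("`census` has no rows", call. = FALSE)
  census |>
    dplyr::filter(!is.na(.data$canopy_openness_pct)) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$census_day, .by_group = TRUE) |>
    dplyr::summarise(
      mean_openness_pct = mean_openness_below(
        .data$canopy_openness_pct, .data$height_cm, threshold_cm
      ),
      n_readings_used = sum(!is.na(.data$height_cm) & .data$height_cm <= threshold_cm) |>
        max(1L),
      .groups = "drop"
    )
}

mean_openness_below <- function(openness, height, threshold_cm) {
  use <- !is.na(height) & height <= threshold_cm
  if (!any(use)) openness[1] else mean(openness[use])
}
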