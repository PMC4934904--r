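#' Growing-season window for a latitude
#'
#' The annual compositing window is centred on day 209 (July 28, the boreal
#' peak-NDVI day) with a length that shrinks linearly with latitude,
#' `L = a + b * latitude`. The default coefficients reproduce start days
#' between May 7 and June 15 and end days between September 9 and October 18
#' across latitudes 45--65.
#'
#' @param latitude Degrees north, in `[40, 75]`.
#' @param season_model List with coefficients `a` (days) and `b` (days per
#'   degree).
#' @param centre_day Peak-of-season day of year (default 209).
#' @return Named integer vector `c(start, end)`, rounded outward.
#' @export
season_window <- function(latitude, season_model = list(a = 339.5, b = -3.9),
                          centre_day = 209) {
  assert_scalar_num(latitude, "latitude", 40, 75)
  len <- season_model$a + season_model$b * latitude
  if (!is.finite(len) || len < 30) {
    stop_input("season model gives a window shorter than 30 days")
  }
  c(start = as.integer(floor(centre_day - len / 2)),
    end = as.integer(ceiling(centre_day + len / 2)))
}

#' Score candidate observations for best-available-pixel compositing
#'
#' Each candidate is scored on four terms, all in `[0, 1]` with higher
#' better: preferred-sensor membership; distance to cloud/cloud shadow as an
#' increasing Gaussian beyond a hard 50 m buffer; acquisition day of year as a
#' Gaussian of distance from the season centre; and a decreasing Gaussian in
#' atmospheric opacity. The score is the weighted mean of the four terms.
#'
#' @param obs Data frame of candidates with columns `day_of_year`,
#'   `sensor_class` (`"preferred"`/`"non_preferred"`), `distance_to_cloud`
#'   (metres) and `opacity` (unitless, >= 0).
#' @param weights Named weights `sensor`, `cloud`, `day`, `opacity`
#'   (normalized internally; the source scoring scheme publishes no values, so
#'   equal weights are the default).
#' @param window Growing-season window from [season_window()]; observations
#'   outside it violate the scoring precondition and raise an error.
#' @param cloud_buffer,cloud_sigma Hard exclusion radius and Gaussian scale
#'   (metres) of the cloud-distance term.
#' @param opacity_scale Gaussian scale of the opacity term.
#' @param sensor_scores Term values per sensor class.
#' @param centre_day Peak-of-season day (209).
#' @return Numeric vector of scores, one per row of `obs`.
#' @export
score_candidate <- function(obs,
                            weights = c(sensor = 1, cloud = 1, day = 1, opacity = 1),
                            window = season_window(55),
                            cloud_buffer = 50, cloud_sigma = 50,
                            opacity_scale = 0.2,
                            sensor_scores = c(preferred = 1, non_preferred = 0.5),
                            centre_day = 209) {
  obs <- as.data.frame(obs)
  req <- c("day_of_year", "sensor_class", "distance_to_cloud", "opacity")
  if (!all(req %in% names(obs))) {
    stop_input("obs must have columns ", paste(req, collapse = ", "))
  }
  if (any(obs$distance_to_cloud < 0, na.rm = TRUE) ||
      any(obs$opacity < 0, na.rm = TRUE)) {
    stop_input("distance_to_cloud and opacity must be non-negative")
  }
  if (any(obs$day_of_year < window[["start"]] | obs$day_of_year > window[["end"]])) {
    stop_input("candidate day_of_year outside the growing-season window")
  }
  w <- weights[c("sensor", "cloud", "day", "opacity")] / sum(weights)
  sensor_term <- unname(sensor_scores[as.character(obs$sensor_class)])
  if (anyNA(sensor_term)) stop_input("unknown sensor_class value")
  d <- pmax(obs$distance_to_cloud - cloud_buffer, 0)
  cloud_term <- 1 - exp(-d^2 / (2 * cloud_sigma^2))
  sigma_day <- (window[["end"]] - window[["start"]]) / 4
  day_term <- exp(-(obs$day_of_year - centre_day)^2 / (2 * sigma_day^2))
  opacity_term <- exp(-(obs$opacity / opacity_scale)^2 / 2)
  as.numeric(w[["sensor"]] * sensor_term + w[["cloud"]] * cloud_term +
               w[["day"]] * day_term + w[["opacity"]] * opacity_term)
}

#' Build one year's best-available-pixel composite
#'
#' Picks, per pixel, the candidate with the highest score; ties are broken by
#' earlier acquisition day and then lower opacity, so the result is
#' deterministic. Pixels with no candidate in the window are flagged as gaps.
#' Candidates outside the growing-season window are rejected up front.
#'
#' @param candidates Data frame with `pixel_id` plus the columns required by
#'   [score_candidate()]; any other columns (the spectral payload) are carried
#'   through to the winner.
#' @param pixels Vector of all pixel ids the composite must cover (defaults to
#'   those present in `candidates`).
#' @param ... Passed to [score_candidate()].
#' @param window Growing-season window.
#' @return Tibble with one row per pixel: winning candidate columns, `score`,
#'   and a logical `gap`.
#' @export
composite_year <- function(candidates, pixels = NULL,
                           window = season_window(55), ...) {
  candidates <- tibble::as_tibble(candidates)
  if (is.null(pixels)) pixels <- unique(candidates$pixel_id)
  keep <- candidates$day_of_year >= window[["start"]] &
    candidates$day_of_year <= window[["end"]]
  candidates <- candidates[keep, , drop = FALSE]
  if (nrow(candidates)) {
    candidates$score <- score_candidate(candidates, window = window, ...)
    winners <- candidates |>
      dplyr::arrange(.data$pixel_id, dplyr::desc(.data$score),
                     .data$day_of_year, .data$opacity) |>
      dplyr::distinct(.data$pixel_id, .keep_all = TRUE)
  } else {
    winners <- candidates
    winners$score <- numeric(0)
  }
  out <- tibble::tibble(pixel_id = pixels) |>
    dplyr::left_join(winners, by = "pixel_id") |>
    dplyr::mutate(gap = is.na(.data$score))
  out
}

#' Interpolate gaps in an annual pixel series
#'
#' Interior gaps are filled linearly between the two nearest data years that
#' bracket the gap; leading and trailing gaps are filled by nearest-value
#' extension. All-gap series are returned unchanged (they are removed later by
#' [validity_filter()]).
#'
#' @param x Numeric vector (one value per year) with `NA` gaps.
#' @return Tibble with columns `value` (filled series) and `filled` (logical
#'   fill flags).
#' @export
fill_gaps <- function(x) {
  stopifnot(is.numeric(x))
  filled <- is.na(x)
  value <- as.numeric(fill_series_matrix(matrix(x, nrow = 1L)))
  tibble::tibble(value = value, filled = filled & !is.na(value))
}

#' Screen pixel series for chronic data gaps
#'
#' A pixel series is invalid when it has three or more consecutive gap years
#' or more than six gap years in total (assessed on the pre-fill gap flags).
#' Invalid pixels become background for all downstream stages.
#'
#' @param gaps Logical vector of per-year gap flags (or a pixels x years
#'   logical matrix).
#' @param max_consecutive,max_total Exclusion thresholds.
#' @return Logical: `TRUE` when the series is valid (vectorized over rows for
#'   matrix input).
#' @export
validity_filter <- function(gaps, max_consecutive = 3L, max_total = 6L) {
  if (!is.matrix(gaps)) gaps <- matrix(gaps, nrow = 1L)
  run <- max_run_per_row(gaps)
  tot <- rowSums(gaps)
  as.vector(run < max_consecutive & tot <= max_total)
}

#' Gap-fill and validity-screen a spectral scene
#'
#' Applies [fill_gaps()] logic to every layer of a scene along the year axis
#' and computes the per-pixel validity mask from the pre-fill gap flags. The
#' operation is idempotent: compositing an already-composited scene returns it
#' unchanged.
#'
#' @param scene A `fp_scene`.
#' @param max_consecutive,max_total Validity thresholds, see
#'   [validity_filter()].
#' @return List with `scene` (gap-filled `fp_scene`), `valid` (logical
#'   matrix), and `gap_summary` (tibble with per-year gap counts and fill
#'   counts).
#' @export
composite_scene <- function(scene, max_consecutive = 3L, max_total = 6L) {
  stopifnot(inherits(scene, "fp_scene"))
  d <- dim(scene$layers[[1L]])
  npx <- d[1L] * d[2L]; Tn <- d[3L]
  gapmat <- matrix(scene$nodata, npx, Tn)
  valid <- matrix(validity_filter(gapmat, max_consecutive, max_total),
                  d[1L], d[2L])
  out_layers <- lapply(scene$layers, function(a) {
    m <- matrix(a, npx, Tn)
    array(fill_series_matrix(m), d)
  })
  filled_scene <- new_scene(out_layers, array(is.na(out_layers[[1L]]), d),
                            scene$years, scene$pixel_size, scene$origin,
                            scene$latitude)
  gap_summary <- tibble::tibble(
    year = scene$years,
    n_gap = colSums(gapmat),
    n_filled = colSums(gapmat & !is.na(matrix(out_layers[[1L]], npx, Tn)))
  )
  list(scene = filled_scene, valid = valid, gap_summary = gap_summary)
}
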