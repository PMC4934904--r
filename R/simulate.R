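#' Configure the synthetic disturbance-and-recovery scene simulator
#'
#' Builds the configuration for [generate_truth()] and [render_spectral()].
#' The simulator emulates a boreal study scene: a mostly contiguous forest
#' matrix with permanent water bodies and open (persistent non-forest) land,
#' annual stand-replacing disturbance patches whose sizes follow a truncated
#' discrete power law (the inverse size--frequency relationship typical of
#' boreal fire regimes), and linear spectral recovery ramps after a lag.
#'
#' @param grid_rows,grid_cols Scene dimensions in pixels.
#' @param pixel_size Pixel edge length in metres (30 m Landsat grain, 0.09 ha).
#' @param n_years Number of annual time steps (>= 4 so trajectories can be
#'   classified downstream).
#' @param start_year Calendar year of the first layer.
#' @param initial_forest_fraction Fraction of the whole grid that is forest in
#'   year one.
#' @param water_fraction Fraction of the grid occupied by permanent water.
#' @param annual_disturbance_rate Expected fraction of the current forest area
#'   disturbed each year, in `[0, 1)`.
#' @param patch_size_alpha Exponent of the truncated power-law patch-size
#'   distribution `P(s) propto s^-alpha`.
#' @param min_patch_px,max_patch_px Patch-size support in pixels.
#' @param recovery_lag Years after a disturbance before spectral recovery
#'   begins.
#' @param recovery_rate Fraction of the disturbance spectral deficit regained
#'   per year once recovery starts; 0 disables recovery.
#' @param recovery_target Fraction of the pre-disturbance NBR at which a pixel
#'   counts as forest again in the truth maps (matches the spectral recovery
#'   rule applied downstream).
#' @param noise_sd Gaussian noise standard deviation, either one value for all
#'   spectral layers or a named vector over
#'   `c("brightness","greenness","wetness","nbr","ndvi")`.
#' @param gap_prob Per-pixel-per-year probability of a no-data gap.
#' @param smooth_sigma Smoothing length (pixels) of the random fields behind
#'   the initial forest and water masks.
#' @param latitude Scene-centre latitude in degrees (metadata used by the
#'   growing-season model).
#' @param class_means Named list of per-class spectral means (`forest`,
#'   `open`, `water`), each a named vector over the five layers.
#' @param disturbance_contrast Named vector of absolute spectral shifts applied
#'   to the forest means at the moment of disturbance. The defaults put the
#'   standardized disturbance-index step at about 6 under the default
#'   `noise_sd`, comfortably above the magnitude threshold of 5.
#' @param seed Integer seed; identical configurations give bit-identical
#'   scenes.
#' @return A `fp_sim_config` list.
#' @export
sim_config <- function(grid_rows = 472L, grid_cols = 472L,
                       pixel_size = 30, n_years = 26L, start_year = 1985L,
                       initial_forest_fraction = 0.70, water_fraction = 0.08,
                       annual_disturbance_rate = 0.002,
                       patch_size_alpha = 1.5,
                       min_patch_px = 12L, max_patch_px = 2000L,
                       recovery_lag = 5L, recovery_rate = 0.10,
                       recovery_target = 0.80,
                       noise_sd = 0.02, gap_prob = 0.05,
                       smooth_sigma = 8, latitude = 55,
                       class_means = NULL, disturbance_contrast = NULL,
                       seed = 1L) {
  assert_scalar_num(grid_rows, "grid_rows", 1)
  assert_scalar_num(grid_cols, "grid_cols", 1)
  assert_scalar_num(pixel_size, "pixel_size", 1e-6)
  assert_scalar_num(n_years, "n_years", 3)
  assert_scalar_num(initial_forest_fraction, "initial_forest_fraction", 0, 1)
  assert_scalar_num(water_fraction, "water_fraction", 0, 1)
  if (initial_forest_fraction + water_fraction > 1) {
    stop_input("initial_forest_fraction + water_fraction must be <= 1")
  }
  assert_scalar_num(annual_disturbance_rate, "annual_disturbance_rate", 0, 1 - 1e-9)
  assert_scalar_num(patch_size_alpha, "patch_size_alpha")
  assert_scalar_num(min_patch_px, "min_patch_px", 1)
  assert_scalar_num(max_patch_px, "max_patch_px", 1)
  if (min_patch_px > max_patch_px) stop_input("min_patch_px must be <= max_patch_px")
  assert_scalar_num(recovery_lag, "recovery_lag", 0)
  assert_scalar_num(recovery_rate, "recovery_rate", 0, 1)
  assert_scalar_num(recovery_target, "recovery_target", 0, 1)
  assert_scalar_num(gap_prob, "gap_prob", 0, 1)
  assert_scalar_num(latitude, "latitude", -90, 90)

  if (is.null(class_means)) {
    class_means <- list(
      forest = c(brightness = 0.30, greenness = 0.50, wetness = -0.05,
                 nbr = 0.60, ndvi = 0.80),
      open   = c(brightness = 0.45, greenness = 0.30, wetness = -0.15,
                 nbr = 0.25, ndvi = 0.45),
      water  = c(brightness = 0.05, greenness = 0.02, wetness = 0.30,
                 nbr = -0.10, ndvi = -0.10)
    )
  }
  if (is.null(disturbance_contrast)) {
    disturbance_contrast <- c(brightness = 0.04, greenness = -0.04,
                              wetness = -0.04, nbr = -0.45, ndvi = -0.35)
  }
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, 5L), SPECTRAL_LAYERS)
  }
  if (!all(SPECTRAL_LAYERS %in% names(noise_sd)) || any(noise_sd < 0)) {
    stop_input("noise_sd must be a single value or a non-negative vector named over all five layers")
  }
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    pixel_size = pixel_size, n_years = as.integer(n_years),
    start_year = as.integer(start_year),
    initial_forest_fraction = initial_forest_fraction,
    water_fraction = water_fraction,
    annual_disturbance_rate = annual_disturbance_rate,
    patch_size_alpha = patch_size_alpha,
    min_patch_px = as.integer(min_patch_px),
    max_patch_px = as.integer(max_patch_px),
    recovery_lag = as.integer(recovery_lag), recovery_rate = recovery_rate,
    recovery_target = recovery_target,
    noise_sd = noise_sd[SPECTRAL_LAYERS], gap_prob = gap_prob,
    smooth_sigma = smooth_sigma, latitude = latitude,
    class_means = class_means, disturbance_contrast = disturbance_contrast,
    seed = as.integer(seed)
  ), class = "fp_sim_config")
}

# Deterministic number of years from event to "forest again", implied by the
# linear NBR ramp: no recovery during the lag, then `recovery_rate` of the
# deficit regained per year until recovery_target * pre-event NBR is reached.
# Returns Inf when recovery never happens.
years_to_recovery <- function(config) {
  nbr_pre <- config$class_means$forest[["nbr"]]
  nbr_dist <- nbr_pre + config$disturbance_contrast[["nbr"]]
  thr <- config$recovery_target * nbr_pre
  if (config$recovery_rate <= 0) return(Inf)
  for (j in seq_len(10000L)) {
    frac <- ramp_fraction(j, config$recovery_lag, config$recovery_rate)
    if (nbr_dist + frac * (nbr_pre - nbr_dist) >= thr - 1e-12) return(j)
  }
  Inf
}

# Fraction of the spectral deficit recovered j years after the event.
ramp_fraction <- function(j, lag, rate) {
  pmin(1, pmax(0, rate * (j - lag + 1)))
}

draw_patch_sizes_prob <- function(config) {
  s <- config$min_patch_px:config$max_patch_px
  p <- s^(-config$patch_size_alpha)
  list(sizes = s, prob = p / sum(p))
}

# Region growing: repeatedly annex a uniformly random eligible frontier pixel
# (8-neighbourhood). Produces irregular blobs with realistic perimeter/area
# variation. May stop early when the patch is locked in.
grow_patch <- function(eligible, nr, nc, seed_px, size) {
  members <- integer(size)
  members[1L] <- seed_px
  n <- 1L
  queued <- integer(0)
  frontier <- setdiff(neighbours8(seed_px, nr, nc), seed_px)
  frontier <- frontier[eligible[frontier]]
  in_set <- new.env(hash = TRUE, size = max(16L, 2L * size))
  assign(as.character(seed_px), TRUE, envir = in_set)
  for (f in frontier) assign(as.character(f), TRUE, envir = in_set)
  while (n < size && length(frontier)) {
    pick <- if (length(frontier) == 1L) 1L else sample.int(length(frontier), 1L)
    cell <- frontier[pick]
    frontier <- frontier[-pick]
    n <- n + 1L
    members[n] <- cell
    nb <- neighbours8(cell, nr, nc)
    nb <- nb[eligible[nb]]
    for (x in nb) {
      k <- as.character(x)
      if (!exists(k, envir = in_set, inherits = FALSE)) {
        assign(k, TRUE, envir = in_set)
        frontier <- c(frontier, x)
      }
    }
  }
  members[seq_len(n)]
}

#' Generate a ground-truth disturbance history
#'
#' Simulates annual forest/non-forest truth maps plus an event log. The
#' initial forest mask is a thresholded smoothed Gaussian random field hitting
#' `initial_forest_fraction`; each subsequent year, disturbance patches grown
#' from random forest seeds (8-neighbour region growing, sizes drawn from the
#' truncated power law) are removed from the forest until the expected
#' disturbed area for the year is met in expectation. Disturbed pixels return
#' to forest at the deterministic year their spectral NBR ramp re-crosses
#' `recovery_target` of the pre-event level (never, if recovery is disabled).
#'
#' @param config A [sim_config()] object.
#' @return A `fp_truth` list with elements `forest` (logical
#'   rows x cols x years array), `water` (logical matrix), `last_event`
#'   (integer array: most recent event year per pixel as of each year),
#'   `change_year`/`recovery_year` matrices for the final most recent event,
#'   `events` (tibble: `year`, `event_id`, `size_drawn`, `size`, `flagged`,
#'   `pixels` list-column of linear cell indices), `years`, and `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "fp_sim_config"))
  set.seed(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols; Tn <- config$n_years
  years <- config$start_year + seq_len(Tn) - 1L

  water_field <- smooth_random_field(nr, nc, config$smooth_sigma)
  if (config$water_fraction > 0) {
    water <- water_field > stats::quantile(water_field, 1 - config$water_fraction)
  } else {
    water <- matrix(FALSE, nr, nc)
  }
  forest_field <- smooth_random_field(nr, nc, config$smooth_sigma)
  land_vals <- forest_field[!water]
  p_forest <- config$initial_forest_fraction / max(1e-12, 1 - config$water_fraction)
  p_forest <- min(1, p_forest)
  thr <- stats::quantile(land_vals, 1 - p_forest)
  forest1 <- forest_field > thr & !water

  rec_elapse <- years_to_recovery(config)
  sz <- draw_patch_sizes_prob(config)

  forest <- array(FALSE, c(nr, nc, Tn))
  last_event <- array(NA_integer_, c(nr, nc, Tn))
  cur_forest <- forest1
  cur_last <- matrix(NA_integer_, nr, nc)
  rec_year <- matrix(NA_integer_, nr, nc)

  ev_year <- integer(0); ev_id <- integer(0); ev_drawn <- integer(0)
  ev_size <- integer(0); ev_flag <- logical(0); ev_pixels <- list()
  next_id <- 1L

  for (y in seq_len(Tn)) {
    if (y > 1L) {
      rec <- !is.na(rec_year) & rec_year == years[y]
      cur_forest[rec] <- TRUE
      target <- config$annual_disturbance_rate * sum(cur_forest)
      if (target > 0) {
        eligible <- cur_forest
        acc <- 0L
        repeat {
          s <- sample(sz$sizes, 1L, prob = sz$prob)
          if (acc + s > target) {
            # unbiased final patch: include with probability (target - acc)/s
            if (stats::runif(1) >= (target - acc) / s) break
          }
          cand <- which(eligible)
          if (!length(cand)) {
            ev_flag[length(ev_flag)] <- TRUE  # demand exceeded remaining forest
            break
          }
          seed_px <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
          cells <- grow_patch(eligible, nr, nc, seed_px, s)
          eligible[cells] <- FALSE
          cur_forest[cells] <- FALSE
          cur_last[cells] <- years[y]
          rec_year[cells] <- if (is.finite(rec_elapse)) years[y] + rec_elapse else NA_integer_
          ev_year <- c(ev_year, years[y]); ev_id <- c(ev_id, next_id)
          ev_drawn <- c(ev_drawn, s); ev_size <- c(ev_size, length(cells))
          ev_flag <- c(ev_flag, length(cells) < s)
          ev_pixels[[next_id]] <- cells
          next_id <- next_id + 1L
          acc <- acc + length(cells)
          if (acc >= target) break
        }
      }
    }
    forest[, , y] <- cur_forest
    last_event[, , y] <- cur_last
  }

  events <- tibble::tibble(
    year = ev_year, event_id = ev_id, size_drawn = ev_drawn,
    size = ev_size, flagged = ev_flag, pixels = ev_pixels[ev_id]
  )
  structure(list(
    forest = forest, water = water, last_event = last_event,
    change_year = cur_last,
    recovery_year = ifelse(!is.na(cur_last) & !is.na(rec_year) &
                             rec_year <= years[Tn], rec_year, NA_integer_),
    events = events, years = years, config = config
  ), class = "fp_truth")
}

#' Render a truth scene into noisy spectral layers
#'
#' Turns a [generate_truth()] result into annual Tasseled-Cap brightness /
#' greenness / wetness, NBR and NDVI layers. Forest, open land and water
#' pixels receive their class means plus Gaussian noise; a disturbance shifts
#' a pixel to the disturbed means from its event year, and from
#' `event_year + recovery_lag` all layers ramp linearly back toward the forest
#' means at `recovery_rate` of the deficit per year. No-data gaps are injected
#' independently with probability `gap_prob` (consistent across layers within
#' a year).
#'
#' @param truth A `fp_truth` object.
#' @param config The same [sim_config()] used to generate it.
#' @return A `fp_scene` list: `layers` (named list of rows x cols x years
#'   arrays), `nodata` (logical array), `years`, `pixel_size`, `origin`,
#'   `latitude`.
#' @export
render_spectral <- function(truth, config) {
  stopifnot(inherits(truth, "fp_truth"), inherits(config, "fp_sim_config"))
  if (!identical(dim(truth$forest)[1:2], c(config$grid_rows, config$grid_cols))) {
    stop_input("truth and config grids disagree")
  }
  set.seed(config$seed + 1L)
  nr <- config$grid_rows; nc <- config$grid_cols; Tn <- config$n_years
  npx <- nr * nc
  cm <- config$class_means
  dist_means <- cm$forest + config$disturbance_contrast[names(cm$forest)]

  layers <- lapply(SPECTRAL_LAYERS, function(l) array(NA_real_, c(nr, nc, Tn)))
  names(layers) <- SPECTRAL_LAYERS
  nodata <- array(FALSE, c(nr, nc, Tn))

  water_v <- as.vector(truth$water)
  forest1_v <- as.vector(truth$forest[, , 1L])

  for (y in seq_len(Tn)) {
    le <- as.vector(truth$last_event[, , y])
    has_event <- !is.na(le)
    j <- truth$years[y] - le
    frac <- numeric(npx)
    frac[has_event] <- ramp_fraction(j[has_event], config$recovery_lag,
                                     config$recovery_rate)
    gaps <- stats::runif(npx) < config$gap_prob
    for (l in SPECTRAL_LAYERS) {
      v <- numeric(npx)
      v[] <- cm$open[[l]]
      v[forest1_v] <- cm$forest[[l]]
      v[water_v] <- cm$water[[l]]
      v[has_event] <- dist_means[[l]] +
        frac[has_event] * (cm$forest[[l]] - dist_means[[l]])
      if (config$noise_sd[[l]] > 0) {
        v <- v + stats::rnorm(npx, sd = config$noise_sd[[l]])
      }
      v[gaps] <- NA_real_
      layers[[l]][, , y] <- v
    }
    nodata[, , y] <- gaps
  }

  new_scene(layers, nodata, truth$years, config$pixel_size,
            latitude = config$latitude)
}

new_scene <- function(layers, nodata, years, pixel_size,
                      origin = c(x = 0, y = 0), latitude = 55) {
  structure(list(layers = layers, nodata = nodata, years = years,
                 pixel_size = pixel_size, origin = origin,
                 latitude = latitude),
            class = "fp_scene")
}

#' @export
print.fp_scene <- function(x, ...) {
  d <- dim(x$layers[[1L]])
  cat(sprintf("<fp_scene> %d x %d px, %d years (%d-%d), layers: %s\n",
              d[1L], d[2L], d[3L], min(x$years), max(x$years),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
print.fp_truth <- function(x, ...) {
  d <- dim(x$forest)
  cat(sprintf("<fp_truth> %d x %d px, %d years, %d events, water %.1f%%\n",
              d[1L], d[2L], d[3L], nrow(x$events), 100 * mean(x$water)))
  invisible(x)
}
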