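#' Annual binary forest maps from pixel trajectories
#'
#' Persisting forest pixels are forest in every year; persisting non-forest
#' pixels never are; changed pixels are forest before their change year,
#' non-forest from the change year, and forest again from the recovery year
#' when one was detected. Background (invalid) pixels are `NA` in all years.
#'
#' @param states A `fp_states` object from [detect_changes()].
#' @param pixel_size Pixel edge length in metres.
#' @return A `fp_maps` list: `maps` (integer rows x cols x years array with
#'   1 = forest, 0 = non-forest, `NA` = background), `years`, `pixel_size`.
#' @export
annual_maps <- function(states, pixel_size = 30) {
  stopifnot(inherits(states, "fp_states"))
  d <- dim(states$state)
  years <- states$years
  Tn <- length(years)
  st <- as.vector(states$state)
  cy <- as.vector(states$change_year)
  ry <- as.vector(states$recovery_year)
  maps <- array(NA_integer_, c(d[1L], d[2L], Tn))
  for (t in seq_len(Tn)) {
    y <- years[t]
    m <- integer(length(st))
    m[st == STATE_PERSISTING_FOREST] <- 1L
    m[st == STATE_PERSISTING_NONFOREST] <- 0L
    ch <- st == STATE_CHANGED
    m[ch] <- ifelse(y < cy[ch], 1L,
             ifelse(!is.na(ry[ch]) & y >= ry[ch], 1L, 0L))
    m[st == STATE_BACKGROUND] <- NA_integer_
    maps[, , t] <- m
  }
  structure(list(maps = maps, years = years, pixel_size = pixel_size),
            class = "fp_maps")
}

#' @export
print.fp_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<fp_maps> %d x %d px, %d years, mean forest %.1f%%\n",
              d[1L], d[2L], d[3L], 100 * mean(x$maps == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Minimum-mapping-unit filter
#'
#' Two sequential passes under the 8-neighbour rule: non-forest patches
#' smaller than the MMU are reclassified as forest, then forest patches
#' smaller than the MMU (on the intermediate result) are reclassified as
#' non-forest. At the 0.09 ha grain a 1 ha MMU keeps patches of 12 or more
#' pixels (11 px = 0.99 ha is below the unit). Background pixels take part in
#' no patch. The filter is idempotent.
#'
#' @param map Integer matrix with 1 = forest, 0 = non-forest, `NA`
#'   background.
#' @param mmu_area_ha Minimum mapping unit in hectares.
#' @param pixel_size Pixel edge length in metres.
#' @param connectivity Neighbourhood rule (8, the map standard).
#' @return Filtered map matrix.
#' @export
mmu_filter <- function(map, mmu_area_ha = 1, pixel_size = 30,
                       connectivity = 8) {
  stopifnot(is.matrix(map))
  min_px <- ceiling(mmu_area_ha * 1e4 / pixel_size^2)
  reclass_small <- function(m, from, to) {
    lab <- label_matrix(!is.na(m) & m == from, connectivity)
    if (max(lab) == 0L) return(m)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_px)
    if (length(small)) m[lab %in% small] <- to
    m
  }
  map <- reclass_small(map, 0L, 1L)   # small non-forest -> forest
  map <- reclass_small(map, 1L, 0L)   # small forest -> non-forest
  map
}

#' Apply the MMU filter to every year of a map series
#'
#' @param maps A `fp_maps` object.
#' @inheritParams mmu_filter
#' @return A `fp_maps` object with filtered annual maps.
#' @export
mmu_filter_series <- function(maps, mmu_area_ha = 1, connectivity = 8) {
  stopifnot(inherits(maps, "fp_maps"))
  for (t in seq_along(maps$years)) {
    maps$maps[, , t] <- mmu_filter(maps$maps[, , t], mmu_area_ha,
                                   maps$pixel_size, connectivity)
  }
  maps
}

#' Tile a scene into a grid of landscapes at a nominal extent
#'
#' Square, non-overlapping, axis-aligned windows whose side is
#' `round(sqrt(extent) / pixel_size)` pixels (745, 527, 333 and 236 px for
#' the 50,000 / 25,000 / 10,000 / 5,000 ha extents at 30 m). Partial windows
#' at the scene margins are dropped. Row/column offsets are 0-based and
#' windows are half-open; centroids are in scene projection metres referring
#' to pixel centres (y increases upward from the top-left origin).
#'
#' @param scene_dim Integer vector `c(rows, cols)` of the scene.
#' @param nominal_extent_ha Nominal landscape extent in hectares.
#' @param pixel_size Pixel edge length in metres.
#' @param origin Projection coordinates `c(x, y)` of the top-left corner.
#' @return A `fp_grid` tibble: `landscape_id`, `extent_ha`, `side_px`,
#'   `row0`, `col0`, `centroid_x`, `centroid_y`.
#' @export
build_grid <- function(scene_dim, nominal_extent_ha, pixel_size = 30,
                       origin = c(x = 0, y = 0)) {
  stopifnot(length(scene_dim) == 2L, all(scene_dim > 0))
  side <- round(sqrt(nominal_extent_ha * 1e4) / pixel_size)
  n_r <- scene_dim[1L] %/% side
  n_c <- scene_dim[2L] %/% side
  if (n_r < 1L || n_c < 1L) {
    warning("scene smaller than one landscape window; empty grid")
    return(empty_grid(nominal_extent_ha, side))
  }
  g <- expand.grid(ri = seq_len(n_r) - 1L, ci = seq_len(n_c) - 1L)
  out <- tibble::tibble(
    landscape_id = sprintf("E%d_%03d", as.integer(nominal_extent_ha),
                           seq_len(nrow(g))),
    extent_ha = nominal_extent_ha,
    side_px = as.integer(side),
    row0 = as.integer(g$ri * side),
    col0 = as.integer(g$ci * side),
    centroid_x = origin[["x"]] + (g$ci * side + side / 2) * pixel_size,
    centroid_y = origin[["y"]] - (g$ri * side + side / 2) * pixel_size
  )
  class(out) <- c("fp_grid", class(out))
  out
}

empty_grid <- function(extent, side) {
  out <- tibble::tibble(landscape_id = character(0), extent_ha = numeric(0),
                        side_px = integer(0), row0 = integer(0),
                        col0 = integer(0), centroid_x = numeric(0),
                        centroid_y = numeric(0))
  class(out) <- c("fp_grid", class(out))
  out
}

window_cells <- function(grid_row, mat) {
  rows <- grid_row$row0 + seq_len(grid_row$side_px)
  cols <- grid_row$col0 + seq_len(grid_row$side_px)
  mat[rows, cols, drop = FALSE]
}

#' Apply the landscape selection criteria
#'
#' A landscape is kept when at most 25% of it is background (no-data), at
#' least 10% falls in the target zone, and at most 1% is under agricultural
#' influence. Every rejection carries its reason. Water is not background: it
#' is persistent non-forest land cover and stays in the landscape.
#'
#' @param grid A `fp_grid` tibble.
#' @param background Logical matrix of background (invalid / no-data) pixels.
#' @param zone Optional logical matrix of target-zone membership (default:
#'   everywhere).
#' @param agriculture Optional logical matrix of agricultural influence
#'   (default: nowhere).
#' @param max_background,min_zone,max_agriculture Selection thresholds as
#'   proportions.
#' @return The grid with `background_frac`, `zone_frac`, `agriculture_frac`,
#'   `selected` and `reject_reason` columns.
#' @export
select_landscapes <- function(grid, background, zone = NULL,
                              agriculture = NULL,
                              max_background = 0.25, min_zone = 0.10,
                              max_agriculture = 0.01) {
  stopifnot(is.matrix(background))
  frac_in <- function(mat) {
    if (is.null(mat)) return(NULL)
    vapply(seq_len(nrow(grid)), function(i) {
      mean(window_cells(grid[i, ], mat))
    }, numeric(1))
  }
  bg <- frac_in(background)
  zn <- frac_in(zone) %||% rep(1, nrow(grid))
  ag <- frac_in(agriculture) %||% rep(0, nrow(grid))
  reason <- rep(NA_character_, nrow(grid))
  reason[ag > max_agriculture] <- "agriculture"
  reason[zn < min_zone] <- "zone"
  reason[bg > max_background] <- "background"
  out <- grid
  out$background_frac <- bg
  out$zone_frac <- zn
  out$agriculture_frac <- ag
  out$selected <- is.na(reason)
  out$reject_reason <- reason
  out
}
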