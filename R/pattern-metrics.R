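#' Label forest patches
#'
#' Maximal 8-connected components of forest pixels; background (`NA`) pixels
#' take part in no patch.
#'
#' @param map Integer/logical matrix: 1/`TRUE` = forest, 0/`FALSE` =
#'   non-forest, `NA` = background.
#' @param connectivity 8 (map standard) or 4.
#' @param pixel_size Pixel edge length in metres.
#' @return List with `labels` (integer matrix, 0 outside patches),
#'   `sizes_px` and `areas_ha` per patch.
#' @export
label_patches <- function(map, connectivity = 8, pixel_size = 30) {
  lab <- label_matrix(!is.na(map) & map == 1, connectivity)
  sizes <- if (max(lab) > 0L) tabulate(lab[lab > 0L]) else integer(0)
  list(labels = lab, sizes_px = sizes,
       areas_ha = sizes * pixel_size^2 / 1e4)
}

land_px <- function(map) {
  n <- sum(!is.na(map))
  if (n == 0L) stop_input("landscape is entirely background")
  n
}

#' Forest cover (%)
#'
#' Total forested area divided by total landscape area, times 100. The
#' landscape area excludes background (no-data) pixels but includes water,
#' which is persistent non-forest land cover.
#'
#' @inheritParams label_patches
#' @return Percentage in `[0, 100]`.
#' @export
forest_cover <- function(map) {
  100 * sum(map == 1L, na.rm = TRUE) / land_px(map)
}

#' Largest patch index (%)
#'
#' Area of the largest forest patch divided by total landscape area, times
#' 100; 0 when the landscape holds no forest.
#'
#' @inheritParams label_patches
#' @return Percentage in `[0, 100]`.
#' @export
largest_patch_index <- function(map, connectivity = 8) {
  n <- land_px(map)
  lp <- label_patches(map, connectivity)
  if (!length(lp$sizes_px)) return(0)
  100 * max(lp$sizes_px) / n
}

#' Forest edge density (m per ha)
#'
#' Total forest patch perimeter divided by landscape area. The perimeter
#' counts every forest cell face not shared with another forest cell: faces
#' against non-forest, against background, and (by default) against the
#' window boundary, i.e. patch-perimeter semantics. Set
#' `include_boundary = FALSE` for the convention that ignores the landscape
#' boundary.
#'
#' @inheritParams label_patches
#' @param include_boundary Count faces on the window boundary as edge.
#' @return Edge density in m per ha (>= 0).
#' @export
edge_density <- function(map, pixel_size = 30, include_boundary = TRUE) {
  n <- land_px(map)
  f <- !is.na(map) & map == 1L
  mode(f) <- "integer"
  pad <- if (include_boundary) 0L else 1L   # pad=1 mirrors forest: no edge there
  faces <- 0L
  for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- shift_mat(f, s[1L], s[2L], fill = pad)
    faces <- faces + sum(f == 1L & nb == 0L)
  }
  area_ha <- n * pixel_size^2 / 1e4
  pixel_size * faces / area_ha
}

#' Core forest cover (%)
#'
#' A forest pixel is core when the Euclidean distance from its centre to the
#' centre of the nearest non-forest, background or outside-window pixel
#' exceeds `edge_depth` (120 m, four Landsat pixels). The window boundary
#' counts as edge. `metric = "chebyshev"` instead requires every pixel within
#' a Chebyshev radius of `edge_depth / pixel_size` to be forest (4-pixel
#' erosion).
#'
#' @inheritParams label_patches
#' @param edge_depth Edge influence depth in metres.
#' @param metric `"euclidean"` (default) or `"chebyshev"`.
#' @return Percentage in `[0, 100]`.
#' @export
core_forest_cover <- function(map, pixel_size = 30, edge_depth = 120,
                              metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  n <- land_px(map)
  f <- !is.na(map) & map == 1L
  if (!any(f)) return(0)
  if (metric == "euclidean") {
    pad <- matrix(0, nrow(f) + 2L, ncol(f) + 2L)
    pad[2:(nrow(f) + 1L), 2:(ncol(f) + 1L)] <- f
    dm <- EBImage::distmap(pad, metric = "euclidean")
    dmat <- matrix(dm, nrow(pad), ncol(pad))[2:(nrow(f) + 1L),
                                             2:(ncol(f) + 1L), drop = FALSE]
    core <- f & (dmat * pixel_size > edge_depth)
  } else {
    k <- floor(edge_depth / pixel_size)
    core <- f
    mode(core) <- "integer"
    for (i in seq_len(k)) {
      acc <- core
      for (dr in -1:1) for (dc in -1:1) {
        if (dr || dc) acc <- acc & shift_mat(core, dr, dc, fill = 0L)
      }
      core <- acc
      mode(core) <- "integer"
    }
    core <- core == 1L
  }
  100 * sum(core) / n
}

#' Annual landscape pattern indices
#'
#' Computes the four class-level pattern indices -- forest cover, largest
#' patch index, edge density and core forest cover -- for every landscape
#' window and every year, mirroring the annualized pattern-index tables the
#' method was designed to populate.
#'
#' @param maps A `fp_maps` series (post-MMU).
#' @param grid A `fp_grid` tibble (use the `selected` landscapes from
#'   [select_landscapes()]).
#' @param water Optional logical matrix of permanent water (reported as
#'   `water_frac`).
#' @param stratum Optional matrix of stratum (ecozone-like) labels; the modal
#'   value per window is reported.
#' @param edge_depth Core edge depth in metres.
#' @param include_boundary Edge-density boundary convention, see
#'   [edge_density()].
#' @param core_metric Core distance convention, see [core_forest_cover()].
#' @return A `fp_index_table` tibble with one row per landscape-year:
#'   `landscape_id`, `extent_ha`, `year`, `centroid_x`, `centroid_y`,
#'   `stratum`, `forest_cover`, `lpi`, `edge_density`, `core_cover`,
#'   `background_frac`, `water_frac`.
#' @export
landscape_metrics <- function(maps, grid, water = NULL, stratum = NULL,
                              edge_depth = 120, include_boundary = TRUE,
                              core_metric = "euclidean") {
  stopifnot(inherits(maps, "fp_maps"))
  px <- maps$pixel_size
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    wmask <- if (is.null(water)) NULL else window_cells(g, water)
    strat <- if (is.null(stratum)) "all" else as.character(modal_value(window_cells(g, stratum)))
    res <- lapply(seq_along(maps$years), function(t) {
      sub <- window_cells(g, maps$maps[, , t])
      tibble::tibble(
        landscape_id = g$landscape_id,
        extent_ha = g$extent_ha,
        year = maps$years[t],
        centroid_x = g$centroid_x,
        centroid_y = g$centroid_y,
        stratum = strat,
        forest_cover = forest_cover(sub),
        lpi = largest_patch_index(sub),
        edge_density = edge_density(sub, px, include_boundary),
        core_cover = core_forest_cover(sub, px, edge_depth, core_metric),
        background_frac = mean(is.na(sub)),
        water_frac = if (is.null(wmask)) NA_real_ else mean(wmask)
      )
    })
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fp_index_table", class(out))
  out
}
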