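# Raster and table I/O. Rasters are written as multi-page 32-bit-float TIFF
# (one file per layer, one page per year) with an affine [0,1] encoding and a
# JSON sidecar holding the grid metadata (years, pixel size, origin, latitude,
# per-layer offset/scale). No-data cells are restored from a companion mask
# layer. Round-trips are exact up to float32 quantization of the layer range.

encode_layer <- function(a) {
  v <- as.vector(a)
  fin <- is.finite(v)
  if (!any(fin)) {
    off <- 0; sc <- 1
  } else {
    off <- min(v[fin])
    sc <- max(v[fin]) - off
    if (sc <= 0) sc <- 1
  }
  enc <- (v - off) / sc
  enc[!fin] <- 0
  list(data = array(enc, dim(a)), offset = off, scale = sc)
}

write_pages <- function(a, path) {
  pages <- lapply(seq_len(dim(a)[3L]), function(t) a[, , t])
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
}

read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), c(dim(pages[[1L]])[1:2], length(pages)))
}

#' Write a spectral scene to disk
#'
#' One multi-page float TIFF per layer plus `nodata.tif` and a `scene.json`
#' sidecar with the grid metadata and the affine encoding of each layer.
#'
#' @param scene A `fp_scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "fp_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(type = "fp_scene", years = scene$years,
               pixel_size = scene$pixel_size,
               origin = as.list(scene$origin), latitude = scene$latitude,
               dim = dim(scene$layers[[1L]]), layers = list())
  for (l in names(scene$layers)) {
    enc <- encode_layer(scene$layers[[l]])
    write_pages(enc$data, file.path(dir, paste0(l, ".tif")))
    meta$layers[[l]] <- list(offset = enc$offset, scale = enc$scale)
  }
  write_pages((scene$nodata) * 1, file.path(dir, "nodata.tif"))
  jsonlite::write_json(meta, file.path(dir, "scene.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a spectral scene written by [write_scene()]
#'
#' @param dir Directory holding the layer TIFFs and `scene.json`.
#' @return A `fp_scene`.
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  nodata <- read_pages(file.path(dir, "nodata.tif")) > 0.5
  layers <- lapply(names(meta$layers), function(l) {
    a <- read_pages(file.path(dir, paste0(l, ".tif")))
    a <- a * meta$layers[[l]]$scale + meta$layers[[l]]$offset
    a[nodata] <- NA_real_
    a
  })
  names(layers) <- names(meta$layers)
  new_scene(layers, nodata, meta$years, meta$pixel_size,
            unlist(meta$origin), meta$latitude)
}

#' Write an annual forest map series
#'
#' Forest/non-forest/background maps as one multi-page TIFF plus a JSON
#' sidecar.
#'
#' @param maps A `fp_maps` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_map_series <- function(maps, dir) {
  stopifnot(inherits(maps, "fp_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # background 0, nonforest 0.5, forest 1
  enc <- maps$maps * 0.5 + 0.5
  enc[is.na(enc)] <- 0
  write_pages(enc, file.path(dir, "forest.tif"))
  jsonlite::write_json(list(type = "fp_maps", years = maps$years,
                            pixel_size = maps$pixel_size),
                       file.path(dir, "maps.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a forest map series written by [write_map_series()]
#' @param dir Directory holding `forest.tif` and `maps.json`.
#' @return A `fp_maps` object.
#' @export
read_map_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "maps.json"),
                              simplifyVector = TRUE)
  a <- read_pages(file.path(dir, "forest.tif"))
  m <- array(NA_integer_, dim(a))
  m[a > 0.75] <- 1L
  m[a > 0.25 & a <= 0.75] <- 0L
  structure(list(maps = m, years = meta$years, pixel_size = meta$pixel_size),
            class = "fp_maps")
}

#' Read a stack of single-band rasters on one grid
#'
#' Reads each TIFF and stacks them along a third axis; a file whose shape
#' disagrees with the first is an error naming the file. Values are returned
#' as stored.
#'
#' @param paths Character vector of TIFF paths, one per year.
#' @return Numeric array rows x cols x length(paths).
#' @export
read_raster_series <- function(paths) {
  stopifnot(length(paths) >= 1L)
  first <- tiff::readTIFF(paths[1L])
  out <- array(NA_real_, c(dim(first)[1:2], length(paths)))
  out[, , 1L] <- first
  for (i in seq_along(paths)[-1L]) {
    a <- tiff::readTIFF(paths[i])
    if (!identical(dim(a)[1:2], dim(first)[1:2])) {
      stop_input("raster shape mismatch in file: ", paths[i])
    }
    out[, , i] <- a
  }
  out
}

#' Write an annualized pattern-index table to CSV
#'
#' One row per landscape-year with a stable column order; duplicate
#' (landscape, year) rows are an error.
#'
#' @param index_table A `fp_index_table` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(index_table, path) {
  cols <- c("landscape_id", "extent_ha", "year", "centroid_x", "centroid_y",
            "stratum", "forest_cover", "lpi", "edge_density", "core_cover",
            "background_frac", "water_frac")
  missing <- setdiff(cols, names(index_table))
  if (length(missing)) stop_input("index table lacks columns: ",
                                  paste(missing, collapse = ", "))
  if (anyDuplicated(index_table[, c("landscape_id", "year")])) {
    stop_input("duplicate (landscape_id, year) rows")
  }
  utils::write.csv(as.data.frame(index_table)[, cols], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pattern-index table written by [write_index_table()]
#' @param path CSV path.
#' @return A `fp_index_table` tibble.
#' @export
read_index_table <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8",
                                           stringsAsFactors = FALSE))
  out$stratum <- as.character(out$stratum)
  class(out) <- c("fp_index_table", class(out))
  out
}
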