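#' Assemble a full pipeline configuration
#'
#' Bundles every stage's parameters with a single global seed. Unknown keys
#' in any block are rejected. The resolved configuration is written beside
#' the outputs of every [run_pipeline()] call for provenance.
#'
#' @param sim A [sim_config()] (the simulator defines the scene; pass
#'   `NULL` and supply `scene` to [run_pipeline()] to analyse external data).
#' @param di A [di_params()].
#' @param extents Landscape extents in hectares.
#' @param selection List of selection thresholds: `max_background`,
#'   `min_zone`, `max_agriculture`.
#' @param trend List of trend settings: `bootstrap_B`, `block_length`,
#'   `alpha`, `high_prob`, `stratum_B`.
#' @param autocorr List of autocorrelation settings: `bin_width`,
#'   `min_pairs`, `max_lag`.
#' @param seed Global seed; every source of randomness in the run flows from
#'   it.
#' @param out_dir Optional output directory for rasters, CSVs and the
#'   resolved configuration.
#' @return A `fp_pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), di = di_params(),
                            extents = c(5000, 10000, 25000, 50000),
                            selection = list(), trend = list(),
                            autocorr = list(), seed = 1L, out_dir = NULL) {
  fill <- function(user, defaults, block) {
    extra <- setdiff(names(user), names(defaults))
    if (length(extra)) {
      stop_input("unknown ", block, " option(s): ", paste(extra, collapse = ", "))
    }
    utils::modifyList(defaults, user)
  }
  structure(list(
    sim = sim, di = di, extents = extents,
    selection = fill(selection,
                     list(max_background = 0.25, min_zone = 0.10,
                          max_agriculture = 0.01), "selection"),
    trend = fill(trend,
                 list(bootstrap_B = 500L, block_length = 3L, alpha = 0.05,
                      high_prob = 0.90, stratum_B = 1000L), "trend"),
    autocorr = fill(autocorr,
                    list(bin_width = NULL, min_pairs = 1000L, max_lag = 5L),
                    "autocorr"),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "fp_pipeline_config")
}

#' Run the full landscape-pattern pipeline
#'
#' Stages, in order: simulate (truth + spectral rendering), composite
#' (gap interpolation + validity screen), detect (DI trajectory
#' classification + NBR recovery), maps (annual forest maps + MMU filter),
#' metrics (pattern indices at every extent), autocorrelation (spatial
#' correlogram + temporal ACF), trends (per-landscape and per-stratum), and
#' change classification (at the largest extent present). With `out_dir`
#' set, every tabular artifact and raster series is written beside the
#' resolved configuration.
#'
#' @param config A [pipeline_config()].
#' @param scene Optional externally supplied `fp_scene` (skips simulation).
#' @param stratum,zone,agriculture Optional matrices on the scene grid.
#' @param quiet Suppress stage messages.
#' @return List with `truth`, `scene`, `composite`, `states`, `maps`,
#'   `grid`, `index_table`, `trends`, `classes`, `stratum_trends`,
#'   `correlogram`, `acf`, `detection` (when truth is available).
#' @export
run_pipeline <- function(config, scene = NULL, stratum = NULL, zone = NULL,
                         agriculture = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "fp_pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  set.seed(config$seed)

  truth <- NULL
  if (is.null(scene)) {
    if (is.null(config$sim)) stop_input("no scene and no simulator configured")
    sim <- config$sim
    sim$seed <- config$seed
    say("simulate: ", sim$grid_rows, " x ", sim$grid_cols, " px, ",
        sim$n_years, " years")
    truth <- generate_truth(sim)
    scene <- render_spectral(truth, sim)
  }

  say("composite: gap interpolation and validity screen")
  comp <- composite_scene(scene)

  say("detect: DI trajectories and NBR recovery")
  states <- detect_changes(comp$scene, config$di, valid = comp$valid)

  say("maps: annual forest maps and MMU filter")
  maps <- annual_maps(states, scene$pixel_size)
  maps <- mmu_filter_series(maps)

  background <- !comp$valid
  dims <- dim(maps$maps)[1:2]
  grids <- lapply(config$extents, function(e) {
    g <- build_grid(dims, e, scene$pixel_size, scene$origin)
    if (nrow(g) == 0L) return(g)
    select_landscapes(g, background, zone, agriculture,
                      config$selection$max_background,
                      config$selection$min_zone,
                      config$selection$max_agriculture)
  })
  grid <- dplyr::bind_rows(grids)
  sel <- grid[grid$selected %||% TRUE, , drop = FALSE]
  if (nrow(sel) == 0L) stop_input("no landscape passed the selection criteria")

  say("metrics: ", nrow(sel), " landscapes x ", length(scene$years), " years")
  water <- if (!is.null(truth)) truth$water else NULL
  index_table <- landscape_metrics(maps, sel, water = water, stratum = stratum)

  say("autocorrelation")
  big_extent <- max(index_table$extent_ha)
  one_year <- dplyr::filter(index_table, .data$extent_ha == big_extent,
                            .data$year == max(.data$year))
  correlogram <- if (nrow(one_year) >= 3L) {
    withCallingHandlers(
      spatial_correlogram(one_year, "forest_cover",
                          bin_width = config$autocorr$bin_width,
                          min_pairs = config$autocorr$min_pairs),
      warning = function(w) invokeRestart("muffleWarning"))
  } else {
    say("too few landscapes for a correlogram; skipping")
    NULL
  }
  acf_tbl <- acf_by_landscape(index_table, "forest_cover",
                              config$autocorr$max_lag, extent = big_extent)
  acf_sum <- suppressWarnings(acf_significance(acf_tbl))

  say("trends and change classification")
  trends <- landscape_trends(index_table, "forest_cover", extent = big_extent,
                             B = config$trend$bootstrap_B,
                             block_length = config$trend$block_length)
  classes <- classify_change(trends, config$trend$alpha,
                             config$trend$high_prob)
  strat <- stratum_trends(index_table, "forest_cover", extent = big_extent,
                          B = config$trend$stratum_B)

  detection <- if (!is.null(truth)) evaluate_detection(truth, states) else NULL

  out <- list(truth = truth, scene = scene, composite = comp,
              states = states, maps = maps, grid = grid,
              index_table = index_table, trends = trends, classes = classes,
              stratum_trends = strat, correlogram = correlogram,
              acf = acf_sum, detection = detection)

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    say("writing artifacts to ", d)
    write_scene(scene, file.path(d, "scene"))
    write_map_series(maps, file.path(d, "maps"))
    write_index_table(index_table, file.path(d, "index_table.csv"))
    utils::write.csv(as.data.frame(grid), file.path(d, "grid.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(classes), file.path(d, "trends.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(strat), file.path(d, "stratum_trends.csv"),
                     row.names = FALSE)
    if (!is.null(correlogram)) {
      utils::write.csv(as.data.frame(correlogram),
                       file.path(d, "correlogram.csv"), row.names = FALSE)
    }
    utils::write.csv(as.data.frame(acf_sum), file.path(d, "acf.csv"),
                     row.names = FALSE)
    if (!is.null(detection)) {
      utils::write.csv(as.data.frame(detection),
                       file.path(d, "detection.csv"), row.names = FALSE)
    }
    write_resolved_config(config, file.path(d, "config.yaml"))
  }
  out
}

# Serialise the resolved configuration (provenance record beside outputs).
write_resolved_config <- function(config, path) {
  ser <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::write_yaml(ser, path)
  invisible(path)
}
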