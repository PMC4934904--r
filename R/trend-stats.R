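#' Mann-Kendall test for monotonic trend
#'
#' Nonparametric trend test based on the signs of all pairwise differences:
#' `S = sum_{i<j} sign(x_j - x_i)`. Tau is tie-corrected (tau-b), the
#' variance of `S` carries the tie correction, and the two-sided p-value uses
#' the normal approximation with continuity correction. A constant series
#' returns tau 0 and p 1.
#'
#' @param x Numeric series in time order (n >= 4).
#' @param years Time points (defaults to `1:n`; annual, so never tied).
#' @return A `fp_mk` object with elements `s`, `tau`, `var_s`, `z`,
#'   `p_value`, `n`.
#' @export
mann_kendall <- function(x, years = seq_along(x)) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop_input("Mann-Kendall needs at least 4 observations")
  if (anyNA(x)) stop_input("series contains NA")
  d <- outer(x, x, "-")
  S <- as.integer(sum(sign(d[lower.tri(d)])))  # d[j, i] = x_j - x_i, j > i
  ties <- table(x)
  ties <- ties[ties > 1L]
  D <- n * (n - 1) / 2
  t1 <- sum(ties * (ties - 1) / 2)
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  denom <- sqrt((D - t1) * D)
  tau <- if (denom > 0) S / denom else 0
  if (var_s <= 0) {
    z <- 0; p <- 1
  } else {
    z <- if (S > 0) (S - 1) / sqrt(var_s) else if (S < 0) (S + 1) / sqrt(var_s) else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(s = S, tau = tau, var_s = var_s, z = z, p_value = p, n = n,
                 years = years),
            class = "fp_mk")
}

#' @export
print.fp_mk <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %d, tau = %.3f, p = %.4g (n = %d)\n",
              x$s, x$tau, x$p_value, x$n))
  invisible(x)
}

# kendall tau-b, minimal and fast, for bootstrap replicates
tau_b <- function(x) {
  n <- length(x)
  d <- outer(x, x, "-")
  S <- sum(sign(d[lower.tri(d)]))
  ties <- table(x)
  ties <- ties[ties > 1L]
  D <- n * (n - 1) / 2
  denom <- sqrt((D - sum(ties * (ties - 1) / 2)) * D)
  if (denom > 0) S / denom else 0
}

#' Theil-Sen robust line
#'
#' Slope is the median of all pairwise slopes
#' `(x_j - x_i) / (t_j - t_i)`, the intercept the median of
#' `x_t - slope * t`.
#'
#' @param x Numeric series (n >= 2).
#' @param years Time points (distinct).
#' @return A `fp_theilsen` object with `slope`, `intercept`, `n`.
#' @export
theil_sen <- function(x, years = seq_along(x)) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop_input("Theil-Sen needs at least 2 observations")
  if (anyNA(x)) stop_input("series contains NA")
  dt <- outer(years, years, "-")
  dx <- outer(x, x, "-")
  lt <- lower.tri(dt)
  slope <- stats::median(dx[lt] / dt[lt])
  intercept <- stats::median(x - slope * years)
  structure(list(slope = slope, intercept = intercept, n = n),
            class = "fp_theilsen")
}

#' @export
print.fp_theilsen <- function(x, ...) {
  cat(sprintf("Theil-Sen: slope = %.4g, intercept = %.4g (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

#' Block-bootstrap confidence interval for Kendall's tau
#'
#' Circular moving-block bootstrap: blocks of `block_length` consecutive
#' years (wrapping at the series end) are drawn with replacement, ordered by
#' their position in the original series (so replicates preserve the series'
#' time order), and concatenated until the series length is reached; tau is
#' recomputed per replicate and the percentile interval returned. The block
#' length default of 3 spans the up-to-two-year serial correlation typical of
#' these index series.
#'
#' @param x Numeric series (n >= 2 * block_length).
#' @param B Bootstrap replicates (500; fewer than 100 draws a warning).
#' @param block_length Block length in years.
#' @param level Confidence level.
#' @param statistic Statistic to bootstrap (defaults to tau-b).
#' @return Named vector `c(low, high)`.
#' @export
block_bootstrap_ci <- function(x, B = 500L, block_length = 3L, level = 0.95,
                               statistic = tau_b) {
  n <- length(x)
  if (n < 2L * block_length) stop_input("series too short for the block length")
  if (B < 100L) warning("fewer than 100 bootstrap repetitions")
  nb <- ceiling(n / block_length)
  reps <- vapply(seq_len(B), function(b) {
    starts <- sort(sample.int(n, nb, replace = TRUE))
    idx <- as.vector(vapply(starts, function(s) {
      ((s - 1L + 0:(block_length - 1L)) %% n) + 1L
    }, integer(block_length)))[seq_len(n)]
    statistic(x[idx])
  }, numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE)
  c(low = q[1L], high = q[2L])
}

#' Per-landscape trend tests on an index table
#'
#' Runs [mann_kendall()] and [theil_sen()] (plus, optionally, the
#' block-bootstrap tau interval) on one index's annual series for every
#' landscape.
#'
#' @param index_table A `fp_index_table` tibble from [landscape_metrics()].
#' @param index Column to test (`"forest_cover"`, `"lpi"`, `"edge_density"`,
#'   `"core_cover"`).
#' @param extent Optional extent filter in hectares.
#' @param bootstrap Compute the block-bootstrap tau interval.
#' @param B,block_length,level Bootstrap settings.
#' @return A `fp_trend_table` tibble with one row per landscape: `s`, `tau`,
#'   `p_value`, `ci_low`, `ci_high`, `sen_slope`, `sen_intercept`, `n_years`.
#' @export
landscape_trends <- function(index_table, index = "forest_cover",
                             extent = NULL, bootstrap = TRUE, B = 500L,
                             block_length = 3L, level = 0.95) {
  stopifnot(index %in% names(index_table))
  tbl <- index_table
  if (!is.null(extent)) tbl <- dplyr::filter(tbl, .data$extent_ha == extent)
  out <- tbl |>
    dplyr::group_by(.data$landscape_id, .data$extent_ha, .data$stratum) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::summarise(res = {
      x <- .data[[index]]
      yr <- .data$year
      mk <- mann_kendall(x, yr)
      ts <- theil_sen(x, yr)
      ci <- if (bootstrap) block_bootstrap_ci(x, B, block_length, level)
            else c(low = NA_real_, high = NA_real_)
      list(tibble::tibble(
        s = mk$s, tau = mk$tau, p_value = mk$p_value,
        ci_low = ci[["low"]], ci_high = ci[["high"]],
        sen_slope = ts$slope, sen_intercept = ts$intercept,
        n_years = mk$n))
    }, .groups = "drop") |>
    tidyr::unnest("res")
  out$index <- index
  class(out) <- c("fp_trend_table", class(out))
  out
}

#' Stratum-level trend summaries
#'
#' Two complementary views per stratum, following the ecozone treatment:
#' (a) the annual cross-landscape median series is tested with the
#' Mann-Kendall test and fitted with a Theil-Sen line; (b) the per-landscape
#' Theil-Sen slopes are summarised by their median with a bootstrap
#' percentile confidence interval over landscapes.
#'
#' @param index_table A `fp_index_table`.
#' @param index Index column to summarise.
#' @param extent Optional extent filter.
#' @param B Bootstrap repetitions over landscapes (default 1000).
#' @param level Confidence level.
#' @param min_landscapes Strata with fewer landscapes are flagged `low_n`.
#' @return Tibble with one row per stratum: `n_landscapes`, `low_n`,
#'   `median_mk_s`, `median_mk_tau`, `median_mk_p`, `median_series_slope`,
#'   `median_slope`, `ci_low`, `ci_high`.
#' @export
stratum_trends <- function(index_table, index = "forest_cover", extent = NULL,
                           B = 1000L, level = 0.95, min_landscapes = 5L) {
  tbl <- index_table
  if (!is.null(extent)) tbl <- dplyr::filter(tbl, .data$extent_ha == extent)
  per_landscape <- landscape_trends(tbl, index, bootstrap = FALSE)
  med_series <- tbl |>
    dplyr::group_by(.data$stratum, .data$year) |>
    dplyr::summarise(med = stats::median(.data[[index]]), .groups = "drop")
  a <- (1 - level) / 2
  res <- lapply(split(per_landscape, per_landscape$stratum), function(pl) {
    st <- pl$stratum[1L]
    ms <- med_series[med_series$stratum == st, ]
    ms <- ms[order(ms$year), ]
    mk <- mann_kendall(ms$med, ms$year)
    ts <- theil_sen(ms$med, ms$year)
    slopes <- pl$sen_slope
    boot <- vapply(seq_len(B), function(b) {
      stats::median(slopes[sample.int(length(slopes), replace = TRUE)])
    }, numeric(1))
    ci <- stats::quantile(boot, c(a, 1 - a), names = FALSE)
    tibble::tibble(
      stratum = st, index = index, n_landscapes = nrow(pl),
      low_n = nrow(pl) < min_landscapes,
      median_mk_s = mk$s, median_mk_tau = mk$tau, median_mk_p = mk$p_value,
      median_series_slope = ts$slope,
      median_slope = stats::median(slopes),
      ci_low = ci[1L], ci_high = ci[2L])
  })
  dplyr::bind_rows(res)
}

#' Classify landscapes by change magnitude
#'
#' Landscapes without a significant Mann-Kendall forest-cover trend are
#' `no_change`. Significant landscapes are ranked by the magnitude of their
#' Theil-Sen slope: those at or above the 90th percentile (linear
#' interpolation, inclusive upper tail) are `high` magnitude change, the rest
#' `moderate`.
#'
#' @param trends A `fp_trend_table` from [landscape_trends()], one row per
#'   landscape.
#' @param alpha Significance level (0.05).
#' @param prob Percentile split (0.90).
#' @param ranking `"absolute"` (default, |slope|) or `"signed"`.
#' @return The input with a `class` factor column
#'   (`no_change`/`moderate`/`high`).
#' @export
classify_change <- function(trends, alpha = 0.05, prob = 0.90,
                            ranking = c("absolute", "signed")) {
  ranking <- match.arg(ranking)
  sig <- trends$p_value < alpha
  score <- if (ranking == "absolute") abs(trends$sen_slope) else trends$sen_slope
  cls <- rep("no_change", nrow(trends))
  if (any(sig)) {
    if (sum(sig) < 10L) {
      warning("fewer than 10 significant landscapes; percentile split is unstable")
    }
    cut <- stats::quantile(score[sig], prob, names = FALSE, type = 7)
    cls[sig] <- ifelse(score[sig] >= cut, "high", "moderate")
  }
  trends$class <- factor(cls, levels = c("no_change", "moderate", "high"))
  trends
}
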