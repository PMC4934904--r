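#' Moran's I
#'
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`
#' and `W = sum_ij w_ij`. Weights must be symmetric; values with zero
#' variance are an error (the statistic is undefined).
#'
#' @param x Numeric values, one per unit (n >= 3).
#' @param w Symmetric numeric weight matrix with zero diagonal and at least
#'   one positive weight.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(x, w) {
  n <- length(x)
  if (n < 3L) stop_input("Moran's I needs at least 3 units")
  stopifnot(is.matrix(w), nrow(w) == n, ncol(w) == n)
  if (max(abs(w - t(w))) > 1e-12) stop_input("weight matrix must be symmetric")
  W <- sum(w)
  if (W <= 0) stop_input("weight matrix has no pairs")
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom <= 0) stop_input("zero variance: Moran's I is undefined")
  (n / W) * as.numeric(t(z) %*% w %*% z) / denom
}

# Variance of Moran's I under the randomization (permutation) null
# (Cliff & Ord): used as the large-lag standard error of a correlogram bin.
moran_var_rand <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  m4 <- sum(z^4) / n
  b2 <- m4 / m2^2
  W <- sum(w)
  s1 <- sum((w + t(w))^2) / 2
  s2 <- sum((rowSums(w) + colSums(w))^2)
  ei <- -1 / (n - 1)
  num <- n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * W^2) -
    b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * W^2)
  num / ((n - 1) * (n - 2) * (n - 3) * W^2) - ei^2
}

#' Moran's I spatial correlogram over distance classes
#'
#' Pairs of landscape centroids are assigned to half-open distance bins
#' `((k-1) * bin_width, k * bin_width]`; each unordered pair contributes to
#' exactly one bin. Per bin, binary weights connect the pair members and
#' Moran's I is computed, with a large-lag standard error taken as the square
#' root of the randomization-null variance of I for that bin's weight matrix.
#' A bin is significant when `|I - E[I]| > 2 * SE`, `E[I] = -1/(n-1)`. Bins
#' with fewer than `min_pairs` pairs are dropped.
#'
#' @param data Data frame with centroid coordinates and a value per
#'   landscape (one year of one index).
#' @param value Column name of the value (string).
#' @param coords Column names of the planar centroid coordinates.
#' @param bin_width Lag bin width in coordinate units; defaults to the
#'   smallest positive pair distance (adjacent landscapes then fall in the
#'   first bin).
#' @param min_pairs Minimum pairs per retained bin (1000, the published
#'   criterion).
#' @param max_bins Optional cap on the number of bins.
#' @return A `fp_correlogram` tibble: `bin`, `lag_lo`, `lag_hi`, `lag_mid`,
#'   `n_pairs`, `observed` (I), `expected`, `se`, `significant`.
#' @export
spatial_correlogram <- function(data, value, coords = c("centroid_x", "centroid_y"),
                                bin_width = NULL, min_pairs = 1000L,
                                max_bins = NULL) {
  stopifnot(all(c(coords, value) %in% names(data)))
  x <- data[[value]]
  n <- length(x)
  dmat <- as.matrix(stats::dist(as.matrix(data[, coords])))
  pos <- dmat[upper.tri(dmat)]
  pos <- pos[pos > 0]
  if (!length(pos)) stop_input("need at least two distinct centroids")
  if (is.null(bin_width)) bin_width <- min(pos)
  bins <- ceiling(dmat / bin_width)
  nb <- max(bins)
  if (!is.null(max_bins)) nb <- min(nb, max_bins)
  rows <- list()
  for (k in seq_len(nb)) {
    w <- (bins == k) * 1
    diag(w) <- 0
    npairs <- sum(w) / 2
    if (npairs < min_pairs) next
    I <- morans_i(x, w)
    se <- sqrt(moran_var_rand(x, w))
    ei <- -1 / (n - 1)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      bin = k, lag_lo = (k - 1) * bin_width, lag_hi = k * bin_width,
      lag_mid = (k - 0.5) * bin_width, n_pairs = npairs,
      observed = I, expected = ei, se = se,
      significant = abs(I - ei) > 2 * se)
  }
  if (!length(rows)) {
    warning("no lag bin reaches min_pairs; empty correlogram")
    out <- tibble::tibble(bin = integer(0), lag_lo = numeric(0),
                          lag_hi = numeric(0), lag_mid = numeric(0),
                          n_pairs = numeric(0), observed = numeric(0),
                          expected = numeric(0), se = numeric(0),
                          significant = logical(0))
  } else {
    out <- dplyr::bind_rows(rows)
  }
  class(out) <- c("fp_correlogram", class(out))
  out
}

#' Temporal autocorrelation of an annual series
#'
#' `r_k = sum_{t<=n-k} (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`
#' with a single global mean and the biased (stable) denominator -- the
#' standard sample autocorrelation, computed via [stats::acf()].
#'
#' @param x Numeric series.
#' @param max_lag Largest annual lag (requires `length(x) > max_lag + 2`).
#' @return Tibble with `lag` (1..max_lag) and `r`; `r` is `NA` (with a
#'   warning) for zero-variance series.
#' @export
temporal_acf <- function(x, max_lag = 5L) {
  n <- length(x)
  if (n <= max_lag + 2L) stop_input("series too short for max_lag")
  if (stats::sd(x) == 0) {
    warning("zero-variance series: autocorrelation undefined")
    return(tibble::tibble(lag = seq_len(max_lag), r = NA_real_))
  }
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble::tibble(lag = seq_len(max_lag), r = as.numeric(a$acf)[-1L])
}

#' Temporal autocorrelation for every landscape in an index table
#'
#' @param index_table A `fp_index_table`.
#' @param index Index column.
#' @param max_lag Largest annual lag.
#' @param extent Optional extent filter.
#' @return Tibble with `landscape_id`, `lag`, `r`.
#' @export
acf_by_landscape <- function(index_table, index = "forest_cover",
                             max_lag = 5L, extent = NULL) {
  tbl <- index_table
  if (!is.null(extent)) tbl <- dplyr::filter(tbl, .data$extent_ha == extent)
  tbl |>
    dplyr::group_by(.data$landscape_id) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::reframe(suppressWarnings(temporal_acf(.data[[index]], max_lag)))
}

#' Cross-landscape significance of temporal autocorrelation
#'
#' Per lag, a boxplot-style criterion over landscapes: the lag is significant
#' when the interquartile range of the per-landscape autocorrelations lies
#' entirely outside the band of two standard errors around zero
#' (`SE = sd(r) / sqrt(n)` across landscapes).
#'
#' @param acf_table Output of [acf_by_landscape()].
#' @param min_landscapes Fewer landscapes draws a warning.
#' @return A `fp_acf_summary` tibble per lag: `mean_r`, `se`, `q25`, `q75`,
#'   `significant`.
#' @export
acf_significance <- function(acf_table, min_landscapes = 10L) {
  if (dplyr::n_distinct(acf_table$landscape_id) < min_landscapes) {
    warning("fewer than ", min_landscapes, " landscapes; verdicts are unstable")
  }
  out <- acf_table |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_r = mean(.data$r),
      se = stats::sd(.data$r) / sqrt(dplyr::n()),
      q25 = stats::quantile(.data$r, 0.25, names = FALSE),
      q75 = stats::quantile(.data$r, 0.75, names = FALSE),
      .groups = "drop") |>
    dplyr::mutate(significant = .data$q25 > 2 * .data$se |
                    .data$q75 < -2 * .data$se)
  class(out) <- c("fp_acf_summary", class(out))
  out
}
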