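#' Disturbance-index trajectory parameters
#'
#' @param di_threshold Standardized disturbance-index exceedance threshold
#'   separating forest-like from non-forest-like condition. The boreal
#'   calibration behind the published maps is not printed anywhere, so the
#'   default (2 standardized units) is a configuration choice.
#' @param min_consecutive_years Minimum run of exceedance years for a change
#'   (default 3).
#' @param magnitude_threshold Minimum change magnitude, measured as the run's
#'   peak DI minus the pre-run baseline DI (default 5).
#' @param recovery_fraction Fraction of the mean pre-disturbance NBR defining
#'   spectral recovery (default 0.80).
#' @return A `fp_di_params` list.
#' @export
di_params <- function(di_threshold = 2, min_consecutive_years = 3L,
                      magnitude_threshold = 5, recovery_fraction = 0.8) {
  assert_scalar_num(di_threshold, "di_threshold", 1e-12)
  assert_scalar_num(min_consecutive_years, "min_consecutive_years", 1)
  assert_scalar_num(magnitude_threshold, "magnitude_threshold", 1e-12)
  assert_scalar_num(recovery_fraction, "recovery_fraction", 1e-12, 1)
  structure(list(di_threshold = di_threshold,
                 min_consecutive_years = as.integer(min_consecutive_years),
                 magnitude_threshold = magnitude_threshold,
                 recovery_fraction = recovery_fraction),
            class = "fp_di_params")
}

#' Standardized Tasseled-Cap disturbance index
#'
#' `DI = Bz - (Gz + Wz)`, where each component is standardized against the
#' mean and standard deviation of a forest reference sample for that year.
#' Forest-like pixels score near zero; strongly positive values indicate
#' bright, dry, low-vegetation (disturbed or non-forest) condition.
#'
#' @param brightness,greenness,wetness Numeric vectors (one year) or
#'   pixels x years matrices.
#' @param reference_stats List with elements `brightness`, `greenness`,
#'   `wetness`, each a list of per-year `mean` and `sd` vectors (see
#'   [reference_stats()]).
#' @return DI values with the same shape as the inputs.
#' @export
disturbance_index <- function(brightness, greenness, wetness, reference_stats) {
  # vectors are one year's pixels: a single column in the pixels x years layout
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1L)
  B <- as_mat(brightness); G <- as_mat(greenness); W <- as_mat(wetness)
  stopifnot(identical(dim(B), dim(G)), identical(dim(B), dim(W)))
  for (l in c("brightness", "greenness", "wetness")) {
    s <- reference_stats[[l]]
    if (length(s$mean) != ncol(B) || length(s$sd) != ncol(B)) {
      stop_input("reference_stats year dimension does not match the input")
    }
    if (any(s$sd <= 0)) {
      stop_input("degenerate reference sample: zero standard deviation for ", l)
    }
  }
  z <- function(X, s) sweep(sweep(X, 2L, s$mean), 2L, s$sd, "/")
  di <- z(B, reference_stats$brightness) -
    (z(G, reference_stats$greenness) + z(W, reference_stats$wetness))
  if (is.matrix(brightness)) di else as.numeric(di)
}

#' Self-calibrated forest reference statistics
#'
#' Replaces an externally trained forest mask with one-pass self-calibration:
#' provisional statistics over all valid pixels in the first year give a
#' provisional DI; pixels with `|DI| < di_threshold` in year one form the
#' forest reference sample; per-year means and standard deviations of the
#' Tasseled-Cap components are then recomputed over that sample. Standard
#' deviations are floored at `floor_sd` so noise-free scenes (where the
#' reference sample is spectrally homogeneous) remain well defined.
#'
#' @param scene A gap-filled `fp_scene`.
#' @param di_threshold Provisional forest cut-off in standardized DI units.
#' @param valid Optional logical matrix of valid pixels.
#' @param floor_sd Lower bound applied to reference standard deviations.
#' @return List of per-layer per-year `mean`/`sd` vectors plus the logical
#'   `sample` matrix of reference pixels.
#' @export
reference_stats <- function(scene, di_threshold = 2, valid = NULL,
                            floor_sd = 1e-8) {
  stopifnot(inherits(scene, "fp_scene"))
  d <- dim(scene$layers$brightness)
  npx <- d[1L] * d[2L]
  ok <- if (is.null(valid)) rep(TRUE, npx) else as.vector(valid)
  y1 <- lapply(c("brightness", "greenness", "wetness"),
               function(l) as.vector(scene$layers[[l]][, , 1L]))
  names(y1) <- c("brightness", "greenness", "wetness")
  ok <- ok & !is.na(y1$brightness)
  prov <- lapply(y1, function(v) list(mean = mean(v[ok]),
                                      sd = max(stats::sd(v[ok]), floor_sd)))
  di1 <- disturbance_index(y1$brightness, y1$greenness, y1$wetness, prov)
  samp <- ok & abs(di1) < di_threshold
  if (sum(samp) < 2L) stop_input("forest reference sample is empty")
  out <- lapply(c("brightness", "greenness", "wetness"), function(l) {
    m <- matrix(scene$layers[[l]], npx, d[3L])[samp, , drop = FALSE]
    list(mean = colMeans(m, na.rm = TRUE),
         sd = pmax(apply(m, 2L, stats::sd, na.rm = TRUE), floor_sd))
  })
  names(out) <- c("brightness", "greenness", "wetness")
  out$sample <- matrix(samp, d[1L], d[2L])
  out
}

# Vectorized trajectory classifier over a pixels x years DI matrix.
# Returns integer state codes, change-year index and per-pixel run info.
classify_matrix <- function(DI, params) {
  np <- nrow(DI); Tn <- ncol(DI)
  above <- DI > params$di_threshold          # disturbance direction
  above[is.na(above)] <- FALSE
  outside <- abs(DI) > params$di_threshold   # outside the two-sided forest band
  outside[is.na(outside)] <- FALSE
  n_outside <- rowSums(outside)
  runlen <- integer(np)
  peak <- rep(-Inf, np)
  base <- numeric(np)
  start <- integer(np)
  cs <- numeric(np)
  change_idx <- rep(NA_integer_, np)
  qualifies <- function(len, pk, bs) {
    len >= params$min_consecutive_years & (pk - bs) > params$magnitude_threshold
  }
  for (t in seq_len(Tn)) {
    a <- above[, t]
    newrun <- a & runlen == 0L
    if (any(newrun)) {
      base[newrun] <- if (t == 1L) 0 else cs[newrun] / (t - 1L)
      peak[newrun] <- -Inf
      start[newrun] <- t
    }
    ended <- !a & runlen > 0L
    if (any(ended)) {
      q <- ended & qualifies(runlen, peak, base)
      change_idx[q] <- start[q]
      runlen[ended] <- 0L
    }
    runlen[a] <- runlen[a] + 1L
    di_t <- DI[, t]
    peak[a] <- pmax(peak[a], di_t[a])
    cs <- cs + ifelse(is.na(di_t), 0, di_t)
  }
  pnf <- n_outside == Tn                     # outside the band in every year
  q <- !pnf & runlen > 0L & runlen < Tn & qualifies(runlen, peak, base)
  change_idx[q] <- start[q]
  state <- rep(STATE_PERSISTING_FOREST, np)
  state[pnf] <- STATE_PERSISTING_NONFOREST
  state[!pnf & !is.na(change_idx)] <- STATE_CHANGED
  change_idx[state != STATE_CHANGED] <- NA_integer_
  list(state = state, change_idx = change_idx)
}

#' Classify one pixel's DI trajectory
#'
#' A pixel is `changed` when its DI exceeds the threshold for at least
#' `min_consecutive_years` consecutive years and the run's peak DI minus the
#' pre-run baseline (mean DI over the years before the run; 0 when the run
#' opens the series) exceeds the magnitude threshold. Pixels outside the
#' two-sided forest band (`|DI|` above the threshold: DI deviating from zero
#' in either direction is non-forest-like) in every year are
#' `persisting_nonforest`; everything else is
#' `persisting_forest`. When several runs qualify only the most recent is
#' kept, and its first year is the change year.
#'
#' @param di_series Numeric DI vector, one value per year (gap-filled).
#' @param params A [di_params()] object.
#' @return List with `state` (character) and `change_year` (index into the
#'   series, or `NA`).
#' @export
classify_trajectory <- function(di_series, params = di_params()) {
  if (length(di_series) < params$min_consecutive_years + 1L) {
    stop_input("series must be longer than min_consecutive_years")
  }
  res <- classify_matrix(matrix(di_series, nrow = 1L), params)
  list(state = state_labels(res$state), change_year = res$change_idx[1L])
}

#' Spectral recovery threshold for a disturbed pixel
#'
#' `recovery_fraction` (default 80%) of the mean NBR over the two years
#' preceding the disturbance. With a change in year two only one
#' pre-disturbance year exists and it is used alone (flagged); a change in
#' year one has no pre-disturbance year and yields `NA`.
#'
#' @param nbr_series Annual NBR vector.
#' @param change_year Index of the change year within the series.
#' @param recovery_fraction Recovery fraction.
#' @return Threshold in NBR units, with attribute `flagged` when fewer than
#'   two pre-disturbance years were available.
#' @export
recovery_threshold <- function(nbr_series, change_year,
                               recovery_fraction = 0.8) {
  stopifnot(change_year >= 1L, change_year <= length(nbr_series))
  pre <- nbr_series[seq_len(change_year - 1L)]
  pre <- utils::tail(pre, 2L)
  if (!length(pre)) {
    return(structure(NA_real_, flagged = TRUE))
  }
  structure(recovery_fraction * mean(pre), flagged = length(pre) < 2L)
}

#' Detect spectral recovery after a disturbance
#'
#' The recovery year is the first year after the change year whose NBR meets
#' or exceeds the recovery threshold; `NA` when the threshold is never
#' reached. From the recovery year onward the pixel counts as forest again in
#' the annual maps.
#'
#' @param nbr_series Annual NBR vector (original spectral values, gap-filled).
#' @param change_year Index of the change year.
#' @param threshold Recovery threshold from [recovery_threshold()].
#' @return Recovery year index or `NA`.
#' @export
apply_recovery <- function(nbr_series, change_year, threshold) {
  if (is.na(threshold)) return(NA_integer_)
  idx <- which(seq_along(nbr_series) > change_year & nbr_series >= threshold)
  if (length(idx)) idx[1L] else NA_integer_
}

#' Run trajectory classification over a whole scene
#'
#' Computes self-calibrated reference statistics, the DI stack, per-pixel
#' trajectory states, change years and NBR-based recovery years. Invalid
#' pixels (per the validity screen) become background.
#'
#' @param scene A gap-filled `fp_scene` (see [composite_scene()]).
#' @param params A [di_params()] object.
#' @param valid Optional logical matrix of valid pixels.
#' @param keep_di Keep the DI array in the result (memory permitting).
#' @return A `fp_states` list: `state` (integer matrix: 0 background,
#'   1 persisting forest, 2 persisting non-forest, 3 changed), `change_year`
#'   and `recovery_year` (calendar-year matrices), `years`, and optionally
#'   `di`.
#' @export
detect_changes <- function(scene, params = di_params(), valid = NULL,
                           keep_di = FALSE) {
  stopifnot(inherits(scene, "fp_scene"))
  d <- dim(scene$layers$brightness)
  npx <- d[1L] * d[2L]; Tn <- d[3L]
  if (Tn < params$min_consecutive_years + 1L) {
    stop_input("scene has too few years for trajectory classification")
  }
  rs <- reference_stats(scene, params$di_threshold, valid)
  DI <- disturbance_index(matrix(scene$layers$brightness, npx, Tn),
                          matrix(scene$layers$greenness, npx, Tn),
                          matrix(scene$layers$wetness, npx, Tn), rs)
  cls <- classify_matrix(DI, params)
  state <- cls$state
  if (!is.null(valid)) state[!as.vector(valid)] <- STATE_BACKGROUND
  change_idx <- cls$change_idx
  change_idx[state != STATE_CHANGED] <- NA_integer_

  # recovery, vectorized over changed pixels
  rec_idx <- rep(NA_integer_, npx)
  ch <- which(state == STATE_CHANGED)
  if (length(ch)) {
    NBR <- matrix(scene$layers$nbr, npx, Tn)[ch, , drop = FALSE]
    ci <- change_idx[ch]
    pre1 <- NBR[cbind(seq_along(ch), pmax(ci - 1L, 1L))]
    pre2 <- NBR[cbind(seq_along(ch), pmax(ci - 2L, 1L))]
    thr <- params$recovery_fraction *
      ifelse(ci >= 3L, (pre1 + pre2) / 2,
             ifelse(ci == 2L, pre1, NA_real_))
    found <- rep(NA_integer_, length(ch))
    for (t in seq_len(Tn)) {
      hit <- is.na(found) & !is.na(thr) & t > ci & NBR[, t] >= thr
      found[hit] <- t
    }
    rec_idx[ch] <- found
  }

  to_year <- function(ix) {
    out <- rep(NA_integer_, npx)
    ok <- !is.na(ix)
    out[ok] <- scene$years[ix[ok]]
    matrix(out, d[1L], d[2L])
  }
  res <- structure(list(
    state = matrix(state, d[1L], d[2L]),
    change_year = to_year(change_idx),
    recovery_year = to_year(rec_idx),
    years = scene$years,
    params = params
  ), class = "fp_states")
  if (keep_di) res$di <- array(DI, d)
  res
}

#' @export
print.fp_states <- function(x, ...) {
  tab <- table(factor(state_labels(as.vector(x$state)),
                      levels = state_labels(0:3)))
  cat("<fp_states>", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Compare detected changes against simulator truth
#'
#' Event-level detection rate: an injected disturbance event counts as
#' detected when more than half of its pixels are labelled `changed` with a
#' change year within `tolerance` years of the event year. Only events that
#' are the most recent event for their pixels and occur early enough to
#' satisfy the consecutive-year rule before the series ends are evaluable.
#' Commission: fraction of never-disturbed forest pixels labelled `changed`.
#'
#' @param truth A `fp_truth` object.
#' @param states A `fp_states` object.
#' @param tolerance Year tolerance (default 1).
#' @return Tibble with `n_events`, `n_evaluable`, `detection_rate`,
#'   `commission_rate`, `mean_year_error`.
#' @export
evaluate_detection <- function(truth, states, tolerance = 1L) {
  Tn <- length(truth$years)
  last_year_ok <- truth$years[Tn] - (states$params$min_consecutive_years - 1L)
  last_ev <- truth$last_event[, , Tn]
  ev <- truth$events
  det <- vapply(seq_len(nrow(ev)), function(i) {
    px <- ev$pixels[[i]]
    px <- px[last_ev[px] == ev$year[i]]        # still the most recent event
    px <- px[states$state[px] != STATE_BACKGROUND]
    if (!length(px)) return(NA)
    hit <- states$state[px] == STATE_CHANGED &
      !is.na(states$change_year[px]) &
      abs(states$change_year[px] - ev$year[i]) <= tolerance
    mean(hit) > 0.5
  }, logical(1))
  evaluable <- ev$year <= last_year_ok & !is.na(det)
  undisturbed <- truth$forest[, , 1L] & is.na(last_ev) &
    states$state != STATE_BACKGROUND
  commission <- mean(states$state[undisturbed] == STATE_CHANGED)
  err <- abs(states$change_year - last_ev)
  tibble::tibble(
    n_events = nrow(ev),
    n_evaluable = sum(evaluable),
    detection_rate = mean(det[evaluable]),
    commission_rate = commission,
    mean_year_error = mean(err[!is.na(err)])
  )
}
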