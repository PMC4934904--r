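# Brute-force oracles, kept deliberately independent of the implementation:
# queue-based flood fill for labelling, explicit face counting for perimeter,
# exhaustive distance scans for core area, full pairwise loops for the trend
# and autocorrelation statistics.

oracle_label <- function(map) {
  nr <- nrow(map); nc <- ncol(map)
  forest <- !is.na(map) & map == 1
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(forest & lab == 0L)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cell <- queue[1L]; queue <- queue[-1L]
      r <- ((cell - 1L) %% nr) + 1L
      c <- ((cell - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if ((dr || dc) && rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          nb <- (cc - 1L) * nr + rr
          if (forest[nb] && lab[nb] == 0L) {
            lab[nb] <- nxt
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  lab
}

oracle_patch_sizes <- function(map) {
  lab <- oracle_label(map)
  if (max(lab) == 0L) integer(0) else tabulate(lab[lab > 0L])
}

oracle_forest_cover <- function(map) {
  100 * sum(map == 1, na.rm = TRUE) / sum(!is.na(map))
}

oracle_lpi <- function(map) {
  s <- oracle_patch_sizes(map)
  if (!length(s)) 0 else 100 * max(s) / sum(!is.na(map))
}

oracle_edge_density <- function(map, pixel_size = 30, include_boundary = TRUE) {
  nr <- nrow(map); nc <- ncol(map)
  forest <- !is.na(map) & map == 1
  faces <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!forest[r, c]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      outside <- rr < 1 || rr > nr || cc < 1 || cc > nc
      if (outside) {
        if (include_boundary) faces <- faces + 1L
      } else if (!forest[rr, cc]) {
        faces <- faces + 1L
      }
    }
  }
  area_ha <- sum(!is.na(map)) * pixel_size^2 / 1e4
  pixel_size * faces / area_ha
}

oracle_core_cover <- function(map, pixel_size = 30, edge_depth = 120) {
  nr <- nrow(map); nc <- ncol(map)
  forest <- !is.na(map) & map == 1
  nf <- which(!forest, arr.ind = TRUE)
  n_core <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!forest[r, c]) next
    d_out <- min(r, nr + 1 - r, c, nc + 1 - c)  # nearest outside pixel centre
    d_nf <- if (nrow(nf)) sqrt(min((nf[, 1] - r)^2 + (nf[, 2] - c)^2)) else Inf
    if (min(d_out, d_nf) * pixel_size > edge_depth) n_core <- n_core + 1L
  }
  100 * n_core / sum(!is.na(map))
}

oracle_mann_kendall_s <- function(x) {
  n <- length(x)
  S <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S <- S + as.integer(sign(x[j] - x[i]))
  }
  S
}

oracle_tau <- function(x) {
  n <- length(x)
  S <- oracle_mann_kendall_s(x)
  ties <- table(x)
  ties <- ties[ties > 1]
  D <- n * (n - 1) / 2
  den <- sqrt((D - sum(ties * (ties - 1) / 2)) * D)
  if (den > 0) S / den else 0
}

oracle_sen_slope <- function(x, t = seq_along(x)) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    slopes <- c(slopes, (x[j] - x[i]) / (t[j] - t[i]))
  }
  median(slopes)
}

oracle_morans_i <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0; W <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + w[i, j] * z[i] * z[j]
    W <- W + w[i, j]
  }
  (n / W) * num / sum(z^2)
}

# random binary landscape with background, clumped enough to make patches
random_map <- function(nr, nc, p_forest = 0.5, p_background = 0.05) {
  m <- matrix(rbinom(nr * nc, 1L, p_forest), nr, nc)
  if (p_background > 0) m[runif(nr * nc) < p_background] <- NA_integer_
  m
}

rook_weights <- function(nr, nc) {
  n <- nr * nc
  w <- matrix(0, n, n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- (c - 1) * nr + r
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        w[i, (cc - 1) * nr + rr] <- 1
      }
    }
  }
  w
}

quick_sim <- function(...) {
  args <- utils::modifyList(
    list(grid_rows = 96L, grid_cols = 96L, n_years = 12L,
         annual_disturbance_rate = 0.01, max_patch_px = 200L),
    list(...))
  do.call(sim_config, args)
}
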