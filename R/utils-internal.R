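# Internal helpers shared across modules. Nothing here is exported.

SPECTRAL_LAYERS <- c("brightness", "greenness", "wetness", "nbr", "ndvi")

# state codes used in fp_states$state matrices
STATE_BACKGROUND <- 0L
STATE_PERSISTING_FOREST <- 1L
STATE_PERSISTING_NONFOREST <- 2L
STATE_CHANGED <- 3L

state_labels <- function(code) {
  c("background", "persisting_forest", "persisting_nonforest", "changed")[code + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_input(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

# Linear-index 8-neighbourhoods on an nr x nc grid, one cell at a time.
neighbours8 <- function(idx, nr, nc) {
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  rr <- r + dr
  cc <- c + dc
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  (cc[ok] - 1L) * nr + rr[ok]
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Per-row linear interpolation of interior NA runs with nearest-value extension
# at the ends. Rows that are entirely NA stay NA.
fill_series_matrix <- function(M) {
  Tn <- ncol(M)
  obs <- !is.na(M)
  if (all(obs)) return(M)
  np <- nrow(M)
  prev_i <- matrix(NA_integer_, np, Tn)
  next_i <- matrix(NA_integer_, np, Tn)
  carry <- ifelse(obs[, 1L], 1L, NA_integer_)
  prev_i[, 1L] <- carry
  for (t in seq_len(Tn)[-1L]) {
    carry <- ifelse(obs[, t], t, carry)
    prev_i[, t] <- carry
  }
  carry <- ifelse(obs[, Tn], Tn, NA_integer_)
  next_i[, Tn] <- carry
  for (t in rev(seq_len(Tn - 1L))) {
    carry <- ifelse(obs[, t], t, carry)
    next_i[, t] <- carry
  }
  out <- M
  gap <- which(!obs)
  r <- ((gap - 1L) %% np) + 1L
  t <- ((gap - 1L) %/% np) + 1L
  p <- prev_i[gap]
  nx <- next_i[gap]
  vp <- M[cbind(r, p)]
  vn <- M[cbind(r, nx)]
  val <- ifelse(is.na(p), vn,
         ifelse(is.na(nx), vp,
                vp + (vn - vp) * (t - p) / (nx - p)))
  out[gap] <- val
  out
}

# Longest run of TRUE per row of a logical matrix.
max_run_per_row <- function(G) {
  cur <- integer(nrow(G))
  mx <- integer(nrow(G))
  for (t in seq_len(ncol(G))) {
    cur <- ifelse(G[, t], cur + 1L, 0L)
    mx <- pmax(mx, cur)
  }
  mx
}

# 8- (or 4-) connected component labelling of a logical/binary matrix.
# EBImage::bwlabel is 4-connected; diagonal adjacencies are merged afterwards
# with a small union-find over the label set.
label_matrix <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  m <- mask
  m[is.na(m)] <- 0
  lab <- EBImage::bwlabel(m != 0)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab, 0L)
  if (connectivity == 8 && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    p <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),
      cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L]))
    )
    p <- p[p[, 1L] > 0L & p[, 2L] > 0L & p[, 1L] != p[, 2L], , drop = FALSE]
    if (nrow(p)) {
      p <- unique(p)
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(p))) {
        a <- find(p[k, 1L]); b <- find(p[k, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(nlab), find, integer(1L))
      pos <- lab > 0L
      lab[pos] <- roots[lab[pos]]
    }
  }
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

# Smoothed Gaussian random field via FFT convolution; used for initial forest
# and water masks. Returns a matrix of (approximately) standardized values.
smooth_random_field <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return(z)
  rs <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  cs <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  k <- exp(-outer(rs^2, cs^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}
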