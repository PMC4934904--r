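test_that("truth generation is deterministic and respects the no-event case", {
  cfg <- quick_sim(seed = 11L)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  s1 <- render_spectral(t1, cfg)
  s2 <- render_spectral(t2, cfg)
  expect_identical(s1, s2)

  cfg0 <- quick_sim(annual_disturbance_rate = 0, seed = 3L)
  tr0 <- generate_truth(cfg0)
  for (t in 2:cfg0$n_years) {
    expect_identical(tr0$forest[, , t], tr0$forest[, , 1L])
  }
  expect_identical(nrow(tr0$events), 0L)
  # initial fractions hit their targets
  expect_lt(abs(mean(tr0$forest[, , 1L]) - cfg0$initial_forest_fraction), 0.02)
  expect_lt(abs(mean(tr0$water) - cfg0$water_fraction), 0.02)
  expect_false(any(tr0$forest[, , 1L] & tr0$water))
})

test_that("disturbed pixels were forest the year before their event", {
  cfg <- quick_sim(seed = 21L, annual_disturbance_rate = 0.02)
  tr <- generate_truth(cfg)
  expect_gt(nrow(tr$events), 0L)
  for (i in seq_len(nrow(tr$events))) {
    y <- match(tr$events$year[i], tr$years)
    px <- tr$events$pixels[[i]]
    expect_true(all(tr$forest[, , y - 1L][px]))
    expect_false(any(tr$forest[, , y][px]))
    expect_false(any(tr$water[px]))
  }
})

test_that("cumulative disturbed fraction matches the closed-form expectation", {
  d <- 0.02
  Tn <- 10L
  fracs <- vapply(1:50, function(s) {
    cfg <- sim_config(grid_rows = 96L, grid_cols = 96L, n_years = Tn,
                      annual_disturbance_rate = d, recovery_rate = 0,
                      max_patch_px = 100L, seed = s)
    tr <- generate_truth(cfg)
    ever <- Reduce(`|`, lapply(seq_len(nrow(tr$events)),
                               function(i) {
                                 v <- logical(96 * 96)
                                 v[tr$events$pixels[[i]]] <- TRUE
                                 v
                               }),
                   accumulate = FALSE, init = logical(96 * 96))
    sum(ever) / sum(tr$forest[, , 1L])
  }, numeric(1))
  # disturbance runs in years 2..Tn, so Tn - 1 rounds of rate d
  expected <- 1 - (1 - d)^(Tn - 1)
  expect_lt(abs(mean(fracs) - expected), 3 * sd(fracs) / sqrt(length(fracs)))
})

test_that("realized annual disturbance rate converges at large grids", {
  cfg <- sim_config(grid_rows = 512L, grid_cols = 512L, n_years = 11L,
                    annual_disturbance_rate = 0.01, recovery_rate = 0,
                    seed = 5L)
  tr <- generate_truth(cfg)
  per_year <- vapply(2:11, function(y) {
    disturbed <- sum(tr$events$size[tr$events$year == tr$years[y]])
    disturbed / sum(tr$forest[, , y - 1L])
  }, numeric(1))
  expect_lt(abs(mean(per_year) - 0.01) / 0.01, 0.10)
})

test_that("patch sizes follow the configured truncated power law", {
  cfg <- sim_config(grid_rows = 256L, grid_cols = 256L, n_years = 26L,
                    initial_forest_fraction = 0.85, water_fraction = 0.02,
                    annual_disturbance_rate = 0.02, patch_size_alpha = 1.7,
                    min_patch_px = 12L, max_patch_px = 500L,
                    recovery_rate = 0, seed = 9L)
  tr <- generate_truth(cfg)
  sizes <- tr$events$size[!tr$events$flagged]
  expect_gte(length(sizes), 200L)
  s <- cfg$min_patch_px:cfg$max_patch_px
  pmf <- s^(-cfg$patch_size_alpha)
  pmf <- pmf / sum(pmf)
  cdf <- cumsum(pmf)
  # randomized PIT: uniform under the null even for a discrete law
  set.seed(1)
  lo <- c(0, cdf)[match(sizes, s)]
  hi <- cdf[match(sizes, s)]
  u <- runif(length(sizes), lo, hi)
  expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.01)
})

test_that("noise-free rendering is constant for undisturbed forest and ramps after events", {
  cfg <- sim_config(grid_rows = 48L, grid_cols = 48L, n_years = 16L,
                    annual_disturbance_rate = 0.03, noise_sd = 0,
                    gap_prob = 0, max_patch_px = 60L,
                    recovery_lag = 3L, recovery_rate = 0.2, seed = 2L)
  tr <- generate_truth(cfg)
  sc <- render_spectral(tr, cfg)
  undisturbed <- tr$forest[, , 1L] & is.na(tr$last_event[, , cfg$n_years])
  i <- which(undisturbed)[1L]
  ri <- (i - 1L) %% 48L + 1L
  ci <- (i - 1L) %/% 48L + 1L
  expect_equal(sc$layers$nbr[ri, ci, ],
               rep(cfg$class_means$forest[["nbr"]], 16))

  # one disturbed pixel: NBR crosses recovery_target * pre-event NBR exactly
  # years_to_recovery years after the event
  ev <- tr$events[tr$events$year <= tr$years[8L], ][1L, ]
  px <- ev$pixels[[1L]][1L]
  r <- (px - 1) %% 48 + 1; c <- (px - 1) %/% 48 + 1
  nbr <- sc$layers$nbr[r, c, ]
  thr <- cfg$recovery_target * cfg$class_means$forest[["nbr"]]
  k <- forestpattern:::years_to_recovery(cfg)
  crossing <- which(nbr >= thr & tr$years > ev$year)
  expect_identical(tr$years[crossing[1L]], ev$year + k)
})

test_that("truth recovery restores forest at the spectral recovery year", {
  cfg <- sim_config(grid_rows = 64L, grid_cols = 64L, n_years = 20L,
                    annual_disturbance_rate = 0.02, recovery_lag = 2L,
                    recovery_rate = 0.25, max_patch_px = 60L, seed = 13L)
  tr <- generate_truth(cfg)
  k <- forestpattern:::years_to_recovery(cfg)
  ev <- tr$events[tr$events$year + k <= tr$years[cfg$n_years], ]
  expect_gt(nrow(ev), 0L)
  e <- ev[1L, ]
  px <- e$pixels[[1L]]
  # pixels not re-disturbed in the meantime are forest again at year + k
  last <- tr$last_event[, , cfg$n_years]
  px <- px[last[px] == e$year]
  y_rec <- match(e$year + k, tr$years)
  expect_true(all(tr$forest[, , y_rec][px]))
  expect_false(any(tr$forest[, , y_rec - 1L][px]))
})
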