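make_stats <- function(Tn, mean = 0, sd = 1) {
  one <- list(mean = rep(mean, Tn), sd = rep(sd, Tn))
  list(brightness = one, greenness = one, wetness = one)
}

test_that("disturbance index is the standardized B - (G + W) combination", {
  st <- make_stats(1)
  expect_equal(disturbance_index(0, 0, 0, st), 0)
  expect_equal(disturbance_index(4, -1, -1, st), 6)
  st2 <- list(brightness = list(mean = 2, sd = 2),
              greenness = list(mean = 1, sd = 0.5),
              wetness = list(mean = -1, sd = 0.25))
  expect_equal(disturbance_index(4, 0.5, -1.5, st2),
               (4 - 2) / 2 - ((0.5 - 1) / 0.5 + (-1.5 + 1) / 0.25))
  bad <- list(brightness = list(mean = 0, sd = 0),
              greenness = list(mean = 0, sd = 1),
              wetness = list(mean = 0, sd = 1))
  expect_error(disturbance_index(1, 1, 1, bad), "degenerate")
})

test_that("trajectory classification enforces run length, magnitude and recency", {
  p <- di_params()  # threshold 2, 3 consecutive years, magnitude 5
  base <- rep(0, 26)
  # two consecutive exceedance years, huge magnitude: still persisting forest
  x <- base; x[10:11] <- 8
  expect_identical(classify_trajectory(x, p)$state, "persisting_forest")
  # three-year run, peak - baseline = 6 > 5: changed at the run start
  x <- base; x[10:13] <- c(6, 6, 6, 6)
  res <- classify_trajectory(x, p)
  expect_identical(res$state, "changed")
  expect_identical(res$change_year, 10L)
  # three-year run with magnitude exactly 5: not greater than five, unchanged
  x <- base; x[10:12] <- 5
  expect_identical(classify_trajectory(x, p)$state, "persisting_forest")
  # above threshold in every year: persisting non-forest
  expect_identical(classify_trajectory(rep(8, 26), p)$state,
                   "persisting_nonforest")
  # two qualifying runs: the most recent wins
  x <- base; x[5:8] <- 7; x[18:21] <- 7
  expect_identical(classify_trajectory(x, p)$change_year, 18L)
  # baseline matters: elevated pre-run DI cancels the magnitude
  x <- rep(1.5, 26); x[10:12] <- 6   # peak 6 - baseline 1.5 = 4.5 < 5
  expect_identical(classify_trajectory(x, p)$state, "persisting_forest")
  # strongly negative DI in every year is outside the forest band too
  expect_identical(classify_trajectory(rep(-8, 26), p)$state,
                   "persisting_nonforest")
  expect_error(classify_trajectory(c(1, 2, 3), p), "longer than")
})

test_that("raising the magnitude threshold never adds changed pixels", {
  set.seed(42)
  Tn <- 20L
  DI <- matrix(rnorm(400 * Tn, sd = 2), 400, Tn)
  DI[1:150, 8:14] <- DI[1:150, 8:14] + 7
  prev <- Inf
  for (mag in c(3, 5, 7, 9)) {
    p <- di_params(magnitude_threshold = mag)
    n_changed <- sum(forestpattern:::classify_matrix(DI, p)$state ==
                       forestpattern:::STATE_CHANGED)
    expect_lte(n_changed, prev)
    prev <- n_changed
  }
})

test_that("recovery threshold is 80% of the two-year pre-disturbance NBR mean", {
  x <- c(0.5, 0.5, 0, 0, 0)
  expect_equal(as.numeric(recovery_threshold(x, 3)), 0.40)
  expect_equal(as.numeric(recovery_threshold(c(0.4, 0.6, 0, 0), 3)), 0.40)
  expect_equal(as.numeric(recovery_threshold(c(0.3, 0.5, 0, 0), 3,
                                             recovery_fraction = 1)), 0.40)
  # single available pre-year is used and flagged
  th <- recovery_threshold(c(0.5, 0, 0, 0), 2)
  expect_equal(as.numeric(th), 0.40)
  expect_true(attr(th, "flagged"))
  # change in year one: no pre-year at all
  expect_true(is.na(recovery_threshold(c(0, 0, 0), 1)))
})

test_that("recovery detection finds the first threshold crossing after change", {
  nbr <- c(0.6, 0.6, 0.1, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  thr <- as.numeric(recovery_threshold(nbr, 3))  # 0.48
  expect_identical(apply_recovery(nbr, 3, thr), 8L)
  expect_identical(apply_recovery(rep(c(0.6, 0.1), c(2, 7)), 3, 0.48),
                   NA_integer_)
  # boundary: threshold met the year right after the change
  expect_identical(apply_recovery(c(0.6, 0.6, 0.1, 0.55, 0.1), 3, 0.48), 4L)
})

test_that("zero-noise scenes are detected exactly at the injected year", {
  cfg <- quick_sim(noise_sd = 0, gap_prob = 0, seed = 8L,
                   annual_disturbance_rate = 0.02, recovery_rate = 0)
  tr <- generate_truth(cfg)
  sc <- render_spectral(tr, cfg)
  comp <- composite_scene(sc)
  st <- detect_changes(comp$scene, di_params(), valid = comp$valid)
  last <- tr$last_event[, , cfg$n_years]
  detectable <- !is.na(last) &
    last <= tr$years[cfg$n_years] - (di_params()$min_consecutive_years - 1L)
  expect_true(all(st$state[detectable] == forestpattern:::STATE_CHANGED))
  expect_identical(st$change_year[detectable], last[detectable])
  undisturbed <- tr$forest[, , 1L] & is.na(last)
  expect_true(all(st$state[undisturbed] == forestpattern:::STATE_PERSISTING_FOREST))
  open_land <- !tr$forest[, , 1L] & is.na(last)
  expect_true(all(st$state[open_land] == forestpattern:::STATE_PERSISTING_NONFOREST))
})

test_that("detection quality holds under moderate noise", {
  # default contrasts put the standardized DI step near 6; noise_sd 0.02 makes
  # the DI noise sd sqrt(3), i.e. under a third of the contrast
  cfg <- quick_sim(grid_rows = 128L, grid_cols = 128L, n_years = 20L,
                   annual_disturbance_rate = 0.01, seed = 31L)
  tr <- generate_truth(cfg)
  comp <- composite_scene(render_spectral(tr, cfg))
  st <- detect_changes(comp$scene, di_params(), valid = comp$valid)
  ev <- evaluate_detection(tr, st)
  expect_gte(ev$detection_rate, 0.90)
  expect_lte(ev$commission_rate, 0.05)
})

test_that("rendered disturbances raise DI by at least the configured contrast", {
  cfg <- quick_sim(seed = 17L, annual_disturbance_rate = 0.02)
  tr <- generate_truth(cfg)
  comp <- composite_scene(render_spectral(tr, cfg))
  rs <- reference_stats(comp$scene, valid = comp$valid)
  d <- dim(comp$scene$layers$brightness)
  DI <- disturbance_index(matrix(comp$scene$layers$brightness, prod(d[1:2]), d[3]),
                          matrix(comp$scene$layers$greenness, prod(d[1:2]), d[3]),
                          matrix(comp$scene$layers$wetness, prod(d[1:2]), d[3]),
                          rs)
  ev <- tr$events[tr$events$year <= tr$years[d[3]] - 2L, ]
  e <- ev[which.max(ev$size), ]
  px <- e$pixels[[1L]]
  yi <- match(e$year, tr$years)
  pre <- rowMeans(DI[px, seq_len(yi - 1L), drop = FALSE])
  post <- DI[px, yi]
  # mean DI jump across the patch is close to the nominal standardized step
  step <- sum(abs(cfg$disturbance_contrast[c("brightness", "greenness",
                                             "wetness")]) / 0.02)
  expect_gt(mean(post - pre), step - 2)
})
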