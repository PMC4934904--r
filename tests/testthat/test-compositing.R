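test_that("season window is centred on day 209 and tracks latitude", {
  # constant model: L = 120 regardless of latitude
  expect_identical(season_window(50, list(a = 120, b = 0)), c(start = 149L, end = 269L))
  expect_identical(season_window(70, list(a = 120, b = 0)), c(start = 149L, end = 269L))
  # default model stays inside the documented start/end ranges over 45-65 N
  for (lat in seq(45, 65, by = 2.5)) {
    w <- season_window(lat)
    expect_gte(w[["start"]], 127L)  # May 7
    expect_lte(w[["start"]], 166L)  # Jun 15
    expect_gte(w[["end"]], 252L)    # Sep 9
    expect_lte(w[["end"]], 291L)    # Oct 18
    # symmetric about the centre up to outward rounding
    expect_lte(abs((209 - w[["start"]]) - (w[["end"]] - 209)), 1L)
  }
  expect_error(season_window(55, list(a = 20, b = 0)), "shorter than 30")
})

test_that("candidate scores behave as the four-term model dictates", {
  w <- season_window(55)
  base <- data.frame(day_of_year = 209, sensor_class = "preferred",
                     distance_to_cloud = 1e6, opacity = 0)
  # day term: closer to the season centre always scores higher
  near <- base; near$day_of_year <- 200
  far <- base; far$day_of_year <- 180
  expect_gt(score_candidate(near, window = w), score_candidate(far, window = w))
  # cloud term saturates to 1 far from clouds
  far_cloud <- score_candidate(base, window = w)
  expect_equal(far_cloud, 1)  # all four terms at their maximum
  # hand-computed score: preferred sensor, 150 m to cloud, day 209, opacity 0.2
  obs <- data.frame(day_of_year = 209, sensor_class = "preferred",
                    distance_to_cloud = 150, opacity = 0.2)
  expected <- (1 + (1 - exp(-100^2 / (2 * 50^2))) + 1 + exp(-0.5)) / 4
  expect_equal(score_candidate(obs, window = w), expected)
  # inside the hard 50 m buffer the cloud term is zero
  buf <- base; buf$distance_to_cloud <- 30
  expect_equal(score_candidate(buf, window = w), 3 / 4)
  expect_error(score_candidate(transform(base, opacity = -1), window = w),
               "non-negative")
  expect_error(score_candidate(transform(base, day_of_year = 10), window = w),
               "outside the growing-season window")
})

test_that("composite_year picks the argmax with deterministic tie-breaking", {
  w <- season_window(55)
  cands <- tibble::tibble(
    pixel_id = c(1, 1, 1, 2),
    candidate = c("a", "b", "c", "d"),
    day_of_year = c(209, 209, 180, 250),
    sensor_class = c("preferred", "preferred", "preferred", "non_preferred"),
    distance_to_cloud = c(1e6, 1e6, 1e6, 20),
    opacity = c(0.3, 0.1, 0, 0.5))
  out <- composite_year(cands, pixels = 1:3, window = w)
  expect_identical(out$candidate[out$pixel_id == 1], "b")  # ties: lower opacity
  expect_identical(out$candidate[out$pixel_id == 2], "d")  # single candidate wins
  expect_true(out$gap[out$pixel_id == 3])                  # no candidate: gap
  # scores of the winners agree with score_candidate on the same rows
  expect_equal(out$score[out$pixel_id == 2],
               score_candidate(cands[4, ], window = w))
  # a candidate outside the window is rejected, not scored
  cands2 <- cands
  cands2$day_of_year[4] <- 1
  out2 <- composite_year(cands2, pixels = 1:3, window = w)
  expect_true(out2$gap[out2$pixel_id == 2])
})

test_that("gap filling interpolates interior gaps and extends the ends", {
  f <- fill_gaps(c(10, NA, 14))
  expect_equal(f$value, c(10, 12, 14))
  expect_identical(f$filled, c(FALSE, TRUE, FALSE))
  f2 <- fill_gaps(c(NA, NA, 5, 7))
  expect_equal(f2$value, c(5, 5, 5, 7))
  f3 <- fill_gaps(c(10, NA, NA, 16))
  expect_equal(f3$value, c(10, 12, 14, 16))
  # filling never alters observed values
  set.seed(1)
  x <- rnorm(20)
  x[c(3, 9, 10, 17)] <- NA
  f4 <- fill_gaps(x)
  expect_identical(f4$value[!is.na(x)], x[!is.na(x)])
  expect_identical(sum(f4$filled), 4L)
})

test_that("validity screen applies the consecutive and total gap rules", {
  Tn <- 26L
  gap_at <- function(idx) {
    g <- rep(FALSE, Tn); g[idx] <- TRUE; g
  }
  expect_false(validity_filter(gap_at(5:7)))          # 3 consecutive
  expect_true(validity_filter(gap_at(c(5, 6, 8, 9)))) # runs of 2 only
  expect_true(validity_filter(gap_at(c(1, 4, 8, 12, 16, 20))))   # 6 total
  expect_false(validity_filter(gap_at(c(1, 4, 8, 12, 16, 20, 24)))) # 7 total
  expect_true(validity_filter(rep(FALSE, Tn)))
})

test_that("scene compositing is exact without noise and idempotent", {
  cfg <- quick_sim(noise_sd = 0, gap_prob = 0, seed = 6L)
  sc <- render_spectral(generate_truth(cfg), cfg)
  comp <- composite_scene(sc)
  expect_equal(comp$scene$layers, sc$layers)
  expect_true(all(comp$valid))

  cfg2 <- quick_sim(gap_prob = 0.08, seed = 6L)
  sc2 <- render_spectral(generate_truth(cfg2), cfg2)
  comp2 <- composite_scene(sc2)
  # observed values unchanged, all gap flags on valid pixels filled
  obs <- !sc2$nodata
  expect_identical(comp2$scene$layers$nbr[obs], sc2$layers$nbr[obs])
  comp3 <- composite_scene(comp2$scene)
  expect_identical(comp3$scene$layers, comp2$scene$layers)
  expect_identical(comp3$valid, matrix(TRUE, 96, 96) & comp3$valid)
})
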