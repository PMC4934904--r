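test_that("Mann-Kendall S and tau match the exhaustive pairwise oracle", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  mk <- mann_kendall(x)
  expect_identical(mk$s, oracle_mann_kendall_s(x))
  expect_equal(mk$tau, oracle_tau(x))
  # strictly increasing n = 10: every pair positive
  mk_up <- mann_kendall(1:10)
  expect_identical(mk_up$s, 45L)
  expect_equal(mk_up$tau, 1)
  # constant series: S = 0, tau 0, p 1
  mk_const <- mann_kendall(rep(2, 8))
  expect_identical(mk_const$s, 0L)
  expect_equal(mk_const$tau, 0)
  expect_equal(mk_const$p_value, 1)
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    x <- if (i %% 3 == 0) sample(1:4, n, replace = TRUE) else rnorm(n)
    mk <- mann_kendall(x)
    expect_identical(mk$s, oracle_mann_kendall_s(x))
    expect_equal(mk$tau, oracle_tau(x))
    # independent cross-check of tau against base R
    expect_equal(mk$tau, suppressWarnings(cor(x, seq_along(x), method = "kendall")),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Kendall is invariant where it must be", {
  set.seed(4)
  x <- rnorm(15)
  base <- mann_kendall(x)
  shifted <- mann_kendall(x + 100)
  expect_identical(base$s, shifted$s)
  expect_equal(base$p_value, shifted$p_value)
  # tau is invariant to strictly monotone transforms of the values
  expect_equal(mann_kendall(exp(x))$tau, base$tau)
  expect_equal(mann_kendall(rank(x))$tau, base$tau)
})

test_that("Theil-Sen matches the pairwise-median oracle and resists outliers", {
  t <- 1:12
  expect_equal(theil_sen(2 * t + 1, t)$slope, 2)
  expect_equal(theil_sen(2 * t + 1, t)$intercept, 1)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    expect_equal(theil_sen(x)$slope, oracle_sen_slope(x))
  }
  # one gross outlier in 11 points barely moves the slope
  x <- 2 * (1:11) + 1
  x[6] <- 100
  expect_lt(abs(theil_sen(x)$slope - 2), 0.2)
})

test_that("tidy and glance expose the fitted objects as tibbles", {
  mk <- mann_kendall(c(3, 1, 4, 1, 5, 9, 2, 6))
  td <- generics::tidy(mk)
  expect_identical(td$statistic, mk$s)
  expect_identical(td$p.value, mk$p_value)
  ts <- theil_sen(2 * (1:8) - 3)
  expect_equal(generics::glance(ts)$slope, 2)
  expect_identical(generics::tidy(ts)$term, c("(Intercept)", "slope"))
})

test_that("block bootstrap intervals behave on signal and are reproducible", {
  x <- seq(0, 5, length.out = 26)
  set.seed(10)
  ci <- block_bootstrap_ci(x)
  # noiseless linear series: blocks preserve local order, so the interval sits
  # tight against tau = 1 (wrapped circular blocks keep it just below)
  expect_lte(ci[["high"]], 1)
  expect_gte(ci[["high"]], 0.9)
  expect_gt(ci[["low"]], 0.4)
  expect_lt(ci[["high"]] - ci[["low"]], 0.5)
  set.seed(10)
  expect_identical(block_bootstrap_ci(x), ci)
  expect_warning(block_bootstrap_ci(x, B = 50L), "100")
  expect_error(block_bootstrap_ci(1:4, block_length = 3), "too short")
  # i.i.d. noise: the interval usually covers zero
  covered <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(26)
    ci <- block_bootstrap_ci(x, B = 200L)
    ci[["low"]] <= 0 && ci[["high"]] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("change classification partitions by significance and the 90th percentile", {
  mk_table <- function(slopes, ps) {
    structure(tibble::tibble(
      landscape_id = sprintf("L%03d", seq_along(slopes)),
      p_value = ps, sen_slope = slopes),
      class = c("fp_trend_table", class(tibble::tibble())))
  }
  # 100 significant landscapes with |slope| 1..100: exactly the top decile high
  tb <- mk_table(-(1:100), rep(0.001, 100))
  cl <- classify_change(tb)
  expect_identical(sum(cl$class == "high"), 10L)
  expect_true(all(cl$landscape_id[cl$class == "high"] == sprintf("L%03d", 91:100)))
  expect_identical(sum(cl$class == "moderate"), 90L)
  # non-significant landscapes are no_change regardless of slope
  tb2 <- mk_table(c(-(1:20), -50), c(rep(0.001, 20), 0.5))
  cl2 <- classify_change(tb2)
  expect_identical(as.character(cl2$class[21]), "no_change")
  # p = 0.04 with a small slope: significant but moderate
  expect_identical(as.character(cl2$class[1]), "moderate")
  # all non-significant: everything no_change
  cl3 <- classify_change(mk_table(1:5, rep(0.9, 5)))
  expect_true(all(cl3$class == "no_change"))
  expect_warning(classify_change(mk_table(1:5, rep(0.01, 5))), "fewer than 10")
})

test_that("stratum summaries recover injected slopes and orderings", {
  years <- 1985:2010
  make_tbl <- function(slopes, stratum, sd = 0.5) {
    dplyr::bind_rows(lapply(seq_along(slopes), function(i) {
      tibble::tibble(landscape_id = paste0(stratum, i), extent_ha = 5000,
                     year = years, stratum = stratum,
                     forest_cover = 70 + slopes[i] * (years - 1985) +
                       rnorm(length(years), sd = sd))
    }))
  }
  set.seed(12)
  tbl <- make_tbl(rnorm(50, -0.1, 0.01), "A")
  st <- stratum_trends(tbl, "forest_cover", B = 200L)
  expect_lt(abs(st$median_slope - (-0.1)), 0.03)
  expect_true(st$ci_low <= st$median_slope & st$median_slope <= st$ci_high)
  # identical landscapes: zero-width interval at the common slope
  one <- make_tbl(-0.2, "B", sd = 0)
  same <- dplyr::bind_rows(lapply(1:6, function(i) {
    x <- one; x$landscape_id <- paste0("B", i); x
  }))
  stb <- stratum_trends(same, "forest_cover", B = 50L)
  expect_equal(stb$median_slope, -0.2)
  expect_equal(stb$ci_low, stb$ci_high)
  # two strata with different injected slopes: ordering recovered
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    two <- dplyr::bind_rows(make_tbl(rnorm(10, -0.15, 0.02), "steep"),
                            make_tbl(rnorm(10, -0.05, 0.02), "mild"))
    st2 <- stratum_trends(two, "forest_cover", B = 50L)
    st2$median_slope[st2$stratum == "steep"] <
      st2$median_slope[st2$stratum == "mild"]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
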