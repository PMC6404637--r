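test_that("avalanche detection splits runs of active bins", {
  # occupancy pattern 0,2,3,1,0,3,0 -> two avalanches of sizes 6 and 3
  t <- c(0.31, 0.35, 0.61, 0.62, 0.65, 0.91, 1.51, 1.52, 1.55)
  av <- detect_avalanches(t, dt_bin = 0.3)
  expect_equal(av$sizes, c(6L, 3L))
  expect_equal(av$n_bins, c(3L, 1L))
  expect_equal(av$first_bin, c(2L, 3L))
  expect_equal(av$second_bin, c(3L, 0L))

  expect_length(detect_avalanches(numeric(0), 0.3)$sizes, 0)
  # all spikes in one bin
  one <- detect_avalanches(rep(0.05, 7), 0.3)
  expect_equal(one$sizes, 7L)
  expect_equal(one$n_bins, 1L)
})

test_that("avalanche sizes conserve the total spike count", {
  set.seed(1)
  for (k in 1:5) {
    t <- sort(runif(500 + 100 * k, 0, 300))
    av <- detect_avalanches(t, dt_bin = 0.5)
    expect_equal(sum(av$sizes), length(t))
    # a global shift by a multiple of the bin width is irrelevant
    av2 <- detect_avalanches(t + 5 * 0.5, dt_bin = 0.5)
    expect_equal(av2$sizes, av$sizes)
  }
})

test_that("branching parameter follows the descendants/ancestors mean", {
  mk <- function(bins) {     # build an avalanche_set from per-bin counts
    t <- unlist(lapply(seq_along(bins), function(g) {
      unlist(lapply(seq_along(bins[[g]]), function(b)
        rep((g - 1) * 100 + b * 0.3 + 0.01, bins[[g]][b])))
    }))
    detect_avalanches(t, dt_bin = 0.3)
  }
  expect_equal(branching_parameter(mk(list(c(1, 3, 2))))$sigma, 3)
  expect_equal(branching_parameter(mk(list(c(2, 4), 1)))$sigma, 1)
  est <- branching_parameter(mk(list(c(2, 4), 1)), include_single_bin = FALSE)
  expect_equal(est$sigma, 2)
  expect_error(branching_parameter(detect_avalanches(numeric(0), 0.3)),
               "empty")
})

test_that("branching estimates recover the offspring mean of the process", {
  r <- branching_raster(0.8, 10000, seed = 2)
  av <- detect_avalanches(r$time, 0.3)
  est <- branching_parameter(av)
  expect_gt(est$sigma, 0.75); expect_lt(est$sigma, 0.85)
  # extinct-at-once process: every avalanche single-bin, sigma 0
  r0 <- branching_raster(0, 500, seed = 3)
  av0 <- detect_avalanches(r0$time, 0.3)
  expect_true(all(av0$n_bins == 1))
  expect_equal(branching_parameter(av0)$sigma, 0)
})

test_that("critical branching has a heavier size tail than subcritical", {
  sub <- detect_avalanches(branching_raster(0.8, 5000, seed = 4)$time, 0.3)
  crit <- detect_avalanches(branching_raster(1.0, 5000, seed = 4)$time, 0.3)
  qs <- quantile(sub$sizes, c(0.9, 0.99))
  qc <- quantile(crit$sizes, c(0.9, 0.99))
  expect_true(all(qc >= qs))
  expect_gt(max(crit$sizes), max(sub$sizes))
  # shallower fitted exponent at criticality
  fs <- fit_power_law(sub$sizes)
  fc <- fit_power_law(crit$sizes)
  expect_gt(fc$alpha, fs$alpha)
})

test_that("power-law fitting recovers known exponents", {
  s <- powerlaw_sizes(-1.5, s_max = 1e4, n = 1e4, seed = 7)
  f <- fit_power_law(s)
  expect_gt(f$alpha, -1.6); expect_lt(f$alpha, -1.4)
  expect_false(f$low_count)
  expect_true(f$ks >= 0 && f$ks <= 1)
  expect_true(f$s_range[1] >= 1 && f$s_range[2] <= max(s) * 1.26)

  s3 <- powerlaw_sizes(-3, s_max = 1e4, n = 1e4, seed = 8)
  f3 <- fit_power_law(s3)
  expect_lt(f3$alpha, f$alpha)        # ordered recovery
  expect_lt(abs(f3$alpha - -3), 0.45)
})

test_that("degenerate and non-power-law inputs are flagged", {
  expect_error(fit_power_law(rep(5, 100)), "unfittable")
  expect_true(fit_power_law(powerlaw_sizes(-1.5, n = 10, seed = 1),
                            min_count = 50)$low_count)
  # geometric (exponential-tailed) sizes fit strictly worse than power law
  set.seed(9)
  geo <- rgeom(1e4, 1 / 3) + 1
  f_geo <- fit_power_law(geo)
  f_pl <- fit_power_law(powerlaw_sizes(-1.5, n = 1e4, seed = 9))
  expect_gt(f_geo$ks, f_pl$ks)
})

test_that("adaptive bin width doubles the mean inter-event interval", {
  t <- sort(runif(2000, 0, 1000))
  av <- detect_avalanches(t, dt_bin = "adaptive")
  expect_equal(av$dt_bin, 2 * mean(diff(t)), tolerance = 1e-12)
})
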