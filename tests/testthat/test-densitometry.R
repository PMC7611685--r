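std_windows <- band_windows(supercoiled = c(130, 175), relaxed = c(40, 85),
                            linear = c(85, 120))

test_that("lane profiles sum intensities across the lane and respect bounds", {
  img <- matrix(0, 50, 30)
  p <- lane_profile(img, c(1, 50, 5, 15))
  expect_true(all(p$intensity == 0))
  expect_equal(p$position, 1:50)
  expect_error(lane_profile(img, c(0, 50, 5, 15)), "bounds")
  expect_error(lane_profile(img, c(10, 5, 5, 15)), "bounds")

  # locality: swapping rectangles swaps profiles
  img[, 1:10] <- 1; img[, 21:30] <- 2
  pa <- lane_profile(img, c(1, 50, 1, 10))
  pb <- lane_profile(img, c(1, 50, 21, 30))
  expect_equal(pa$intensity, rep(10, 50))
  expect_equal(pb$intensity, rep(20, 50))
})

test_that("profile integral preserves the rendered band intensity", {
  g <- simulate_gel_image(list(c(1, 0, 0)), noise_sd = 0, amplitude = 500)
  p <- lane_profile(g$image, g$lane_rects[[1]])
  expect_equal(sum(p$intensity), 500, tolerance = 0.01 * 500)
})

test_that("baseline subtraction removes flat and ramped backgrounds", {
  flat <- data.frame(position = 1:100, intensity = rep(7, 100))
  expect_equal(subtract_baseline(flat, "linear_endpoints")$intensity,
               rep(0, 100))
  expect_equal(subtract_baseline(flat, "snip")$intensity, rep(0, 100))
  expect_equal(subtract_baseline(flat, "rolling_minimum")$intensity,
               rep(0, 100))

  zero <- data.frame(position = 1:100, intensity = rep(0, 100))
  expect_equal(subtract_baseline(zero)$intensity, rep(0, 100))

  # Gaussian band on a linear ramp: area within the band window within 2%
  x <- 1:300
  band <- 800 * dnorm(x, 150, 5)
  prof <- data.frame(position = x, intensity = 0.3 * x + band)
  corr <- subtract_baseline(prof, "snip", window = 61)
  sel <- x >= 120 & x < 180
  expect_equal(sum(corr$intensity[sel]), sum(band[sel]),
               tolerance = 0.02 * sum(band[sel]))
  expect_error(subtract_baseline(prof, "snip", window = 1000), "window")
})

test_that("band quantification: shares of total window signal", {
  x <- 1:200
  mk <- function(a_s, a_r, a_l)
    data.frame(position = x, intensity = a_s * dnorm(x, 150, 4) +
                 a_r * dnorm(x, 60, 4) + a_l * dnorm(x, 100, 4))
  # single supercoiled band
  expect_equal(unname(quantify_bands(mk(100, 0, 0), std_windows)),
               c(100, 0, 0), tolerance = 1e-9)
  # 50:40:10 well-separated bands within 0.5 percentage points
  pct <- quantify_bands(mk(50, 40, 10), std_windows)
  expect_lt(max(abs(pct - c(supercoiled = 50, relaxed = 40, linear = 10))), 0.5)
  expect_equal(sum(pct), 100, tolerance = 1e-6)
  # symmetric two-band lane: congruent windows around each centre
  sym <- band_windows(supercoiled = c(130, 175), relaxed = c(40, 80),
                      linear = c(80, 120))
  # (half-open windows on the integer grid shift one boundary pixel, so
  # symmetry is exact only to the sub-ppm tail mass at that pixel)
  pct <- quantify_bands(mk(0, 30, 30), sym)
  expect_equal(unname(pct), c(0, 50, 50), tolerance = 1e-4)
  # scale invariance
  p1 <- mk(50, 40, 10); p2 <- p1; p2$intensity <- 37.5 * p2$intensity
  expect_equal(quantify_bands(p1, std_windows), quantify_bands(p2, std_windows))
  # zero signal errors rather than returning NaN
  expect_error(quantify_bands(mk(0, 0, 0), std_windows), "no band signal")
})

test_that("signal outside every window triggers a smear warning", {
  x <- 1:200
  prof <- data.frame(position = x, intensity = 100 * dnorm(x, 150, 4) +
                       30 * dnorm(x, 10, 3))
  expect_warning(quantify_bands(prof, std_windows), "outside")
})

test_that("window auto-detection brackets the true band centres", {
  g <- simulate_gel_image(list(c(0.5, 0.4, 0.1)), noise_sd = 0)
  prof <- subtract_baseline(lane_profile(g$image, g$lane_rects[[1]]))
  w <- auto_detect_windows(prof)
  for (sp in c("supercoiled", "relaxed", "linear")) {
    ctr <- g$centers[[sp]]
    expect_true(w[[sp]][1] <= ctr && ctr < w[[sp]][2])
  }
  flat <- data.frame(position = 1:100, intensity = rep(0, 100))
  expect_error(auto_detect_windows(flat), "flat profile")
  two <- data.frame(position = 1:200,
                    intensity = dnorm(1:200, 60, 4) + dnorm(1:200, 150, 4))
  expect_error(auto_detect_windows(two), "3 bands")
})

test_that("window labels follow the configured migration order", {
  g <- simulate_gel_image(list(c(0.4, 0.3, 0.3)), noise_sd = 0)
  prof <- subtract_baseline(lane_profile(g$image, g$lane_rects[[1]]))
  w <- auto_detect_windows(prof)  # default: relaxed slowest, supercoiled fastest
  expect_lt(w$relaxed[2], w$linear[2])
  expect_lt(w$linear[2], w$supercoiled[2])
  w2 <- auto_detect_windows(prof, migration_order = c("supercoiled", "linear",
                                                      "relaxed"))
  expect_lt(w2$supercoiled[2], w2$relaxed[2])
})

test_that("band windows must be disjoint and well-formed", {
  expect_error(band_windows(c(10, 5), c(20, 30), c(40, 50)), "start < end")
  expect_error(band_windows(c(10, 25), c(20, 30), c(40, 50)), "overlap")
  # half-open adjacency is allowed
  w <- band_windows(c(10, 20), c(20, 30), c(30, 40))
  expect_s3_class(w, "band_windows")
})

test_that("synthetic gels round-trip through densitometry within 2 points", {
  lanes <- list(c(0.97, 0.02, 0.01), c(0.5, 0.4, 0.1), c(0.31, 0.69, 0.001),
                c(0.1, 0.5, 0.4))
  # separation >= 4 sigma (here ~10 sigma) and SNR >= 20
  g <- simulate_gel_image(lanes, noise_sd = 0.05, background_ramp = 0.3,
                          amplitude = 1000, seed = 7)
  res <- quantify_gel(g$image, g$lane_rects, windows = std_windows)
  for (i in seq_along(lanes)) {
    got <- unlist(res[i, c("pct_supercoiled", "pct_relaxed", "pct_linear")])
    expect_lt(max(abs(got - 100 * lanes[[i]])), 2)
    expect_equal(sum(got), 100, tolerance = 1e-6)
  }
})
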