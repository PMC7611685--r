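ebrt_grid <- c(0, 0.5, 1, 2, 5, 10, 20, 40)

test_that("replicate summaries give textbook means and sample SDs", {
  d <- gel_dataset(x = rep(1, 3), s = c(50, 50, 50), r = c(40, 40, 40),
                   l = c(10, 10, 10))
  sm <- summarize_replicates(d)
  expect_equal(sm$mean_supercoiled, 50)
  expect_equal(sm$sd_supercoiled, 0)

  d <- gel_dataset(x = rep(2, 3), s = c(40, 50, 60), r = c(30, 25, 20),
                   l = c(30, 25, 20))
  sm <- summarize_replicates(d)
  expect_equal(sm$mean_supercoiled, 50)
  expect_equal(sm$sd_supercoiled, 10)  # sample SD, n - 1 denominator
  expect_equal(sm$n, 3)
  expect_error(summarize_replicates(d[0, ]), "empty")
})

test_that("pooled replicate SD estimates the generating noise", {
  d <- simulate_gel_dataset(0.5, 0.01, s0 = 0.97, grid = c(0, 1, 2), n = 50,
                            sd = 5, seed = 11)
  sm <- summarize_replicates(d)
  # at mid-range proportions clipping is negligible; renormalization shares
  # the three species' noise, so per-species SD is somewhat below the raw 5
  pooled <- mean(c(sm$sd_supercoiled, sm$sd_relaxed))
  expect_gt(pooled, 3)
  expect_lt(pooled, 7)
})

test_that("noiseless data are recovered exactly (paper rate pairs)", {
  for (rp in list(c(1.21, 0.017), c(0.45, 0.004))) {
    d <- simulate_gel_dataset(rp[1], rp[2], s0 = 0.97, grid = ebrt_grid,
                              n = 3, sd = 0, seed = 1)
    f <- fit_topology(d)
    expect_true(f$converged)
    truth <- c(ksr = rp[1], krl = rp[2], s0 = 0.97)
    expect_lt(max(abs(coef(f) - truth) / truth), 1e-6)
  }
  # time-axis design
  d <- simulate_gel_dataset(0.59, 0.003, s0 = 0.92, axis = "time", n = 3,
                            sd = 0, seed = 1)
  f <- fit_topology(d)
  expect_lt(max(abs(coef(f) - c(0.59, 0.003, 0.92)) /
                c(0.59, 0.003, 0.92)), 1e-6)
  expect_equal(f$axis, "time")
})

test_that("a zero relaxed-to-linear rate sits cleanly on the boundary", {
  d <- simulate_gel_dataset(0.8, 0, s0 = 1, grid = c(0, 1, 2, 4, 8), n = 2,
                            sd = 0, seed = 1)
  f <- fit_topology(d)
  expect_lt(unname(coef(f)["krl"]), 1e-8)
  expect_true(f$at_boundary[["krl"]])
  lres <- residuals(f)[grepl("^l@", names(residuals(f)))]
  expect_lt(max(abs(lres)), 1e-6)
})

test_that("the initial guess recovers a pure exponential decay exactly", {
  d <- simulate_gel_dataset(0.59, 0.003, s0 = 1, axis = "time", n = 1,
                            sd = 0, seed = 1)
  g <- initial_guess(d)
  expect_equal(unname(g["ksr"]), 0.59, tolerance = 1e-6)
  expect_equal(unname(g["krl"]), 0.59 / 50, tolerance = 1e-6)

  # a zero-supercoiled point at high exposure must not break the log fit
  d2 <- gel_dataset(x = c(0, 1, 2, 50), s = c(100 * exp(-0.59 * c(0, 1, 2)), 0),
                    r = c(0, 30, 50, 60), l = c(0, 10, 20, 40), axis = "time")
  g2 <- initial_guess(d2)
  expect_true(all(is.finite(g2)))
  expect_equal(unname(g2["ksr"]), 0.59, tolerance = 1e-6)
})

test_that("rescaling all SDs leaves the point estimates unchanged", {
  # replicate triplets perturbed by a lane-sum-preserving pattern, so every
  # species has SD = sqrt(3) * e at every exposure and scaling e scales all
  # SDs by the same constant (all SDs stay above the floor)
  make <- function(e) {
    grid <- c(0, 0.25, 0.5, 1, 2)
    tr <- predict_topology(grid, 1.21, 0.017, init = plasmid_init(0.8))
    pat <- list(c(-2, 1, 1), c(1, -2, 1), c(1, 1, -2))
    d <- do.call(rbind, lapply(seq_along(grid), function(i)
      data.frame(x = grid[i], replicate = 1:3,
                 s = 100 * tr$s[i] + e * pat[[1]] + 7,
                 r = 100 * tr$r[i] + e * pat[[2]] + 7,
                 l = 100 * tr$l[i] + e * pat[[3]] + 7)))
    gel_dataset(x = d$x, s = d$s, r = d$r, l = d$l, replicate = d$replicate)
  }
  f1 <- fit_topology(make(1), sd_floor = 0.1)
  f3 <- fit_topology(make(3), sd_floor = 0.1)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-6)
  # but the reported SEs do scale when covariance rescaling is off
  g1 <- fit_topology(make(1), sd_floor = 0.1, scale_covariance = FALSE)
  g3 <- fit_topology(make(3), sd_floor = 0.1, scale_covariance = FALSE)
  expect_equal(g3$se[["ksr"]] / g1$se[["ksr"]], 3, tolerance = 1e-3)
})

test_that("refitting the model's own predictions is a fixed point", {
  d <- simulate_gel_dataset(1.21, 0.017, s0 = 0.97, n = 6, sd = 5, seed = 5)
  f1 <- fit_topology(d)
  pr <- predict(f1, newdata = sort(unique(d$x)))
  d2 <- gel_dataset(x = pr$x, s = 100 * pr$s, r = 100 * pr$r, l = 100 * pr$l)
  f2 <- fit_topology(d2, start = coef(f1)[c("ksr", "krl", "s0")])
  expect_equal(coef(f2), coef(f1), tolerance = 1e-6)
})

test_that("the optimum is reached from the data-driven and perturbed starts", {
  agree <- 0L; total <- 0L
  for (s in 1:20) {
    d <- simulate_gel_dataset(1.21, 0.017, s0 = 0.97, n = 6, sd = 5, seed = s)
    f0 <- fit_topology(d)
    ok <- TRUE
    for (fac in c(1 / 3, 3)) {
      fs <- fit_topology(d, start = c(ksr = 1.21 * fac, krl = 0.017 / fac))
      if (max(abs(coef(fs) - coef(f0))) > 1e-4) ok <- FALSE
    }
    total <- total + 1L
    agree <- agree + ok
  }
  expect_gte(agree / total, 0.9)
})

test_that("stochastic designs recover the rates and their ordering", {
  est <- t(vapply(1:30, function(s) {
    d <- simulate_gel_dataset(1.21, 0.017, s0 = 0.97, n = 6, sd = 5, seed = s)
    f <- fit_topology(d)
    c(coef(f)[c("ksr", "krl")], se_ksr = f$se[["ksr"]])
  }, numeric(3)))
  expect_lt(abs(median(est[, "ksr"]) - 1.21), 2 * median(est[, "se_ksr"]))
  expect_true(all(est[, "ksr"] > est[, "krl"]))
})

test_that("degenerate fitting inputs are refused with clear errors", {
  d1 <- gel_dataset(x = rep(0, 3), s = c(97, 95, 96), r = c(2, 4, 3),
                    l = c(1, 1, 1))
  expect_error(fit_topology(d1), "2 distinct exposure")
  d2 <- simulate_gel_dataset(1, 0.01, n = 1, sd = 0, grid = c(0, 1), seed = 1)
  f <- fit_topology(d2, fit_s0 = FALSE, s0 = 0.97)  # 6 obs, 2 parameters: fine
  expect_s3_class(f, "topo_fit")
  expect_error(fit_topology(d2, start = c(bogus = 1)), "unknown start")
})

test_that("fit methods are coherent: predict, fitted, residuals, simulate", {
  d <- simulate_gel_dataset(1.21, 0.017, s0 = 0.97, n = 4, sd = 5, seed = 9)
  f <- fit_topology(d)
  pr <- predict(f, newdata = c(0, 1, 2))
  expect_equal(pr$x, c(0, 1, 2))
  expect_true(all(abs(pr$s + pr$r + pr$l - coef(f)[["s0"]]) < 1e-9))
  expect_equal(nrow(fitted(f)), length(unique(d$x)))
  expect_equal(length(residuals(f)), f$n_obs)
  sims <- simulate(f, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "gel_dataset")
  expect_output(print(f), "Exposure axis")
  expect_output(print(summary(f)), "reduced chi-square")
  # vcov is symmetric PSD and SEs match its diagonal
  v <- vcov(f)
  expect_equal(v, t(v), tolerance = 1e-10)
  expect_true(all(eigen(v, only.values = TRUE)$values > -1e-12))
  expect_equal(unname(f$se), unname(sqrt(diag(v))), tolerance = 1e-10)
})
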