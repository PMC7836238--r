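test_that("ramp signal spans 0 to 1 along x, constant in y", {
  sig <- signal_spec("ramp2d")
  mu <- array(make_signal(sig), dim = c(100, 100))
  expect_equal(mu[, 1], (0:99) / 99)
  expect_equal(mu[, 57], mu[, 1])           # constant in y
  expect_equal(min(mu), 0)
  expect_equal(max(mu), 1)
  expect_equal(mu[41, 7], 40 / 99)
})

test_that("smoothed phantoms have the documented peak intensities", {
  circ <- make_signal(signal_spec("circle2d", shape = c(60, 60), radius = 18))
  expect_lte(max(circ), 1)                   # 2D disk is not rescaled
  expect_gt(max(circ), 0.99)                 # interior plateau of a wide disk
  sph <- make_signal(signal_spec("sphere3d_small", shape = c(24, 24, 24),
                                 radius = 5))
  expect_equal(max(sph), 1)                  # imagewise rescaling to max 1
  ms_spec <- signal_spec("multi_sphere3d", shape = c(40, 40, 40),
                         radii = c(4, 6),
                         centers = rbind(c(14, 14, 14), c(26, 26, 26)))
  ms <- make_signal(ms_spec)
  expect_equal(max(ms), 1)
  a <- array(ms, dim = c(40, 40, 40))
  expect_equal(a[14, 14, 14], 1)             # each phantom centre at magnitude 1
  expect_equal(a[26, 26, 26], 1)
})

test_that("smoothed noise is standardized to the requested sd field", {
  set.seed(81)
  g <- domain_grid(c(15, 15))
  st <- make_noise(g, noise_spec(), 2500)
  sds <- apply(st$data, 1, sd)
  # every voxel's empirical sd close to 1 (3 MC SEs ~ 4.2%; allow the max
  # over 225 voxels a little more room)
  expect_lt(max(abs(sds - 1)), 0.08)
  # heterogeneous: sd rises linearly along the last axis from 0.5 to 1.5
  st2 <- make_noise(g, noise_spec(sd = "linear"), 2500)
  sds2 <- array(apply(st2$data, 1, sd), dim = c(15, 15))
  prof <- 0.5 + (0:14) / 14
  expect_equal(colMeans(t(sds2) / prof), rep(1, 15), tolerance = 0.05)
  expect_lt(mean(sds2[, 1]), mean(sds2[, 15]))
})

test_that("noise autocorrelation matches the analytic kernel correlation", {
  set.seed(82)
  g <- domain_grid(c(21, 21))
  st <- make_noise(g, noise_spec(), 4000)
  sigma <- kernel_sigma(3)
  center <- 10 + 10 * 21                     # voxel (10, 11), away from edges
  for (lag in 1:3) {
    rho_hat <- cor(st$data[center, ], st$data[center + lag, ])
    rho <- exp(-lag^2 / (4 * sigma^2))
    expect_lt(abs(rho_hat - rho), 0.05)
  }
})

test_that("homogeneous noise leaves the true effect equal to the signal", {
  sig <- signal_spec("circle2d", shape = c(30, 30), radius = 9)
  mu <- make_signal(sig)
  g <- domain_grid(sig$shape)
  tr <- truth_set(mu, g, noise_spec(), 0.8)
  expect_equal(tr$d, mu)
  expect_equal(tr$a_c, mu >= 0.8)
  # heterogeneous: d = mu / sd field
  tr2 <- truth_set(mu, g, noise_spec(sd = "linear"), 0.8)
  sdf <- cohensdCS:::noise_sd_field(g, noise_spec(sd = "linear"))
  expect_equal(tr2$d, mu / sdf)
})

test_that("coverage assessment: vacuous truth, subset violations, interpolated near-miss", {
  g <- domain_grid(c(2, 2))
  base <- structure(list(
    upper = rep(FALSE, 4), lower = rep(TRUE, 4),
    point_estimate = rep(FALSE, 4),
    decision_upper = rep(-1, 4), decision_lower = rep(1, 4),
    summary = list(grid = g), degenerate = FALSE), class = "confidence_sets")
  truth0 <- structure(list(d = rep(0, 4), a_c = rep(FALSE, 4), c = 0.8,
                           a = integer(0), b = integer(0), w = numeric(0),
                           grid = g), class = "truth_set")
  expect_true(assess_coverage_trial(base, truth0))    # empty upper, full lower

  # one upper voxel outside the true set is an immediate failure
  viol <- base; viol$upper[2] <- TRUE
  expect_false(assess_coverage_trial(viol, truth0))

  # lattice checks pass but an interpolated true-boundary point violates the
  # lower CS: true d crosses c between voxels 1 and 2 at w = 0.5, where the
  # interpolated lower decision field dips negative
  truth1 <- structure(list(d = c(0.7, 0.9, 0.7, 0.9), a_c = c(FALSE, TRUE, FALSE, TRUE),
                           c = 0.8, a = c(1L, 3L), b = c(2L, 4L), w = c(0.5, 0.5),
                           grid = g), class = "truth_set")
  near <- base
  near$lower <- c(FALSE, TRUE, FALSE, TRUE)           # A_c still inside lower
  near$decision_lower <- c(-3, 1, -3, 1)              # interpolates to -1 < 0
  expect_false(assess_coverage_trial(near, truth1))
  near$decision_lower <- c(-0.5, 1, -0.5, 1)          # interpolates to +0.25
  expect_true(assess_coverage_trial(near, truth1))
})

test_that("upper-CS sensitivity is a plain voxel fraction", {
  g <- domain_grid(c(2, 2))
  truth <- structure(list(d = c(1, 1, 0, 0), a_c = c(TRUE, TRUE, FALSE, FALSE),
                          c = 0.8, a = integer(0), b = integer(0),
                          w = numeric(0), grid = g), class = "truth_set")
  mk <- function(upper) structure(list(upper = upper, summary = list(grid = g)),
                                  class = "confidence_sets")
  expect_equal(upper_cs_sensitivity(mk(c(TRUE, TRUE, FALSE, FALSE)), truth), 1)
  expect_equal(upper_cs_sensitivity(mk(rep(FALSE, 4)), truth), 0)
  expect_equal(upper_cs_sensitivity(mk(c(TRUE, FALSE, FALSE, FALSE)), truth), 0.5)
  truth$a_c <- rep(FALSE, 4)
  expect_error(upper_cs_sensitivity(mk(rep(FALSE, 4)), truth), "undefined")
})

test_that("run_experiment is reproducible and returns a tidy table", {
  cfg <- sim_config(n_trials = 3, n_boot = 60, sample_sizes = c(12, 24),
                    levels = c(0.80, 0.95), c = 0.8, algorithms = c(2, 3),
                    seed = 90)
  sig <- signal_spec("circle2d", shape = c(20, 20), radius = 6)
  res <- run_experiment(cfg, sig, noise_spec())
  expect_s3_class(res, "data.frame")
  expect_equal(nrow(res), 2 * 2 * 2)         # N x level x algorithm
  expect_named(res, c("signal", "noise", "algorithm", "n", "level", "trials",
                      "n_boot", "coverage", "coverage_se", "sensitivity",
                      "seed"))
  expect_true(all(res$coverage >= 0 & res$coverage <= 1))
  expect_true(all(res$sensitivity >= 0 & res$sensitivity <= 1))
  res2 <- run_experiment(cfg, sig, noise_spec())
  expect_identical(res, res2)                # deterministic given the seed
})

test_that("algorithm 1 over-covers relative to algorithm 2 in small samples", {
  # the limiting-variance standardization overestimates the approximating
  # field's spread at N = 30, so on common trial data its coverage dominates
  cfg <- sim_config(n_trials = 60, n_boot = 300, sample_sizes = 30,
                    levels = 0.80, c = 0.8, algorithms = c(1, 2), seed = 92)
  res <- run_experiment(cfg, signal_spec("ramp2d"), noise_spec())
  cov1 <- res$coverage[res$algorithm == 1]
  cov2 <- res$coverage[res$algorithm == 2]
  expect_gte(cov1, cov2)
})

test_that("heterogeneous noise variance barely moves empirical coverage", {
  mk <- function(noi, seed) run_experiment(
    sim_config(n_trials = 80, n_boot = 300, sample_sizes = 120,
               levels = 0.95, c = 0.8, algorithms = 3, seed = seed),
    signal_spec("circle2d"), noi)
  hom <- mk(noise_spec(), 93)
  het <- mk(noise_spec(sd = "linear"), 93)
  se <- sqrt(2 * 0.95 * 0.05 / 80)
  expect_lt(abs(hom$coverage - het$coverage), 3 * se)
})

test_that("an empty true excursion set demands an empty upper set", {
  # null signal: coverage reduces to the upper CS being empty
  cfg <- sim_config(n_trials = 4, n_boot = 60, sample_sizes = 15,
                    levels = 0.95, c = 0.8, algorithms = 2, seed = 91)
  sig <- signal_spec("circle2d", shape = c(12, 12), radius = 3, magnitude = 0)
  res <- suppressWarnings(run_experiment(cfg, sig, noise_spec()))
  expect_true(is.na(res$sensitivity))
  expect_equal(res$coverage, 1)              # upper empty in all trials
})
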