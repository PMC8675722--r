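test_that("analytic-signal phase tracks a pure tone", {
  fs <- 250
  tt <- (0:499) / fs
  x <- cos(2 * pi * 10 * tt)
  pe <- instantaneous_phase(one_trial_epochs(rbind(x), fs))
  ph <- pe$phases[1, 1, ]
  inc <- diff(ph[100:400]) %% (2 * pi)
  expect_lt(mean(abs(inc - 2 * pi * 10 / fs)), 1e-3)

  # quadrature pair: sin lags cos by pi/2
  pe2 <- instantaneous_phase(one_trial_epochs(
    rbind(cos(2 * pi * 10 * tt), sin(2 * pi * 10 * tt)), fs))
  d <- (pe2$phases[1, 1, ] - pe2$phases[1, 2, ]) %% (2 * pi)
  expect_equal(d[100:400], rep(pi / 2, 301), tolerance = 1e-6)

  # sign flip shifts phase by pi everywhere
  pe3 <- instantaneous_phase(one_trial_epochs(rbind(x, -x), fs))
  d3 <- (pe3$phases[1, 1, ] - pe3$phases[1, 2, ]) %% (2 * pi)
  expect_equal(d3, rep(pi, 500), tolerance = 1e-6)

  expect_error(instantaneous_phase(one_trial_epochs(matrix(1, 1, 100))),
               "zero variance")
})

test_that("PLV is the modulus of the mean phasor of the phase difference", {
  set.seed(4)
  phi <- runif(50, -pi, pi)
  expect_equal(plv(phi, phi), 1)
  expect_equal(plv(c(0, pi, 0, pi), c(0, 0, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(plv(c(0, pi / 2), c(0, 0)), sqrt(2) / 2)      # |(1 + i)/2|
  expect_equal(plv(phi, rev(phi)), plv(rev(phi), phi))       # symmetric
  expect_error(plv(1:3, 1:4), "mismatch")
})

test_that("PLV dissimilarity matrices behave as distances", {
  set.seed(11)
  fs <- 250
  x <- rnorm(600)
  es <- one_trial_epochs(rbind(x, x, rnorm(600)), fs)
  dm <- plv_distance_matrix(es, "per_trial")[[1]]
  expect_equal(dm[1, 2], 0, tolerance = 1e-12)   # duplicated channel
  expect_identical(unclass(dm), t(unclass(dm)))  # exact symmetry
  expect_equal(diag(unclass(dm)), rep(0, 3))
  expect_identical(attr(dm, "metric"), "plv_dissimilarity")

  # independent signals: dissimilarity near 1 at N = 1e4
  es2 <- one_trial_epochs(matrix(rnorm(4 * 1e4), 4), fs)
  dm2 <- plv_distance_matrix(es2, "per_trial")[[1]]
  expect_equal(max(abs(dm2[upper.tri(dm2)] - 1)), 0, tolerance = 0.05)

  expect_error(plv_distance_matrix(one_trial_epochs(matrix(rnorm(100), 1))),
               "2 channels")
})

test_that("common phase shifts leave PLV dissimilarity invariant", {
  fs <- 250
  tt <- (0:499) / fs
  mk <- function(shift) {
    one_trial_epochs(rbind(cos(2 * pi * 8 * tt + 0.3 + shift),
                           cos(2 * pi * 8 * tt + 1.1 + shift),
                           cos(2 * pi * 8 * tt - 0.7 + shift)), fs)
  }
  d0 <- plv_distance_matrix(mk(0), "per_trial")[[1]]
  d1 <- plv_distance_matrix(mk(0.9), "per_trial")[[1]]
  expect_equal(unclass(d0), unclass(d1), tolerance = 1e-6)
})

test_that("standardized Euclidean distance follows the per-coordinate rule", {
  X <- rbind(c(0, 0), c(1, 2), c(2, 4))   # v = (1, 2)
  es <- one_trial_epochs(X)
  dm <- std_euclidean_matrix(es, "per_trial")[[1]]
  expect_equal(dm[1, 2], sqrt(2))
  expect_equal(dm[1, 3], sqrt(4 + 4))
  expect_equal(diag(unclass(dm)), rep(0, 3))
  expect_equal(attr(dm, "coordinate_stds"), c(1, 2))

  # global rescaling cancels through the coordinate standard deviations
  dm2 <- std_euclidean_matrix(one_trial_epochs(2 * X), "per_trial")[[1]]
  expect_equal(unclass(dm2), unclass(dm), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a common offset changes neither differences nor coordinate SDs
  dm3 <- std_euclidean_matrix(one_trial_epochs(2 * X + 5), "per_trial")[[1]]
  expect_equal(unclass(dm3), unclass(dm), tolerance = 1e-12,
               ignore_attr = TRUE)

  # zero-variance coordinate is refused with the offending positions
  bad <- rbind(c(1, 0), c(1, 2), c(1, 4))
  expect_error(std_euclidean_matrix(one_trial_epochs(bad)),
               "position\\(s\\) 1")
  expect_error(std_euclidean_matrix(one_trial_epochs(X[1:2, , drop = FALSE])),
               "3 channels")
})

test_that("within-module dissimilarity decreases with coupling strength", {
  res <- vapply(c(1, 2, 4, 8), function(kappa) {
    spec <- coupling_spec(n_channels = 2, n_modules = 1,
                          within_module_concentration = c(a = kappa))
    cfg <- simulation_config(n_trials_per_condition = 1, sampling_rate = 250,
                             epoch_duration = 8, seed = 17)
    es <- generate_coupled_epochs(spec, cfg, "a", seed = 17,
                                  return_phases = TRUE)
    ph <- attr(es, "phases")
    1 - plv(ph[1, 1, ], ph[1, 2, ])
  }, numeric(1))
  expect_true(all(diff(res) < 0))
})
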