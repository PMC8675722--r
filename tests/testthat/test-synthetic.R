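test_that("expected PLV follows the squared Bessel ratio", {
  expect_identical(expected_plv(0), 0)
  expect_equal(expected_plv(Inf), 1)
  # independent oracle: Bessel ratio by direct quadrature of the von Mises
  # characteristic function
  ratio <- function(k) {
    num <- integrate(function(x) cos(x) * exp(k * cos(x)), -pi, pi)$value
    den <- integrate(function(x) exp(k * cos(x)), -pi, pi)$value
    num / den
  }
  expect_equal(expected_plv(2), ratio(2)^2, tolerance = 1e-8)
  expect_equal(ratio(2), 0.6978, tolerance = 1e-4)
  expect_equal(expected_plv(2), 0.4868, tolerance = 1e-3)
  expect_error(expected_plv(-1), "kappa")
})

test_that("generator rejects invalid physics", {
  expect_error(coupling_spec(within_module_concentration = c(a = -1)),
               ">= 0")
  spec <- coupling_spec(n_channels = 4, n_modules = 1,
                        within_module_concentration = c(a = 1),
                        band_carriers = data.frame(band = "x", freq = 200,
                                                   amplitude = 1))
  cfg <- simulation_config(sampling_rate = 250)
  expect_error(generate_coupled_epochs(spec, cfg, "a"), "Nyquist")
  expect_error(generate_coupled_epochs(coupling_spec(n_channels = 4),
                                       simulation_config(), "missing"),
               "unknown condition")
})

test_that("fixed seed reproduces epochs bit for bit", {
  spec <- coupling_spec(n_channels = 6, n_modules = 2,
                        within_module_concentration = c(a = 2, b = 4))
  cfg <- simulation_config(n_subjects = 2, n_trials_per_condition = 2,
                           epoch_duration = 0.5, seed = 42)
  e1 <- generate_coupled_epochs(spec, cfg, "a", seed = 7)
  e2 <- generate_coupled_epochs(spec, cfg, "a", seed = 7)
  expect_identical(e1$data, e2$data)
  s1 <- generate_study(spec, cfg)
  s2 <- generate_study(spec, cfg)
  expect_identical(s1$s01$a$data, s2$s01$a$data)
  expect_identical(s1$s02$b$data, s2$s02$b$data)
})

test_that("empirical within-module PLV matches the von Mises prediction", {
  mk <- function(kappa, dur, seed) {
    spec <- coupling_spec(n_channels = 2, n_modules = 1,
                          within_module_concentration = c(a = kappa))
    cfg <- simulation_config(n_trials_per_condition = 1, sampling_rate = 250,
                             epoch_duration = dur, seed = seed)
    es <- generate_coupled_epochs(spec, cfg, "a", seed = seed,
                                  return_phases = TRUE)
    ph <- attr(es, "phases")
    plv(ph[1, 1, ], ph[1, 2, ])
  }
  # near-infinite concentration: perfect locking
  expect_equal(mk(1e6, 4, 1), 1, tolerance = 1e-3)
  # kappa = 2, 1e4 samples: squared Bessel ratio 0.4868
  expect_equal(mk(2, 40, 2), expected_plv(2), tolerance = 0.02)
  # uncoupled modules (cross kappa = 0): PLV ~ 0 at N = 500
  spec <- coupling_spec(n_channels = 2, n_modules = 2,
                        within_module_concentration = c(a = 1e6),
                        cross_module_concentration = 0)
  cfg <- simulation_config(n_trials_per_condition = 1, sampling_rate = 250,
                           epoch_duration = 2, seed = 3)
  es <- generate_coupled_epochs(spec, cfg, "a", seed = 3, return_phases = TRUE)
  ph <- attr(es, "phases")
  expect_lt(plv(ph[1, 1, ], ph[1, 2, ]), 0.2)  # O(1/sqrt(500))
})

test_that("planted geometries carry their designed topology", {
  sq <- planted_geometry_distance_matrix("square", 4)
  expect_equal(sort(sq[upper.tri(sq)]),
               c(1, 1, 1, 1, sqrt(2), sqrt(2)), tolerance = 1e-12)

  circ <- planted_geometry_distance_matrix("circle", 20)
  bc <- brute_persistence(unclass(circ))
  h1 <- bc[bc$dimension == 1, ]
  expect_identical(nrow(h1), 1L)
  expect_gt(h1$death - h1$birth, 0)

  mod <- planted_geometry_distance_matrix("modular", 10, n_blocks = 2)
  g <- threshold_graph(mod, 0.5)  # between within (0.2) and between (1.0)
  comps <- igraph::count_components(
    igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected"))
  expect_equal(comps, 2)
  expect_error(planted_geometry_distance_matrix("pentagon", 5), "arg")
})

test_that("study generation is balanced bookkeeping", {
  spec <- coupling_spec(n_channels = 4, n_modules = 2,
                        within_module_concentration = c(x = 1, y = 1))
  cfg <- simulation_config(n_subjects = 2, n_trials_per_condition = 3,
                           epoch_duration = 0.2, seed = 9)
  st <- generate_study(spec, cfg)
  expect_length(st, 2)
  expect_named(st[[1]], c("x", "y"))
  expect_identical(dim(st$s02$y$data), c(3L, 4L, 50L))
  expect_identical(st$s01$x$condition, "x")
})
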