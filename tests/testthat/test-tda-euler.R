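unit_square <- function() planted_geometry_distance_matrix("square", 4)

test_that("threshold graphs follow the epsilon rule", {
  sq <- unit_square()
  expect_identical(sum(threshold_graph(sq, 0)$adjacency), 0L)
  expect_equal(sum(threshold_graph(sq, 2)$adjacency) / 2, 6)
  g <- threshold_graph(sq, 1.2)  # the 4-cycle: sides only, no diagonals
  expect_equal(sum(g$adjacency) / 2, 4)
  expect_error(threshold_graph(sq, -0.1), ">= 0")
})

test_that("clique counts match hand values and the closed forms", {
  tri <- matrix(TRUE, 3, 3); diag(tri) <- FALSE
  expect_equal(count_cliques(tri), c(Cl_0 = 3, Cl_1 = 3, Cl_2 = 1, Cl_3 = 0))
  expect_equal(euler_characteristic(count_cliques(tri)), 1)

  k5 <- matrix(TRUE, 5, 5); diag(k5) <- FALSE
  expect_equal(unname(count_cliques(k5)), c(5, 10, 10, 5))
  expect_equal(euler_characteristic(count_cliques(k5)), 0)

  cyc <- matrix(FALSE, 4, 4)
  cyc[cbind(c(1, 2, 3, 4), c(2, 3, 4, 1))] <- TRUE
  cyc <- cyc | t(cyc)
  expect_equal(unname(count_cliques(cyc)), c(4, 4, 0, 0))
  expect_equal(euler_characteristic(count_cliques(cyc)), 0)
})

test_that("clique counts agree exactly with subset enumeration", {
  for (seed in 1:20) {
    n <- sample(4:10, 1)
    A <- random_graph(n, 0.5, seed)
    expect_identical(unname(count_cliques(A, 3)),
                     unname(brute_cliques(A, 3)))
  }
})

test_that("complete-graph Euler characteristic matches binomials at K = 3", {
  for (n in 3:8) {
    A <- matrix(TRUE, n, n); diag(A) <- FALSE
    expect_equal(euler_characteristic(count_cliques(A, 3)),
                 choose(n, 1) - choose(n, 2) + choose(n, 3) - choose(n, 4))
  }
})

test_that("Euler entropy curve reproduces the analytic regimes", {
  # two channels at distance 0.5: chi = 2 then 1, S = ln 2 then 0
  d2 <- distance_matrix(matrix(c(0, 0.5, 0.5, 0), 2), "custom")
  cur <- euler_entropy_curve(d2, grid = seq(0, 1, by = 0.1))
  expect_equal(cur$mean_chi, ifelse(cur$epsilon < 0.5, 2, 1))
  expect_equal(cur$euler_entropy, ifelse(cur$epsilon < 0.5, log(2), 0))
  pt <- detect_phase_transition(cur)
  expect_equal(pt$epsilon_star, 0.5)

  # unit square: chi = 4, 0, 1 on [0,1), [1,sqrt(2)), [sqrt(2),inf)
  sq <- unit_square()
  grid <- c(0.5, 1, 1.2, sqrt(2), 1.5)
  cur2 <- euler_entropy_curve(sq, grid = grid)
  expect_equal(cur2$mean_chi, c(4, 0, 0, 1, 1))
  expect_equal(cur2$euler_entropy, c(log(4), -Inf, -Inf, 0, 0))

  # averaging two identical trials changes nothing
  cur3 <- euler_entropy_curve(list(sq, sq), grid = grid)
  expect_equal(cur3$mean_chi, cur2$mean_chi)

  expect_error(euler_entropy_curve(list(sq, d2)), "inconsistent")
})

test_that("phase transitions sit at the entropy singularity or argmin", {
  sq <- unit_square()
  cur <- euler_entropy_curve(sq, grid = seq(0, 1.5, length.out = 101))
  pt <- detect_phase_transition(cur)
  expect_identical(pt$kind, "zero_crossing")
  expect_lt(abs(pt$epsilon_star - 1.0), 1.5 / 100 + 1e-12)

  # strictly positive decreasing |chi|: smallest-index argmin wins
  cur2 <- data.frame(epsilon = c(0.1, 0.2, 0.3, 0.4),
                     mean_chi = c(8, 2, 2, 4))
  cur2$euler_entropy <- log(abs(cur2$mean_chi))
  expect_equal(detect_phase_transition(cur2)$epsilon_star, 0.2)
  expect_identical(detect_phase_transition(cur2)$kind, "grid_minimum")

  flat <- data.frame(epsilon = 1:3, mean_chi = c(2, 2, 2),
                     euler_entropy = log(c(2, 2, 2)))
  expect_warning(pt3 <- detect_phase_transition(flat), "constant")
  expect_true(pt3$degenerate)
})

test_that("Betti curves: components, holes, and the transition crossing", {
  sq <- unit_square()
  bc <- betti_curves(sq, grid = c(0.5, 1.1, 1.45))
  expect_equal(bc$betti0, c(4, 1, 1))
  expect_equal(bc$betti1, c(0, 1, 0))

  # the Euler transition lies within a grid step of the Betti crossing
  grid <- seq(0, 1.5, length.out = 101)
  pt <- detect_phase_transition(euler_entropy_curve(sq, grid = grid))
  b <- betti_curves(sq, grid = grid)
  crossing <- grid[which(b$betti1 >= b$betti0)[1]]
  expect_lte(abs(pt$epsilon_star - crossing), diff(grid)[1] + 1e-12)
})

test_that("clique counts grow and components shrink along the filtration", {
  M <- random_distance_matrix(12, 31)
  dm <- distance_matrix(M, "custom")
  grid <- seq(0, 1, length.out = 41)
  cur <- euler_entropy_curve(dm, grid = grid)
  for (k in 0:3) expect_true(all(diff(cur[[paste0("Cl_", k)]]) >= 0))
  b <- betti_curves(dm, grid = grid)
  expect_true(all(diff(b$betti0) <= 0))
  expect_equal(b$betti0[length(grid)], 1)
})

test_that("union-find components equal the count of live H0 bars", {
  for (seed in 1:10) {
    M <- random_distance_matrix(7, seed + 100)
    dm <- distance_matrix(M, "custom")
    bc <- rips_persistence(dm, max_dim = 0)
    h0 <- bc[bc$dimension == 0, ]
    for (eps in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      g <- igraph::graph_from_adjacency_matrix(
        threshold_graph(dm, eps)$adjacency, mode = "undirected")
      alive <- sum(h0$birth <= eps & (eps < h0$death | h0$infinite))
      expect_equal(igraph::count_components(g), alive)
    }
  }
})
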