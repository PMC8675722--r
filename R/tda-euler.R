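#' Threshold graph of a distance matrix
#'
#' Vertices are channels; an edge joins r and t iff `d(r, t) <= epsilon`
#' (equivalently, for PLV dissimilarity, iff the PLV is at least
#' `1 - epsilon`).
#'
#' @param matrix A [distance_matrix()] (or plain symmetric matrix).
#' @param epsilon Filtration scale, >= 0.
#' @return A `threshold_graph`: list with logical `adjacency` and the
#'   `epsilon` used.
#' @export
threshold_graph <- function(matrix, epsilon) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  M <- unclass(matrix)
  if (max(abs(M - t(M))) > 1e-8) stop("matrix must be symmetric")
  A <- M <= epsilon
  diag(A) <- FALSE
  structure(list(adjacency = A, epsilon = epsilon), class = "threshold_graph")
}

as_adjacency <- function(graph) {
  if (inherits(graph, "threshold_graph")) graph$adjacency
  else if (is.matrix(graph)) graph != 0 & row(graph) != col(graph)
  else stop("expected a threshold_graph or adjacency matrix")
}

#' Count cliques of each order in a graph
#'
#' `Cl_k` is the number of (k+1)-vertex cliques: nodes (k = 0), edges
#' (k = 1), triangles (k = 2), tetrahedra (k = 3). Counts are exact
#' (recursive enumeration with pruning, compiled).
#'
#' @param graph A [threshold_graph()] or logical adjacency matrix.
#' @param K Highest order to count (default 3).
#' @return Named integer vector `Cl_0` .. `Cl_K`.
#' @export
count_cliques <- function(graph, K = 3) {
  if (K < 0) stop("K must be >= 0")
  A <- as_adjacency(graph)
  counts <- count_cliques_cpp(A, as.integer(K))
  names(counts) <- paste0("Cl_", 0:K)
  counts
}

#' Euler characteristic from clique counts
#'
#' The alternating sum `sum_k (-1)^k Cl_k` over the counted orders
#' (truncated at the highest order counted).
#'
#' @param counts Vector of clique counts `Cl_0..Cl_K` from
#'   [count_cliques()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(counts) {
  sum((-1)^(seq_along(counts) - 1) * counts)
}

default_grid <- function(matrices, n_grid = 101) {
  m1 <- matrices[[1]]
  if (identical(attr(m1, "metric"), "plv_dissimilarity") ||
      identical(attr(m1, "normalization"), "unit_max")) {
    seq(0, 1, length.out = n_grid)
  } else {
    seq(0, max(vapply(matrices, max, numeric(1))), length.out = n_grid)
  }
}

#' Euler characteristic and Euler entropy along a filtration
#'
#' For each scale epsilon of the grid, builds the threshold graph of every
#' trial matrix, counts cliques up to order `K`, forms the per-trial Euler
#' characteristic and averages it over trials (`mean_chi`). The Euler
#' entropy is `S_chi = ln |mean_chi|`, with `-Inf` recorded where the
#' trial-averaged characteristic is exactly zero.
#'
#' @param matrices A [distance_matrix()] or list of them (one per trial,
#'   common channel set).
#' @param grid Increasing vector of epsilon values; default 101 points on
#'   `[0, 1]` for PLV dissimilarity, `[0, max distance]` otherwise.
#' @param K Highest simplex order (default 3).
#' @return A `filtration_curve`: data frame with columns `epsilon`,
#'   `Cl_0..Cl_K` (trial means), `mean_chi`, `euler_entropy`.
#' @export
euler_entropy_curve <- function(matrices, grid = NULL, K = 3) {
  if (inherits(matrices, "distance_matrix")) matrices <- list(matrices)
  ns <- vapply(matrices, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("trial matrices have inconsistent channel sets")
  if (is.null(grid)) grid <- default_grid(matrices)
  if (length(grid) < 1 || is.unsorted(grid)) stop("grid must be increasing")
  counts <- matrix(0, length(grid), K + 1)
  chi <- matrix(0, length(grid), length(matrices))
  for (tr in seq_along(matrices)) {
    M <- unclass(matrices[[tr]])
    for (g in seq_along(grid)) {
      cl <- count_cliques_cpp(M <= grid[g] & row(M) != col(M), as.integer(K))
      counts[g, ] <- counts[g, ] + cl
      chi[g, tr] <- sum((-1)^(0:K) * cl)
    }
  }
  mean_chi <- rowMeans(chi)
  out <- data.frame(epsilon = grid)
  cl_mean <- counts / length(matrices)
  colnames(cl_mean) <- paste0("Cl_", 0:K)
  out <- cbind(out, cl_mean)
  out$mean_chi <- mean_chi
  out$euler_entropy <- ifelse(mean_chi == 0, -Inf, log(abs(mean_chi)))
  structure(out, class = c("filtration_curve", "data.frame"),
            K = K, n_trials = length(matrices),
            metric = attr(matrices[[1]], "metric"),
            provenance = attr(matrices[[1]], "provenance"))
}

#' Betti curves (beta0, beta1) of a single distance matrix
#'
#' `beta0(epsilon)` is the number of connected components of the threshold
#' graph (via graph components); `beta1(epsilon)` is the number of
#' 1-dimensional holes of the clique complex, read from the Rips barcode
#' as the number of H1 intervals alive at epsilon (birth <= epsilon <
#' death; capped intervals count as alive from their birth onward).
#'
#' @param matrix A [distance_matrix()].
#' @param grid Epsilon grid (default as in [euler_entropy_curve()]).
#' @return Data frame with columns `epsilon`, `betti0`, `betti1`.
#' @export
betti_curves <- function(matrix, grid = NULL) {
  if (is.null(grid)) grid <- default_grid(list(matrix))
  M <- unclass(matrix)
  bc <- rips_persistence(matrix, max_dim = 1)
  h1 <- bc[bc$dimension == 1, , drop = FALSE]
  betti0 <- betti1 <- integer(length(grid))
  for (g in seq_along(grid)) {
    A <- M <= grid[g] & row(M) != col(M)
    gr <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    betti0[g] <- igraph::count_components(gr)
    betti1[g] <- sum(h1$birth <= grid[g] &
                       (grid[g] < h1$death | h1$infinite))
  }
  data.frame(epsilon = grid, betti0 = betti0, betti1 = betti1)
}

#' Locate the topological phase transition of an Euler-entropy curve
#'
#' The transition is the scale where the Euler entropy has its negative
#' peak: the smallest grid epsilon achieving the global minimum of
#' `S_chi = ln |mean_chi|`. A scale where the trial-averaged Euler
#' characteristic is exactly zero (an entropy singularity, `S = -Inf`)
#' dominates any finite minimum; `kind` records which case fired
#' (`"zero_crossing"` vs `"grid_minimum"`).
#'
#' @param curve A `filtration_curve` from [euler_entropy_curve()].
#' @return A `phase_transition` list: `epsilon_star`, `kind`,
#'   `degenerate` (TRUE when the curve is constant so the minimum is not
#'   distinct from the endpoints), and the provenance of the curve.
#' @export
detect_phase_transition <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("epsilon", "mean_chi",
                                        "euler_entropy") %in% names(curve)))
  if (nrow(curve) < 3) stop("need a grid of at least 3 points")
  degenerate <- FALSE
  zero <- which(curve$mean_chi == 0)
  if (length(zero)) {
    idx <- zero[1]
    kind <- "zero_crossing"
  } else {
    s <- curve$euler_entropy
    if (max(s) - min(s) < 1e-12) {
      degenerate <- TRUE
      warning("Euler entropy curve is constant; transition not distinct")
    }
    idx <- which(s == min(s))[1]
    kind <- "grid_minimum"
  }
  structure(list(epsilon_star = curve$epsilon[idx], kind = kind,
                 index = idx, degenerate = degenerate,
                 provenance = attr(curve, "provenance")),
            class = "phase_transition")
}

#' @export
print.phase_transition <- function(x, ...) {
  cat(sprintf("<phase_transition> epsilon* = %.4g (%s)\n",
              x$epsilon_star, x$kind))
  invisible(x)
}
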