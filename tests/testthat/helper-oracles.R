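# Independent brute-force oracles used to validate the compiled
# implementations. These deliberately use the slowest, most literal
# algorithms: subset enumeration for cliques, and a full boundary-matrix
# reduction (vertices, edges and triangles interleaved in filtration
# order) for persistence.

# Count cliques of sizes 1..K+1 by enumerating every vertex subset.
brute_cliques <- function(adj, K = 3) {
  n <- nrow(adj)
  counts <- numeric(K + 1)
  counts[1] <- n
  for (k in 1:K) {
    size <- k + 1
    if (size > n) break
    subsets <- utils::combn(n, size)
    is_clique <- apply(subsets, 2, function(v) {
      all(adj[v, v][upper.tri(diag(size))])
    })
    counts[k + 1] <- sum(is_clique)
  }
  names(counts) <- paste0("Cl_", 0:K)
  counts
}

# Full persistence of the Rips filtration (dims 0 and 1) by left-to-right
# reduction of the complete boundary matrix over Z2. Returns a data frame
# (dimension, birth, death, infinite) with zero-length bars dropped,
# sorted like rips_persistence() output.
brute_persistence <- function(D, max_filtration = max(D)) {
  n <- nrow(D)
  verts <- lapply(seq_len(n), function(v) list(v = v, val = 0, dim = 0L))
  edges <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] <= max_filtration) {
      edges[[length(edges) + 1]] <- list(v = c(i, j), val = D[i, j], dim = 1L)
    }
  }
  tris <- list()
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      w <- max(D[i, j], D[i, k], D[j, k])
      if (w <= max_filtration) {
        tris[[length(tris) + 1]] <- list(v = c(i, j, k), val = w, dim = 2L)
      }
    }
  }
  simp <- c(verts, edges, tris)
  vals <- vapply(simp, `[[`, numeric(1), "val")
  dims <- vapply(simp, `[[`, integer(1), "dim")
  lex <- vapply(simp, function(s) paste(sprintf("%04d", s$v), collapse = ""),
                character(1))
  ord <- order(vals, dims, lex)
  simp <- simp[ord]
  vals <- vals[ord]; dims <- dims[ord]
  key <- vapply(simp, function(s) paste(s$v, collapse = "-"), character(1))
  index <- stats::setNames(seq_along(simp), key)

  m <- length(simp)
  reduced <- vector("list", m)
  pivot <- rep(NA_integer_, m)
  bars <- list()
  for (ci in seq_len(m)) {
    s <- simp[[ci]]
    col <- if (s$dim == 0L) integer(0) else {
      faces <- utils::combn(s$v, s$dim)
      sort(unname(index[apply(faces, 2, paste, collapse = "-")]))
    }
    repeat {
      if (!length(col)) break
      low <- max(col)
      other <- pivot[low]
      if (is.na(other)) break
      oc <- reduced[[other]]
      col <- sort(c(setdiff(col, oc), setdiff(oc, col)))
    }
    reduced[[ci]] <- col
    if (length(col)) {
      low <- max(col)
      pivot[low] <- ci
      bars[[length(bars) + 1]] <-
        c(dim = dims[low], birth = vals[low], death = vals[ci], inf = 0)
    }
  }
  # unpaired positive simplices of dim 0/1 persist to the cap
  killed <- which(!is.na(pivot))
  is_negative <- vapply(seq_len(m), function(ci) length(reduced[[ci]]) > 0,
                        logical(1))
  for (ci in seq_len(m)) {
    if (dims[ci] <= 1L && !is_negative[ci] && !(ci %in% killed)) {
      bars[[length(bars) + 1]] <-
        c(dim = dims[ci], birth = vals[ci], death = max_filtration, inf = 1)
    }
  }
  bc <- as.data.frame(do.call(rbind, bars))
  names(bc) <- c("dimension", "birth", "death", "infinite")
  bc <- bc[bc$death > bc$birth, , drop = FALSE]
  bc <- bc[order(bc$dimension, bc$birth, bc$death), , drop = FALSE]
  rownames(bc) <- NULL
  bc$dimension <- as.integer(bc$dimension)
  bc$infinite <- bc$infinite > 0
  bc
}

# Random symmetric distance matrix with zero diagonal, entries in (0, 1).
random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  M <- matrix(runif(n * n, 0.05, 1), n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

# Seeded Erdos-Renyi adjacency matrix.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n) < p, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  A | t(A)
}

# Small helper: epoch_set holding given channels x samples matrix as one trial.
one_trial_epochs <- function(X, fs = 250, band = "broadband") {
  epoch_set(array(X, dim = c(1, nrow(X), ncol(X))), fs, band = band)
}

barcode_from <- function(dimension, birth, death) {
  structure(data.frame(dimension = dimension, birth = birth, death = death,
                       infinite = FALSE),
            class = c("barcode", "data.frame"),
            max_filtration = max(death))
}
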