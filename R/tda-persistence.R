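#' Vietoris-Rips persistence barcode (dimensions 0 and 1)
#'
#' Computes the persistence of the Rips (clique) filtration of a distance
#' matrix by boundary-matrix reduction over the two-element field,
#' implemented in compiled code: H0 via union-find along the sorted edges
#' (elder rule), H1 by reducing triangle columns against edge rows.
#' Features alive at the end of the filtration are reported with their
#' death capped at `max_filtration` and flagged in column `infinite`, so
#' the (otherwise infinite) last connected component contributes a bar to
#' entropy summaries. Zero-persistence pairs (birth equal to death, the
#' bulk of a Rips reduction) are dropped.
#'
#' @param matrix A [distance_matrix()] or plain symmetric matrix with zero
#'   diagonal.
#' @param max_dim Highest homology dimension, 0 or 1.
#' @param max_filtration Cap for the filtration (default: the largest
#'   matrix entry, so the complex ends complete).
#' @return A `barcode`: data frame with columns `dimension`, `birth`,
#'   `death`, `infinite`, sorted by dimension then birth, with attribute
#'   `max_filtration`.
#' @export
rips_persistence <- function(matrix, max_dim = 1, max_filtration = NULL) {
  M <- unclass(matrix)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8) {
    stop("matrix must be square and symmetric")
  }
  if (any(abs(diag(M)) > 1e-12)) stop("matrix must have zero diagonal")
  if (!max_dim %in% c(0, 1)) {
    stop("only dimensions 0 and 1 are supported (max_dim must be 0 or 1)")
  }
  if (is.null(max_filtration)) max_filtration <- max(M)
  res <- rips_persistence_cpp(M, as.numeric(max_filtration),
                              as.integer(max_dim))
  bc <- data.frame(dimension = as.integer(res[, 1]), birth = res[, 2],
                   death = res[, 3], infinite = res[, 4] > 0)
  bc <- bc[bc$death > bc$birth, , drop = FALSE]
  bc <- bc[order(bc$dimension, bc$birth, bc$death), , drop = FALSE]
  rownames(bc) <- NULL
  structure(bc, class = c("barcode", "data.frame"),
            max_filtration = max_filtration,
            provenance = attr(matrix, "provenance"))
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("<barcode> %d interval(s): %s; max_filtration = %.4g\n",
              nrow(x),
              paste(sprintf("H%d x %d", sort(unique(x$dimension)),
                            table(x$dimension)), collapse = ", "),
              attr(x, "max_filtration")))
  NextMethod()
}

bar_lengths <- function(barcode, dimensions) {
  sel <- barcode$dimension %in% dimensions
  len <- barcode$death[sel] - barcode$birth[sel]
  len[len > 0]
}

#' Persistent entropy of a barcode
#'
#' Shannon entropy (natural log) of the bar-length distribution:
#' `H = -sum_i p_i ln p_i` with `p_i = (y_i - x_i) / L` and
#' `L = sum_i (y_i - x_i)`. Zero-length intervals are dropped before
#' normalization.
#'
#' @param barcode A `barcode` from [rips_persistence()].
#' @param dimensions Homology dimensions to pool (default both 0 and 1).
#' @return An `entropy_result` list: `H` (nats), `H_hat` (`NA` here; see
#'   [normalized_persistent_entropy()]), `L`, `ell_max`, `n_bars`,
#'   `dimensions_used`.
#' @export
persistent_entropy <- function(barcode, dimensions = c(0, 1)) {
  len <- bar_lengths(barcode, dimensions)
  if (!length(len)) stop("no positive-length intervals in the selected dimensions")
  L <- sum(len)
  p <- len / L
  structure(list(H = -sum(p * log(p)), H_hat = NA_real_, L = L,
                 ell_max = max(len), n_bars = length(len),
                 dimensions_used = dimensions),
            class = "entropy_result")
}

#' Rescaled (normalized) persistent entropy
#'
#' `H_hat = H / ln(ell_max)` where `ell_max` is the longest bar among the
#' selected dimensions. The rescaling is only well defined when
#' `ell_max > 1` in the metric's native units (`ln(ell_max) > 0`), which
#' is why standardized-Euclidean matrices are not rescaled to `[0, 1]` by
#' default; the function refuses otherwise.
#'
#' @inheritParams persistent_entropy
#' @return An `entropy_result` with `H_hat` filled in.
#' @export
normalized_persistent_entropy <- function(barcode, dimensions = c(0, 1)) {
  res <- persistent_entropy(barcode, dimensions)
  if (res$ell_max <= 1) {
    stop("ell_max = ", format(res$ell_max), " <= 1: ln(ell_max) <= 0 makes ",
         "the rescaled entropy ill-defined; use unnormalized distances")
  }
  res$H_hat <- res$H / log(res$ell_max)
  res
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> H = %.4f nats over %d bar(s) (dims %s); L = %.4g, ell_max = %.4g%s\n",
              x$H, x$n_bars, paste(x$dimensions_used, collapse = ","),
              x$L, x$ell_max,
              if (is.na(x$H_hat)) "" else sprintf(", H_hat = %.4f", x$H_hat)))
  invisible(x)
}
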