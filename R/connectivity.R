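#' Symmetric channel-by-channel distance matrix
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param metric One of `"plv_dissimilarity"`, `"std_euclidean"`,
#'   `"euclidean"` (planted geometries) or `"custom"`.
#' @param coordinate_stds Per-coordinate standard deviations used by the
#'   standardized Euclidean metric (recorded for provenance).
#' @param normalization `"none"` or `"unit_max"`.
#' @param provenance Optional list (band, condition, subject, trial, ...).
#' @return An object of class `distance_matrix` (a numeric matrix with
#'   attributes).
#' @export
distance_matrix <- function(values, metric = "custom", coordinate_stds = NULL,
                            normalization = "none", provenance = list()) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (metric == "plv_dissimilarity" &&
      (min(values) < -1e-9 || max(values) > 1 + 1e-9)) {
    stop("plv_dissimilarity entries must lie in [0, 1]")
  }
  if (any(values < 0)) stop("distances must be >= 0")
  structure(values, class = c("distance_matrix", "matrix", "array"),
            metric = metric, coordinate_stds = coordinate_stds,
            normalization = normalization, provenance = provenance)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d x %d, metric=%s, max=%.4g\n",
              nrow(x), ncol(x), attr(x, "metric"), max(x)))
  invisible(x)
}

# analytic signal via the one-sided spectrum: the imaginary part is the
# quadrature (Hilbert) component
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of every channel via the analytic signal
#'
#' Builds the analytic signal of each (band-limited) trial/channel series
#' from its one-sided spectrum and takes the argument. Intended for
#' narrowband input (use [bandpass_filter()] first).
#'
#' @param epochs An [epoch_set()].
#' @return A `phase_epochs` object: array trials x channels x samples of
#'   phases in `(-pi, pi]`, plus sampling rate and band.
#' @export
instantaneous_phase <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  ph <- array(0, dim = d)
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- epochs$data[tr, ch, ]
      if (sd(x) == 0) {
        stop("channel ", epochs$channel_labels[ch],
             " has zero variance; phase undefined")
      }
      ph[tr, ch, ] <- Arg(analytic_signal(x))
    }
  }
  structure(list(phases = ph, sampling_rate = epochs$sampling_rate,
                 band = epochs$band, condition = epochs$condition,
                 subject_id = epochs$subject_id),
            class = "phase_epochs")
}

#' Phase-locking value of two phase series
#'
#' The modulus of the mean unit phasor of the phase difference:
#' `|1/N sum_n exp(i (phi_r(n) - phi_t(n)))|`. 1 means perfect locking,
#' values near 0 mean independent phases.
#'
#' @param phase_r,phase_t Numeric phase vectors (radians) of equal length.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(phase_r, phase_t) {
  if (length(phase_r) != length(phase_t)) stop("phase series length mismatch")
  if (!length(phase_r)) stop("empty phase series")
  Mod(mean(exp(1i * (phase_r - phase_t))))
}

# PLV matrix of one channels x samples phase matrix via complex outer product
plv_matrix_of <- function(ph) {
  Z <- exp(1i * ph)
  P <- Mod(Z %*% Conj(t(Z))) / ncol(ph)
  P <- pmin(P, 1)
  diag(P) <- 1
  P
}

#' PLV dissimilarity matrices of an epoch set
#'
#' Computes instantaneous phases, then for each trial the channel x channel
#' PLV matrix, stored as the dissimilarity `1 - PLV` so that the Rips edge
#' rule at scale `epsilon` admits a pair iff its PLV is at least
#' `1 - epsilon`. The raw PLV matrix is retrievable from attribute
#' `"similarity"`.
#'
#' @param epochs An [epoch_set()] (narrowband input recommended).
#' @param trial_aggregation `"per_trial"` (a list with one
#'   [distance_matrix()] per trial) or `"mean_over_trials"` (PLV averaged
#'   across trials, then one dissimilarity matrix).
#' @return A list of [distance_matrix()] or a single one, per
#'   `trial_aggregation`.
#' @export
plv_distance_matrix <- function(epochs,
                                trial_aggregation = c("per_trial",
                                                      "mean_over_trials")) {
  trial_aggregation <- match.arg(trial_aggregation)
  if (n_channels_of(epochs) < 2) stop("need at least 2 channels")
  pe <- instantaneous_phase(epochs)
  mats <- lapply(seq_len(dim(pe$phases)[1]), function(tr) {
    plv_matrix_of(pe$phases[tr, , ])
  })
  wrap <- function(P, trial) {
    D <- 1 - P
    diag(D) <- 0
    dm <- distance_matrix(D, metric = "plv_dissimilarity",
                          provenance = list(band = epochs$band,
                                            condition = epochs$condition[1],
                                            subject = epochs$subject_id,
                                            trial = trial,
                                            aggregation = trial_aggregation))
    attr(dm, "similarity") <- P
    dm
  }
  if (trial_aggregation == "per_trial") {
    lapply(seq_along(mats), function(i) wrap(mats[[i]], i))
  } else {
    wrap(Reduce(`+`, mats) / length(mats), NA_integer_)
  }
}

#' Standardized Euclidean distance matrices of an epoch set
#'
#' Each channel is a point whose coordinates are its N sample values; at
#' every sample position k the coordinate is divided by `v_k`, the sample
#' standard deviation (denominator n-1) across all channels at position k,
#' before Euclidean distances are taken:
#' `d(r,t) = sqrt(sum_k ((r_k - t_k) / v_k)^2)`.
#'
#' @param epochs An [epoch_set()] with at least 3 channels.
#' @param trial_aggregation `"per_trial"` or `"mean_over_trials"`
#'   (element-wise mean of the per-trial matrices).
#' @param normalization `"none"` (default; keeps distances in native units
#'   so the rescaled persistent entropy is well defined) or `"unit_max"`.
#' @return A list of [distance_matrix()] or a single one.
#' @export
std_euclidean_matrix <- function(epochs,
                                 trial_aggregation = c("per_trial",
                                                       "mean_over_trials"),
                                 normalization = c("none", "unit_max")) {
  trial_aggregation <- match.arg(trial_aggregation)
  normalization <- match.arg(normalization)
  if (n_channels_of(epochs) < 3) {
    stop("need at least 3 channels for per-coordinate standard deviations")
  }
  one <- function(tr) {
    X <- epochs$data[tr, , ]                      # channels x samples
    v <- apply(X, 2, sd)                          # across channels, n-1
    bad <- which(v == 0)
    if (length(bad)) {
      stop("zero variance across channels at sample position(s) ",
           paste(head(bad, 10), collapse = ", "))
    }
    D <- as.matrix(stats::dist(sweep(X, 2, v, "/")))
    dimnames(D) <- NULL
    if (normalization == "unit_max" && max(D) > 0) D <- D / max(D)
    distance_matrix(D, metric = "std_euclidean", coordinate_stds = v,
                    normalization = normalization,
                    provenance = list(band = epochs$band,
                                      condition = epochs$condition[1],
                                      subject = epochs$subject_id,
                                      trial = tr,
                                      aggregation = trial_aggregation))
  }
  mats <- lapply(seq_len(n_trials(epochs)), one)
  if (trial_aggregation == "per_trial") {
    mats
  } else {
    M <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
    distance_matrix(M, metric = "std_euclidean",
                    normalization = normalization,
                    provenance = list(band = epochs$band,
                                      condition = epochs$condition[1],
                                      subject = epochs$subject_id,
                                      aggregation = "mean_over_trials"))
  }
}
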