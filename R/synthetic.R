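#' Specify the planted coupling structure of a synthetic EEG study
#'
#' A coupling specification describes how channels are grouped into modules
#' and how strongly channel phases lock to their module's common phase under
#' each experimental condition. Phase locking is controlled by von Mises
#' concentration parameters: each channel's phase offset from its module
#' phase is drawn i.i.d. per sample from a von Mises distribution with
#' concentration `kappa`, so two channels of the same module have expected
#' phase-locking value [expected_plv()] `(I1(kappa)/I0(kappa))^2`.
#'
#' @param n_channels Number of channels (electrodes). Default 64, the size
#'   of a standard adult high-density cap.
#' @param n_modules Number of coupling modules; channels are assigned in
#'   contiguous blocks unless `module_assignment` is given.
#' @param module_assignment Optional integer vector of length `n_channels`
#'   giving each channel's module.
#' @param within_module_concentration Named numeric vector of von Mises
#'   concentrations (kappa >= 0), one per condition. The names define the
#'   condition labels of the study.
#' @param cross_module_concentration Single kappa >= 0 controlling phase
#'   locking between modules (0 = independent module phases).
#' @param band_carriers Data frame with columns `band`, `freq` (Hz) and
#'   `amplitude`: one sinusoidal carrier per frequency band.
#' @param phase_walk_sd Standard deviation (radians/sample) of the Gaussian
#'   random-walk increment of each module's common phase.
#'
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(n_channels = 64,
                          n_modules = 4,
                          module_assignment = NULL,
                          within_module_concentration = c(clear = 2, unclear = 4),
                          cross_module_concentration = 0,
                          band_carriers = data.frame(
                            band = c("delta", "theta", "alpha", "beta"),
                            freq = c(2, 6, 10, 22),
                            amplitude = 1
                          ),
                          phase_walk_sd = 0.05) {
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (is.null(module_assignment)) {
    module_assignment <- sort(rep_len(seq_len(n_modules), n_channels))
  }
  if (length(module_assignment) != n_channels) {
    stop("module_assignment must have one entry per channel")
  }
  kw <- within_module_concentration
  if (is.null(names(kw)) || any(!nzchar(names(kw)))) {
    stop("within_module_concentration must be a named vector (one kappa per condition)")
  }
  if (any(!is.finite(kw)) || any(kw < 0)) {
    stop("within-module concentrations must be finite and >= 0")
  }
  if (!is.finite(cross_module_concentration) || cross_module_concentration < 0) {
    stop("cross_module_concentration must be finite and >= 0")
  }
  stopifnot(is.data.frame(band_carriers),
            all(c("band", "freq", "amplitude") %in% names(band_carriers)))
  structure(
    list(
      n_channels = as.integer(n_channels),
      module_assignment = as.integer(module_assignment),
      within_module_concentration = kw,
      cross_module_concentration = cross_module_concentration,
      band_carriers = band_carriers,
      phase_walk_sd = phase_walk_sd
    ),
    class = "coupling_spec"
  )
}

#' Configure the size and noise level of a synthetic study
#'
#' Defaults mirror a typical image-quality EEG session: 20 subjects, 40
#' trials per condition, 250 Hz sampling, 2-s post-stimulus epochs.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_condition Trials per condition per subject.
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_duration Epoch length in seconds.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise, in
#'   the same units as the unit-amplitude carriers.
#' @param seed Master integer seed; the same seed reproduces the study
#'   bit-for-bit.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 20,
                              n_trials_per_condition = 40,
                              sampling_rate = 250,
                              epoch_duration = 2,
                              noise_sd = 0.5,
                              seed = 1L) {
  if (epoch_duration <= 0) stop("epoch_duration must be > 0")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_trials_per_condition = as.integer(n_trials_per_condition),
      sampling_rate = sampling_rate,
      epoch_duration = epoch_duration,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Expected phase-locking value between two jittered channels
#'
#' Two channels share a common (module) phase and each adds independent
#' von Mises jitter with concentration `kappa`, redrawn every sample. The
#' phase difference is then the difference of two independent von Mises
#' variates and the population PLV is the squared ratio of modified Bessel
#' functions `(I1(kappa)/I0(kappa))^2`.
#'
#' @param kappa Von Mises concentration(s), >= 0. `Inf` is allowed and
#'   returns 1.
#' @return Expected PLV in `[0, 1]`, vectorised over `kappa`.
#' @export
expected_plv <- function(kappa) {
  if (any(is.na(kappa)) || any(kappa < 0)) stop("kappa must be >= 0")
  out <- numeric(length(kappa))
  inf <- is.infinite(kappa)
  out[inf] <- 1
  k <- kappa[!inf]
  if (length(k)) {
    # exponentially scaled Bessel ratio is stable for large kappa
    out[!inf] <- (besselI(k, 1, expon.scaled = TRUE) /
                    besselI(k, 0, expon.scaled = TRUE))^2
  }
  out
}

# Von Mises sampler, mean 0, vectorised (Best & Fisher 1979 rejection
# scheme). kappa = 0 falls back to the uniform distribution on (-pi, pi].
rvonmises <- function(n, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(runif(n, -pi, pi))
  if (kappa > 5e5) return(rnorm(n, 0, sqrt(1 / kappa)))  # wrapped-normal limit
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    out[need[ok]] <- theta[ok]
    need <- need[!ok]
  }
  out
}

#' Generate phase-coupled multichannel epochs for one subject/condition
#'
#' Each channel's signal is a sum of band-limited carriers
#' `amplitude * cos(2*pi*f*t + psi_m(t) + theta_c(t))` plus Gaussian noise,
#' where `psi_m` is the module's common phase (a Gaussian random walk, with
#' optional cross-module von Mises locking to a global walk) and `theta_c`
#' is the channel's von Mises phase jitter, drawn independently every
#' sample with the condition's within-module concentration. The same
#' channel phase-offset process modulates every carrier.
#'
#' @param spec A [coupling_spec()].
#' @param config A [simulation_config()].
#' @param condition Condition label; must name an entry of
#'   `spec$within_module_concentration`.
#' @param n_trials Number of trials (defaults to the config value).
#' @param subject_id Subject label stored on the result.
#' @param seed Optional integer seed applied before generation.
#' @param return_phases If `TRUE`, attach the model phase array
#'   (`psi_m + theta_c`, carrier excluded) as attribute `"phases"` for
#'   validation against [expected_plv()].
#'
#' @return An [epoch_set()] with dimensions trials x channels x samples.
#' @export
generate_coupled_epochs <- function(spec, config, condition,
                                    n_trials = config$n_trials_per_condition,
                                    subject_id = "s01",
                                    seed = NULL,
                                    return_phases = FALSE) {
  stopifnot(inherits(spec, "coupling_spec"), inherits(config, "simulation_config"))
  if (!condition %in% names(spec$within_module_concentration)) {
    stop("unknown condition '", condition, "'")
  }
  fs <- config$sampling_rate
  if (any(spec$band_carriers$freq >= fs / 2)) {
    stop("carrier frequency at or above Nyquist (", fs / 2, " Hz)")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  kw <- spec$within_module_concentration[[condition]]
  kx <- spec$cross_module_concentration
  n_ch <- spec$n_channels
  n_s <- round(fs * config$epoch_duration)
  mods <- spec$module_assignment
  n_mod <- max(mods)
  tt <- (seq_len(n_s) - 1) / fs
  carriers <- spec$band_carriers

  data <- array(0, dim = c(n_trials, n_ch, n_s))
  phases <- if (return_phases) array(0, dim = c(n_trials, n_ch, n_s)) else NULL
  for (tr in seq_len(n_trials)) {
    # global walk + per-module lock to it
    g <- cumsum(rnorm(n_s, 0, spec$phase_walk_sd)) + runif(1, -pi, pi)
    psi <- matrix(0, n_mod, n_s)
    for (m in seq_len(n_mod)) {
      psi[m, ] <- g + rvonmises(n_s, kx)
    }
    theta <- matrix(rvonmises(n_ch * n_s, kw), n_ch, n_s)
    ph <- psi[mods, , drop = FALSE] + theta          # channels x samples
    sig <- matrix(0, n_ch, n_s)
    for (b in seq_len(nrow(carriers))) {
      carrier <- 2 * pi * carriers$freq[b] * tt
      sig <- sig + carriers$amplitude[b] *
        cos(sweep(ph, 2, carrier, "+"))
    }
    sig <- sig + matrix(rnorm(n_ch * n_s, 0, config$noise_sd), n_ch, n_s)
    data[tr, , ] <- sig
    if (return_phases) phases[tr, , ] <- ph
  }
  es <- epoch_set(data, sampling_rate = fs, band = "broadband",
                  condition = condition, subject_id = subject_id)
  if (return_phases) attr(es, "phases") <- phases
  es
}

#' Distance matrices with planted topology
#'
#' Unit-test geometries with known Betti structure: `"circle"` (n points
#' evenly spaced on the unit circle, one 1-dimensional hole at zero noise),
#' `"square"` (n points evenly spaced on the unit-square perimeter; for
#' n = 4 the corner fixture with pairwise distances 1,1,1,1,sqrt(2),sqrt(2)),
#' and `"modular"` (block structure: small within-block, large
#' between-block distances, beta0 = number of blocks at intermediate
#' scales).
#'
#' @param kind One of `"circle"`, `"modular"`, `"square"`.
#' @param n_points Number of points (>= 3 for circle, >= 4 for square).
#' @param noise_sd Gaussian noise on point coordinates (circle/square) or
#'   on distances (modular).
#' @param seed Optional integer seed.
#' @param n_blocks Number of blocks for `kind = "modular"`.
#' @param within,between Within/between-block base distances for
#'   `kind = "modular"`.
#' @return A [distance_matrix()].
#' @export
planted_geometry_distance_matrix <- function(kind, n_points, noise_sd = 0,
                                             seed = NULL, n_blocks = 2,
                                             within = 0.2, between = 1) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  kind <- match.arg(kind, c("circle", "modular", "square"))
  if (kind == "circle") {
    if (n_points < 3) stop("circle needs n_points >= 3")
    ang <- 2 * pi * (seq_len(n_points) - 1) / n_points
    xy <- cbind(cos(ang), sin(ang))
    if (noise_sd > 0) xy <- xy + matrix(rnorm(2 * n_points, 0, noise_sd), ncol = 2)
    D <- as.matrix(stats::dist(xy))
  } else if (kind == "square") {
    if (n_points < 4) stop("square needs n_points >= 4")
    # points evenly spaced along the unit-square perimeter, corner start
    s <- 4 * (seq_len(n_points) - 1) / n_points
    xy <- t(vapply(s, function(p) {
      if (p < 1) c(p, 0)
      else if (p < 2) c(1, p - 1)
      else if (p < 3) c(3 - p, 1)
      else c(0, 4 - p)
    }, numeric(2)))
    if (noise_sd > 0) xy <- xy + matrix(rnorm(2 * n_points, 0, noise_sd), ncol = 2)
    D <- as.matrix(stats::dist(xy))
  } else {
    blocks <- sort(rep_len(seq_len(n_blocks), n_points))
    D <- matrix(between, n_points, n_points)
    same <- outer(blocks, blocks, "==")
    D[same] <- within
    if (noise_sd > 0) {
      pert <- matrix(rnorm(n_points^2, 0, noise_sd), n_points)
      pert <- (pert + t(pert)) / 2
      D <- pmax(D + pert, 0)
    }
    diag(D) <- 0
  }
  dimnames(D) <- NULL
  distance_matrix(D, metric = "euclidean",
                  provenance = list(kind = kind, n_points = n_points,
                                    noise_sd = noise_sd))
}

# deterministic per-(subject, condition) seed below 2^31
derive_seed <- function(master, subject_idx, condition_idx) {
  as.integer((as.double(master) %% 2147483647 +
                1000003 * subject_idx + 7919 * condition_idx) %% 2147483647)
}

#' Generate a full synthetic study (subjects x conditions)
#'
#' Epochs for every subject and condition, with per-subject/condition seeds
#' derived deterministically from the master seed so studies are
#' reproducible and subjects mutually independent.
#'
#' @inheritParams generate_coupled_epochs
#' @return A list of class `eeg_study`: one element per subject, each a
#'   named list of [epoch_set()]s, one per condition.
#' @export
generate_study <- function(spec, config) {
  stopifnot(inherits(spec, "coupling_spec"), inherits(config, "simulation_config"))
  conditions <- names(spec$within_module_concentration)
  study <- vector("list", config$n_subjects)
  names(study) <- sprintf("s%02d", seq_len(config$n_subjects))
  for (s in seq_len(config$n_subjects)) {
    study[[s]] <- stats::setNames(lapply(seq_along(conditions), function(ci) {
      generate_coupled_epochs(
        spec, config, conditions[ci],
        subject_id = names(study)[s],
        seed = derive_seed(config$seed, s, ci)
      )
    }), conditions)
  }
  structure(study, class = "eeg_study", conditions = conditions,
            master_seed = config$seed)
}
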