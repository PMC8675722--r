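#' Multichannel EEG recording
#'
#' Container for a continuous recording: a channels x time matrix with its
#' sampling rate, channel labels and stimulus events.
#'
#' @param samples Numeric matrix, channels x time (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Optional character vector of channel names.
#' @param events Data frame with columns `onset_sample` (1-based sample
#'   index) and `condition` (label); may have zero rows.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels = NULL,
                          events = data.frame(onset_sample = integer(),
                                              condition = character())) {
  samples <- as.matrix(samples)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(samples)))
  }
  stopifnot(length(channel_labels) == nrow(samples),
            all(c("onset_sample", "condition") %in% names(events)))
  if (nrow(events) && (any(events$onset_sample < 1) ||
                       any(events$onset_sample > ncol(samples)))) {
    stop("event onsets must lie within the recording")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_labels = channel_labels, events = events),
            class = "eeg_recording")
}

#' Set of equal-length epochs
#'
#' @param data Numeric array, trials x channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Frequency-band label (`"broadband"` or a band name).
#' @param condition Condition label, either one label for all trials or a
#'   vector with one label per trial.
#' @param subject_id Subject label.
#' @param channel_labels Optional channel names.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sampling_rate, band = "broadband",
                      condition = "none", subject_id = "s01",
                      channel_labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!length(condition) %in% c(1L, dim(data)[1])) {
    stop("condition must have length 1 or n_trials")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(dim(data)[2]))
  }
  structure(list(data = data, sampling_rate = sampling_rate, band = band,
                 condition = condition, subject_id = subject_id,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trial(s) x %d channel(s) x %d sample(s) @ %g Hz, band=%s, condition=%s, subject=%s\n",
              d[1], d[2], d[3], x$sampling_rate, x$band,
              paste(unique(x$condition), collapse = "/"), x$subject_id))
  invisible(x)
}

n_trials <- function(es) dim(es$data)[1]
n_channels_of <- function(es) dim(es$data)[2]
n_samples_of <- function(es) dim(es$data)[3]

#' Canonical EEG frequency bands
#'
#' The four classical bands used throughout: delta 1-3 Hz, theta 4-7 Hz,
#' alpha 8-13 Hz, beta 14-30 Hz.
#'
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             low = c(1, 4, 8, 14),
             high = c(3, 7, 13, 30))
}

#' Define a frequency band
#' @param name Band label.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, low, high) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

# zero-phase filtering with reflection padding to tame edge transients
filtfilt_padded <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 250L)
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    y <- signal::filtfilt(filt, c(left, x, right))
    y[seq(pad + 1, pad + n)]
  } else {
    signal::filtfilt(filt, x)
  }
}

#' Downsample a recording by an integer factor
#'
#' Applies an anti-alias low-pass (8th-order Butterworth at 0.4 x target
#' rate, zero-phase) and keeps every q-th sample, where
#' `q = sampling_rate / target_rate` must be an integer. Event onsets are
#' rescaled. `target_rate == sampling_rate` is the identity (no filter).
#'
#' @param recording An [eeg_recording()].
#' @param target_rate Target sampling rate in Hz.
#' @return A downsampled [eeg_recording()].
#' @export
downsample <- function(recording, target_rate) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  if (target_rate > fs) stop("target_rate exceeds the sampling rate")
  if (target_rate == fs) return(recording)
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9) {
    stop("only integer decimation is supported (sampling_rate / target_rate = ",
         format(q), ")")
  }
  q <- as.integer(round(q))
  aa <- signal::butter(8, (0.4 * target_rate) / (fs / 2), type = "low")
  filtered <- t(apply(recording$samples, 1, function(x) filtfilt_padded(aa, x)))
  keep <- seq(1, ncol(filtered), by = q)
  ev <- recording$events
  if (nrow(ev)) {
    ev$onset_sample <- as.integer(floor((ev$onset_sample - 1) / q) + 1L)
  }
  eeg_recording(filtered[, keep, drop = FALSE], target_rate,
                recording$channel_labels, ev)
}

#' Cut stimulus-locked epochs out of a recording
#'
#' One trial per event, spanning `[window_start, window_end)` seconds
#' relative to the event onset (default the 2 s after stimulus onset).
#' Events whose window extends past the end of the recording are dropped
#' with a warning. Sample values are copied unchanged.
#'
#' @param recording An [eeg_recording()] with events.
#' @param window_start,window_end Window in seconds relative to onset.
#' @param subject_id Subject label to store.
#' @return An [epoch_set()]; zero events give an empty (0-trial) set.
#' @export
extract_epochs <- function(recording, window_start = 0, window_end = 2,
                           subject_id = "s01") {
  stopifnot(inherits(recording, "eeg_recording"), window_end > window_start)
  fs <- recording$sampling_rate
  len <- round((window_end - window_start) * fs)
  ev <- recording$events
  n_time <- ncol(recording$samples)
  starts <- ev$onset_sample + round(window_start * fs)
  ok <- starts >= 1 & (starts + len - 1) <= n_time
  if (any(!ok)) {
    warning(sum(!ok), " event(s) dropped: epoch window outside the recording")
  }
  starts <- starts[ok]
  conds <- ev$condition[ok]
  data <- array(0, dim = c(length(starts), nrow(recording$samples), len))
  for (i in seq_along(starts)) {
    data[i, , ] <- recording$samples[, seq(starts[i], length.out = len)]
  }
  epoch_set(data, fs, band = "broadband",
            condition = if (length(conds)) conds else "none",
            subject_id = subject_id,
            channel_labels = recording$channel_labels)
}

#' Band-pass filter an epoch set
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass per pass,
#' applied with reflection padding to each trial and channel. The band
#' label is stored on the result.
#'
#' @param epochs An [epoch_set()].
#' @param band A [band_definition()], or a band name from [eeg_bands()].
#' @param order Butterworth order per pass.
#' @return The filtered [epoch_set()].
#' @export
bandpass_filter <- function(epochs, band, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(band)) {
    tab <- eeg_bands()
    i <- match(band, tab$name)
    if (is.na(i)) stop("unknown band '", band, "'")
    band <- band_definition(tab$name[i], tab$low[i], tab$high[i])
  }
  fs <- epochs$sampling_rate
  if (band$high >= fs / 2) {
    stop("band edge ", band$high, " Hz at or above Nyquist (", fs / 2, " Hz)")
  }
  bf <- signal::butter(order, c(band$low, band$high) / (fs / 2), type = "pass")
  out <- epochs$data
  for (tr in seq_len(dim(out)[1])) {
    for (ch in seq_len(dim(out)[2])) {
      out[tr, ch, ] <- filtfilt_padded(bf, epochs$data[tr, ch, ])
    }
  }
  res <- epochs
  res$data <- out
  res$band <- band$name
  res
}
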