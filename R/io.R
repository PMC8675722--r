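#' Write an epoch set as delimited text plus a JSON sidecar
#'
#' One tab-delimited channels x samples matrix per trial
#' (`trial_001.tsv`, ...) and a `meta.json` sidecar holding sampling rate,
#' band, condition, subject and channel labels.
#'
#' @param epochs An [epoch_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epoch_set <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in seq_len(n_trials(epochs))) {
    write.table(epochs$data[tr, , , drop = TRUE],
                file.path(dir, sprintf("trial_%03d.tsv", tr)),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(sampling_rate = epochs$sampling_rate, band = epochs$band,
               condition = epochs$condition, subject_id = epochs$subject_id,
               channel_labels = epochs$channel_labels,
               n_trials = n_trials(epochs),
               n_channels = n_channels_of(epochs),
               n_samples = n_samples_of(epochs))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an epoch set written by [write_epoch_set()]
#' @param dir Directory containing `trial_*.tsv` and `meta.json`.
#' @return An [epoch_set()].
#' @export
read_epoch_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  data <- array(0, dim = c(meta$n_trials, meta$n_channels, meta$n_samples))
  for (tr in seq_len(meta$n_trials)) {
    data[tr, , ] <- as.matrix(read.table(
      file.path(dir, sprintf("trial_%03d.tsv", tr)), sep = "\t"))
  }
  epoch_set(data, meta$sampling_rate, band = meta$band,
            condition = meta$condition, subject_id = meta$subject_id,
            channel_labels = meta$channel_labels)
}

#' Write a distance matrix as delimited text plus a JSON sidecar
#' @param dm A [distance_matrix()].
#' @param path Path of the matrix file; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  write.table(unclass(dm), path, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  meta <- list(metric = attr(dm, "metric"),
               normalization = attr(dm, "normalization"),
               provenance = attr(dm, "provenance"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#' @param path Path of the matrix file.
#' @return A [distance_matrix()].
#' @export
read_distance_matrix <- function(path) {
  M <- as.matrix(read.table(path, sep = "\t"))
  dimnames(M) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  distance_matrix(M, metric = meta$metric,
                  normalization = if (is.null(meta$normalization)) "none"
                  else meta$normalization,
                  provenance = as.list(meta$provenance))
}

#' Write a barcode as a delimited table
#' @param barcode A `barcode` from [rips_persistence()].
#' @param path Output file (columns dimension, birth, death, infinite).
#' @return `path`, invisibly.
#' @export
write_barcode <- function(barcode, path) {
  write.table(as.data.frame(barcode), path, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a recording from the European Data Format (EDF)
#'
#' Minimal reader for plain continuous EDF: parses the 256-byte fixed
#' header and per-signal headers, decodes the 16-bit little-endian samples
#' of every data record, and rescales digital to physical units per
#' channel. Annotation channels (EDF+) are skipped. Signals must share one
#' sampling rate.
#'
#' @param path Path to an `.edf` file.
#' @return An [eeg_recording()] (with no events).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  version <- hdr(8)
  if (version != "0") stop("unsupported EDF version '", version, "'")
  hdr(80); hdr(80); hdr(8); hdr(8)      # patient, recording, date, time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                                # reserved
  n_records <- as.integer(hdr(8))
  record_duration <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  field <- function(nc) vapply(seq_len(ns), function(i) hdr(nc), character(1))
  labels <- field(16)
  field(80); field(8)                    # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                              # prefiltering
  spr <- as.integer(field(8))            # samples per record per signal
  field(32)                              # reserved
  seek(con, header_bytes)
  keep <- !grepl("Annotations", labels)
  if (length(unique(spr[keep])) != 1) {
    stop("signals with differing sampling rates are not supported")
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, sum(keep), n_records * spr[keep][1])
  for (r in seq_len(n_records)) {
    row <- 0
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      if (keep[s]) {
        row <- row + 1
        cols <- seq((r - 1) * spr[s] + 1, r * spr[s])
        data[row, cols] <- phys_min[s] + gain[s] * (raw - dig_min[s])
      }
    }
  }
  fs <- spr[keep][1] / record_duration
  eeg_recording(data, fs, channel_labels = labels[keep])
}
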