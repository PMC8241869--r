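#' Multi-channel EEG recording container
#'
#' A light container for continuous multi-channel EEG: a numeric matrix of
#' samples by channels plus the sampling rate and the current reference.
#' Values are physical microvolts throughout the package.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param channels Character vector of channel labels (unique, one per
#'   column).
#' @param fs Sampling rate in Hz.
#' @param reference Label describing the reference state (e.g. `"AFz"`,
#'   `"mastoids"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channels, fs, reference = "unknown") {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), length(channels) == ncol(data),
            !anyDuplicated(channels), is.numeric(fs), fs > 0)
  colnames(data) <- channels
  structure(
    list(data = data, channels = as.character(channels), fs = fs,
         reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              length(x$channels), nrow(x$data), x$fs,
              nrow(x$data) / x$fs, x$reference))
  invisible(x)
}

#' @export
`[.eeg_recording` <- function(x, channels) {
  missing <- setdiff(channels, x$channels)
  if (length(missing) > 0) {
    stop("Channel(s) not in recording: ", paste(missing, collapse = ", "))
  }
  eeg_recording(x$data[, channels, drop = FALSE], channels, x$fs, x$reference)
}

#' Duration of a recording in seconds
#' @param eeg An [eeg_recording()].
#' @return Length in seconds.
#' @export
eeg_duration <- function(eeg) nrow(eeg$data) / eeg$fs

#' Write an EEG recording to an EDF file
#'
#' Writes European Data Format (EDF): a fixed-layout ASCII header followed by
#' 16-bit little-endian sample records, one-second data records, physical
#' units microvolts. The physical range is chosen per channel from the data
#' so quantization error is below half a digital step.
#'
#' @param eeg An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_recording"))
  fs <- eeg$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- length(eeg$channels)
  n_samp <- nrow(eeg$data)
  n_rec <- ceiling(n_samp / fs)
  pad <- n_rec * fs - n_samp
  x <- eeg$data
  if (pad > 0) x <- rbind(x, matrix(0, pad, ns))

  phys_min <- apply(x, 2, min)
  phys_max <- apply(x, 2, max)
  span <- pmax(phys_max - phys_min, 1e-6)
  phys_min <- phys_min - 0.001 * span
  phys_max <- phys_max + 0.001 * span
  dig_min <- -32768; dig_max <- 32767

  fmt <- function(v, width) {
    s <- substr(format(v, width = width, justify = "left"), 1, width)
    formatC(s, width = width, flag = "-")
  }
  num <- function(v, width) {
    s <- formatC(signif(v, 8), width = width, format = "g", flag = "-")
    s <- substr(s, 1, width)
    formatC(s, width = width, flag = "-")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    fmt("0", 8),                       # version
    fmt("X X X X", 80),                # patient id (anonymous)
    fmt(paste("Startdate X X X X ref", eeg$reference), 80),
    "01.01.00", "00.00.00",            # start date / time
    fmt(as.character(256 * (ns + 1)), 8),
    fmt("", 44),
    fmt(as.character(n_rec), 8),
    fmt("1", 8),                       # record duration, seconds
    fmt(as.character(ns), 4)
  )
  writeChar(header, con, eos = NULL)
  writeChar(paste0(fmt(eeg$channels, 16), collapse = ""), con, eos = NULL)
  writeChar(paste0(fmt(rep("", ns), 80), collapse = ""), con, eos = NULL)  # transducer
  writeChar(paste0(fmt(rep("uV", ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(num(phys_min, 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(num(phys_max, 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(fmt(rep(as.character(dig_min), ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(fmt(rep(as.character(dig_max), ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(fmt(rep("", ns), 80), collapse = ""), con, eos = NULL)  # prefiltering
  writeChar(paste0(fmt(rep(as.character(fs), ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(fmt(rep("", ns), 32), collapse = ""), con, eos = NULL)  # reserved

  # re-read the physical ranges exactly as a reader will parse them, so the
  # stored digital values invert to the same physical values
  pmin_r <- as.numeric(num(phys_min, 8))
  pmax_r <- as.numeric(num(phys_max, 8))
  gain <- (pmax_r - pmin_r) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    dig <- vapply(seq_len(ns), function(j) {
      as.integer(round((x[idx, j] - pmin_r[j]) / gain[j]) + dig_min)
    }, integer(fs))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Minimal EDF reader covering continuous recordings with a common sampling
#' rate across channels (the layout this package writes).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80)
  rec_info <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  channels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nsamp)) != 1) stop("read_edf supports a common sampling rate only")
  fs <- nsamp[1] / rec_dur
  gain <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, n_rec * nsamp[1], ns)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * nsamp[1], size = 2,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = nsamp[1], ncol = ns)
    idx <- ((r - 1) * nsamp[1] + 1):(r * nsamp[1])
    out[idx, ] <- sweep(sweep(block, 2, dmin, "-"), 2, gain, "*") +
      matrix(pmin, nsamp[1], ns, byrow = TRUE)
  }
  ref <- sub(".*ref ", "", trimws(rec_info))
  eeg_recording(out, channels, fs, reference = ref)
}
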