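#' Raw multichannel recording
#'
#' Bundle a channels-by-samples numeric matrix with its sampling rate. This is
#' the object that flows through band-pass filtering and epoch segmentation.
#'
#' @param samples Numeric matrix, one row per channel (microvolt scale;
#'   unitless internally).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Optional character vector of channel identifiers.
#' @return An object of class `raw_recording` with elements `samples`, `fs`,
#'   `channel_names`.
#' @export
#' @examples
#' rec <- raw_recording(matrix(rnorm(512), nrow = 2), fs = 128)
#' n_channels(rec)
raw_recording <- function(samples, fs, channel_names = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) abort("samples must be numeric")
  if (nrow(samples) < 1) abort("a recording needs at least one channel")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("fs must be a positive scalar (Hz)")
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite sample at channel %d, sample %d", bad[1], bad[2]))
  }
  if (!is.null(channel_names) && length(channel_names) != nrow(samples)) {
    abort("channel_names length must match the number of channels")
  }
  structure(list(samples = samples, fs = fs, channel_names = channel_names),
            class = "raw_recording")
}

#' @rdname raw_recording
#' @param x A `raw_recording`.
#' @export
n_channels <- function(x) nrow(x$samples)

#' Load a recording from disk
#'
#' Two on-disk forms are supported: delimited numeric text (one row per
#' channel, whitespace/comma separated, no header) and an RDS array container
#' holding a list with fields `data` (channels x samples matrix), `fs`, and
#' optionally `labels` and `channel_names`.
#'
#' @param path File path.
#' @param format One of `"delimited"`, `"rds"`. (`"edf"` is recognised but not
#'   supported by this build and raises an error.)
#' @param fs Sampling rate in Hz; required for delimited input, taken from the
#'   container otherwise.
#' @return A [raw_recording()].
#' @export
load_recording <- function(path, format = c("delimited", "rds", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "edf") {
    abort("EDF input is not supported by this build; convert to delimited text or an RDS container")
  }
  if (format == "delimited") {
    if (is.null(fs)) abort("fs must be given for delimited input")
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    mat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    storage.mode(mat) <- "double"
    dimnames(mat) <- NULL
    return(raw_recording(mat, fs = fs))
  }
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$fs)) {
    abort("RDS container must be a list with fields `data` and `fs`")
  }
  rec <- raw_recording(as.matrix(obj$data), fs = obj$fs,
                       channel_names = obj$channel_names)
  rec$labels <- obj$labels
  rec
}

#' Band-pass filter specification
#'
#' Defaults follow standard EEG practice: order-4 Butterworth, 0.5-50 Hz,
#' applied forward-backward (zero phase) so features see no group delay.
#'
#' @param low_hz,high_hz Passband edges in Hz.
#' @param order Filter order (per pass).
#' @param zero_phase Apply forward-backward filtering?
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 50, order = 4L, zero_phase = TRUE) {
  if (!(low_hz > 0 && high_hz > low_hz)) abort("need 0 < low_hz < high_hz")
  if (order < 1) abort("order must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Apply a Butterworth band-pass filter to a recording
#'
#' Attenuates energy outside `[low_hz, high_hz]`; magnitude response is -3 dB
#' at each edge per pass. Zero-phase mode squares the magnitude response and
#' introduces no group delay.
#'
#' @param rec A [raw_recording()].
#' @param spec A [filter_spec()].
#' @return A filtered `raw_recording` of the same shape.
#' @export
apply_bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs / 2
  if (spec$high_hz >= nyq) {
    abort(sprintf("high passband edge (%.3g Hz) must lie below Nyquist (%.3g Hz)",
                  spec$high_hz, nyq))
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq, type = "pass")
  filt1 <- function(x) {
    if (spec$zero_phase) signal::filtfilt(bf, x) else as.numeric(signal::filter(bf, x))
  }
  out <- t(apply(rec$samples, 1, filt1))
  if (nrow(rec$samples) == 1) out <- matrix(out, nrow = 1)
  raw_recording(out, fs = rec$fs, channel_names = rec$channel_names)
}

# Complex frequency response of the designed filter at frequencies f (Hz),
# per single pass; used by tests as the direct transfer-function oracle.
bandpass_response <- function(spec, fs, f) {
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(bf$b * zz^(-(seq_along(bf$b) - 1))), complex(1))
  den <- vapply(z, function(zz) sum(bf$a * zz^(-(seq_along(bf$a) - 1))), complex(1))
  num / den
}

#' Trial-segmented epochs with labels
#'
#' @param data Numeric array, trials x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param labels Binary (0/1) vector, one label per trial.
#' @return An `epoch_set`.
#' @export
epoch_set <- function(data, fs, labels) {
  if (length(dim(data)) != 3) abort("data must be a trials x channels x samples array")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1]) abort("one label per trial required")
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary (0/1)")
  check_finite(data, "epoch data")
  structure(list(data = data, fs = fs, labels = labels), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz (class 1: %d/%d)\n",
              d[1], d[2], d[3], x$fs, sum(x$labels), d[1]))
  invisible(x)
}

#' Segment a continuous recording into labeled epochs
#'
#' The recording is cut into consecutive trials of `trial_len_s` seconds; the
#' first `baseline_s` seconds of every trial (a pre-trial baseline) are
#' discarded. Sample identity is conserved: epochs plus discarded baselines
#' reconstruct the consumed input exactly.
#'
#' @param rec A [raw_recording()].
#' @param trial_len_s Trial length in seconds (baseline included).
#' @param baseline_s Pre-trial baseline to discard, in seconds.
#' @param labels Binary vector, one entry per trial.
#' @return An [epoch_set()] whose epochs have
#'   `round((trial_len_s - baseline_s) * fs)` samples.
#' @export
segment_epochs <- function(rec, trial_len_s, baseline_s = 0, labels) {
  stopifnot(inherits(rec, "raw_recording"))
  n_trials <- length(labels)
  trial_n <- round(trial_len_s * rec$fs)
  base_n <- round(baseline_s * rec$fs)
  if (base_n >= trial_n) abort("baseline must be shorter than the trial")
  need <- n_trials * trial_n
  if (ncol(rec$samples) < need) {
    abort(sprintf("recording too short: need %d samples for %d trials, have %d",
                  need, n_trials, ncol(rec$samples)))
  }
  keep <- trial_n - base_n
  data <- array(0, dim = c(n_trials, nrow(rec$samples), keep))
  for (tr in seq_len(n_trials)) {
    i0 <- (tr - 1) * trial_n + base_n
    data[tr, , ] <- rec$samples[, (i0 + 1):(i0 + keep), drop = FALSE]
  }
  epoch_set(data, fs = rec$fs, labels = labels)
}
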