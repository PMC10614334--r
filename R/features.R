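#' Clinical EEG frequency bands
#'
#' Standard delta/theta/alpha/beta/gamma edges. Bands whose upper edge exceeds
#' the Nyquist frequency are capped at `fs/2` when the power is computed
#' (e.g. gamma becomes 30-64 Hz at fs = 128).
#'
#' @param bands Named list of `c(low_hz, high_hz)` pairs, ordered and
#'   non-overlapping.
#' @return A `band_spec` list.
#' @export
band_spec <- function(bands = list(delta = c(0.5, 4), theta = c(4, 8),
                                   alpha = c(8, 12), beta = c(12, 30),
                                   gamma = c(30, 100))) {
  edges <- do.call(rbind, bands)
  if (any(edges[, 1] >= edges[, 2])) abort("each band needs low_hz < high_hz")
  if (nrow(edges) > 1 && any(edges[-1, 1] < edges[-nrow(edges), 2])) {
    abort("bands must be ordered and non-overlapping")
  }
  structure(list(bands = bands), class = "band_spec")
}

# Welch averaged periodogram: Hann window, seg_len samples, 50% overlap.
# Returns one-sided PSD (power per Hz) at frequencies f.
welch_psd <- function(x, fs, seg_len = NULL) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, round(2 * fs))
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / seg_len)  # Hann (periodic)
  u <- sum(w^2)
  nf <- seg_len %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * w
    sp <- Mod(fft(seg))[1:nf]^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (seg_len %% 2 == 0) scale2[nf] <- 1
  list(f = (0:(nf - 1)) * fs / seg_len, psd = psd * scale2)
}

#' Band power via Welch's averaged periodogram
#'
#' The PSD (Hann window, 2 s segments, 50% overlap) is integrated over each
#' band of `bands`; bands are capped at Nyquist.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param bands A [band_spec()].
#' @return Named nonnegative numeric vector, one power per band.
#' @export
band_power <- function(signal, fs, bands = band_spec()) {
  stopifnot(inherits(bands, "band_spec"))
  est <- welch_psd(signal, fs)
  df <- est$f[2] - est$f[1]
  out <- vapply(bands$bands, function(e) {
    hi <- min(e[2], fs / 2)
    if (e[1] >= fs / 2) abort(sprintf("band [%g, %g] lies above Nyquist", e[1], e[2]))
    sum(est$psd[est$f > e[1] & est$f <= hi]) * df
  }, numeric(1))
  names(out) <- names(bands$bands)
  out
}

#' Flatness of a magnitude spectrum
#'
#' Geometric over arithmetic mean of nonnegative magnitude bins,
#' epsilon-guarded; 1 for a flat spectrum, 0 for an all-zero one.
#'
#' @param y Nonnegative magnitude bins.
#' @param epsilon Guard added inside the log for zero bins.
#' @return Scalar in `[0, 1]`.
#' @export
magnitude_flatness <- function(y, epsilon = 1e-12) {
  if (length(y) == 0) abort("empty magnitude spectrum")
  if (any(y < 0)) abort("magnitude bins must be nonnegative")
  am <- mean(y)
  if (am <= epsilon) return(0)
  gm <- exp(mean(log(y + epsilon)))
  min(gm / am, 1)
}

#' Spectral flatness (Wiener entropy) of a signal
#'
#' Computed on the positive-frequency magnitude spectrum of the whole signal.
#' White-noise-like signals approach 1; pure tones approach 0.
#'
#' @param signal Numeric vector.
#' @param epsilon Guard for zero bins.
#' @return Scalar in `[0, 1]`; 0 for the all-zero signal by convention.
#' @export
spectral_flatness <- function(signal, epsilon = 1e-12) {
  if (length(signal) == 0) abort("empty signal")
  nf <- length(signal) %/% 2 + 1
  y <- Mod(fft(signal))[1:nf]
  magnitude_flatness(y, epsilon)
}

#' Shannon entropy of a probability vector (bits)
#'
#' @param p Probability vector: nonnegative, summing to 1 within 1e-9.
#' @return `-sum(p * log2(p))` with `0 * log(0) = 0`.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) abort("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) abort("probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Bernoulli-map weight sequence
#'
#' Iterates the doubling map `w <- (2 w) mod 1` from `w0`; the weights are the
#' successive iterates (the seed itself is not emitted), floored at `epsilon`
#' so later divisions stay finite.
#'
#' @param n Number of weights.
#' @param w0 Seed in (0, 1); coarse dyadic rationals collapse the map to zero
#'   and are rejected by [entropy_spec()].
#' @param epsilon Floor applied to each weight.
#' @return Numeric vector of `n` weights in `[epsilon, 1)`.
#' @export
bernoulli_weights <- function(n, w0, epsilon = 1e-12) {
  if (n < 1) abort("n must be >= 1")
  if (!(w0 > 0 && w0 < 1)) abort("w0 must lie strictly in (0, 1)")
  w <- numeric(n)
  cur <- w0
  for (i in seq_len(n)) {
    cur <- (2 * cur) %% 1
    w[i] <- max(cur, epsilon)
  }
  w
}

#' Improved-entropy configuration
#'
#' @param n_bins Number of equal-width amplitude histogram bins (>= 2).
#' @param w0 Bernoulli-map seed in (0, 1), not a coarse dyadic rational.
#' @param epsilon Guard used inside the double logarithm and as weight floor.
#' @return An `entropy_spec` list.
#' @export
entropy_spec <- function(n_bins = 8L, w0 = 0.7, epsilon = 1e-12) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (!(w0 > 0 && w0 < 1)) abort("w0 must lie strictly in (0, 1)")
  if (isTRUE(all.equal(w0 * 2^20, round(w0 * 2^20)))) {
    abort("w0 must not be a dyadic rational (the Bernoulli map would collapse to 0)")
  }
  structure(list(n_bins = as.integer(n_bins), w0 = w0, epsilon = epsilon),
            class = "entropy_spec")
}

#' Sign-conditioned, Bernoulli-map-weighted entropy
#'
#' Amplitudes are binned into `n_bins` equal-width histogram bins over
#' `[min, max]`. With `pos`/`neg` the global counts of positive-/negative-
#' signed samples and `P(pos|y_i)` the positive fraction inside bin `i`, the
#' value is
#' `sum_i P(pos|y_i) * (neg/pos) * log2(|ln(P(neg|y_i) * (pos/neg) + eps)| + eps) / wei_i`,
#' where `wei_i` comes from [bernoulli_weights()] and empty bins contribute 0.
#' The double logarithm is guarded with absolute values since its inner
#' argument may fall in (0, 1).
#'
#' @param signal Numeric vector containing at least one positive and one
#'   negative sample (band-passed EEG is zero-mean, so this holds in practice).
#' @param spec An [entropy_spec()].
#' @param weights Optional explicit per-bin weights overriding the
#'   Bernoulli-map sequence (the value is homogeneous of degree -1 in them).
#' @return Scalar entropy value.
#' @export
improved_entropy <- function(signal, spec = entropy_spec(), weights = NULL) {
  stopifnot(inherits(spec, "entropy_spec"))
  pos <- sum(signal > 0)
  neg <- sum(signal < 0)
  if (pos == 0 || neg == 0) {
    abort("signal must contain both positive and negative samples; mean-center it first")
  }
  eps <- spec$epsilon
  b <- spec$n_bins
  edges <- seq(min(signal), max(signal), length.out = b + 1)
  bin <- findInterval(signal, edges, rightmost.closed = TRUE, all.inside = TRUE)
  wei <- weights %||% bernoulli_weights(b, spec$w0, eps)
  if (length(wei) != b) abort("weights must have one entry per bin")
  total <- 0
  for (i in seq_len(b)) {
    in_bin <- bin == i
    n_i <- sum(in_bin)
    if (n_i == 0) next
    p_pos <- sum(signal[in_bin] > 0) / n_i
    p_neg <- sum(signal[in_bin] < 0) / n_i
    inner <- abs(log(p_neg * (pos / neg) + eps)) + eps
    total <- total + p_pos * (neg / pos) * log2(inner) / wei[i]
  }
  total
}

#' Shannon entropy of the amplitude histogram
#'
#' The conventional-entropy ablation counterpart of [improved_entropy()]:
#' Shannon entropy (bits) of the `n_bins` equal-width amplitude-histogram
#' probabilities.
#'
#' @inheritParams improved_entropy
#' @return Scalar in `[0, log2(n_bins)]`.
#' @export
amplitude_entropy <- function(signal, spec = entropy_spec()) {
  b <- spec$n_bins
  edges <- seq(min(signal), max(signal), length.out = b + 1)
  if (edges[1] == edges[b + 1]) return(0)
  bin <- findInterval(signal, edges, rightmost.closed = TRUE, all.inside = TRUE)
  shannon_entropy(tabulate(bin, b) / length(signal))
}

#' Assemble the per-trial feature matrix
#'
#' For every trial, features are computed per channel and concatenated in
#' fixed order: DWT sub-band statistics, band powers, spectral flatness, then
#' entropy (improved or conventional, per `entropy_mode`).
#'
#' @param epochs An [epoch_set()].
#' @param dwt A [dwt_spec()].
#' @param bands A [band_spec()].
#' @param entropy An [entropy_spec()].
#' @param entropy_mode `"improved"` (sign-conditioned weighted entropy) or
#'   `"conventional"` (Shannon entropy of the amplitude histogram).
#' @return A tibble with `.trial`, `.label`, and one column per feature;
#'   attribute `"config"` snapshots the specs used.
#' @export
extract_feature_matrix <- function(epochs, dwt = dwt_spec(), bands = band_spec(),
                                   entropy = entropy_spec(),
                                   entropy_mode = c("improved", "conventional")) {
  stopifnot(inherits(epochs, "epoch_set"))
  entropy_mode <- match.arg(entropy_mode)
  d <- dim(epochs$data)
  if (d[1] < 1) abort("no trials in epoch set")
  ent_fun <- if (entropy_mode == "improved") improved_entropy else amplitude_entropy

  one_channel <- function(x) {
    c(dwt_features(dwt_decompose(x, dwt), dwt$stats),
      stats::setNames(band_power(x, epochs$fs, bands),
                      paste0("bp_", names(bands$bands))),
      flatness = spectral_flatness(x),
      entropy = ent_fun(x, entropy))
  }

  rows <- lapply(seq_len(d[1]), function(tr) {
    feats <- unlist(lapply(seq_len(d[2]), function(ch) {
      v <- one_channel(epochs$data[tr, ch, ])
      names(v) <- paste0("ch", ch, "_", names(v))
      v
    }))
    bad <- which(!is.finite(feats))
    if (length(bad)) {
      abort(sprintf("non-finite feature '%s' in trial %d", names(feats)[bad[1]], tr))
    }
    feats
  })
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- dplyr::bind_cols(tibble::tibble(.trial = seq_len(d[1]),
                                         .label = epochs$labels), out)
  attr(out, "config") <- list(dwt = dwt, bands = bands, entropy = entropy,
                              entropy_mode = entropy_mode, fs = epochs$fs)
  out
}

# Strip the bookkeeping columns of a feature tibble -> plain numeric matrix.
feature_values <- function(features) {
  cols <- setdiff(names(features), c(".trial", ".label"))
  as.matrix(features[, cols, drop = FALSE])
}
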