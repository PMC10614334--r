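#' 1/f (pink-like) noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain so the power
#' spectral density falls off as `f^-exponent`, then centred to zero mean and
#' scaled to unit variance.
#'
#' @param n Number of samples (>= 2).
#' @param exponent Spectral slope (1 = pink noise).
#' @param seed Optional seed; output is deterministic given it.
#' @return Numeric vector of length `n`, zero mean, unit variance.
#' @export
pink_noise <- function(n, exponent = 1, seed = NULL) {
  if (n < 2) abort("n must be >= 2")
  with_local_seed(seed, {
    white <- rnorm(n)
    k <- 0:(n - 1)
    fidx <- pmin(k, n - k)              # symmetric frequency index
    shape <- c(0, fidx[-1]^(-exponent / 2))
    x <- Re(fft(fft(white) * shape, inverse = TRUE)) / n
    x <- x - mean(x)
    x / sd(x)
  })
}

#' Generate trial-structured synthetic EEG epochs
#'
#' Emulates band-limited oscillatory EEG with class-dependent band-power
#' signatures riding on 1/f noise. Every trial carries a 10 Hz (alpha) and a
#' 20 Hz (beta) oscillation of amplitude `amplitude` with random phases;
#' class-1 trials have their beta amplitude scaled by `1 + effect_size`, so
#' the beta/alpha power ratio separates the classes. With `effect_size = 0`
#' the two classes are identically distributed. Labels are balanced and
#' interleaved; generation is deterministic given `seed`.
#'
#' @param n_trials Number of trials (even, for balanced classes).
#' @param n_channels Channels per trial (4 by default; 32 mirrors full-montage
#'   recordings).
#' @param fs Sampling rate in Hz.
#' @param trial_len_s Trial length in seconds.
#' @param effect_size Nonnegative beta-amplitude contrast between classes.
#' @param noise_exponent 1/f slope of the background noise.
#' @param amplitude Oscillation amplitude relative to unit-variance noise.
#' @param line_noise_hz Optional mains-interference frequency; adds a fixed
#'   0.5-amplitude sinusoid to every channel.
#' @param seed RNG seed.
#' @return An [epoch_set()].
#' @export
generate_epochs <- function(n_trials = 100L, n_channels = 4L, fs = 128,
                            trial_len_s = 12, effect_size = 2, noise_exponent = 1,
                            amplitude = 1, line_noise_hz = NULL, seed = 1L) {
  if (n_trials < 2 || n_trials %% 2 != 0) abort("n_trials must be even and >= 2 (balanced classes)")
  if (effect_size < 0) abort("effect_size must be nonnegative")
  if (n_channels < 1 || fs <= 0 || trial_len_s <= 0) abort("degenerate generator config")
  n <- round(trial_len_s * fs)
  tt <- (0:(n - 1)) / fs
  labels <- rep(c(0L, 1L), n_trials / 2)
  with_local_seed(seed, {
    data <- array(0, dim = c(n_trials, n_channels, n))
    for (tr in seq_len(n_trials)) {
      beta_amp <- amplitude * (1 + effect_size * labels[tr])
      for (ch in seq_len(n_channels)) {
        noise <- {
          white <- rnorm(n)
          k <- 0:(n - 1)
          shape <- c(0, pmin(k, n - k)[-1]^(-noise_exponent / 2))
          x <- Re(fft(fft(white) * shape, inverse = TRUE)) / n
          (x - mean(x)) / sd(x)
        }
        sig <- noise +
          amplitude * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) +
          beta_amp * sin(2 * pi * 20 * tt + runif(1, 0, 2 * pi))
        if (!is.null(line_noise_hz)) {
          sig <- sig + 0.5 * sin(2 * pi * line_noise_hz * tt)
        }
        data[tr, ch, ] <- sig
      }
    }
    epoch_set(data, fs = fs, labels = labels)
  })
}
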