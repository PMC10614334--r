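#' Daubechies scaling filters
#'
#' Orthonormal scaling (lowpass reconstruction) coefficients, sum = sqrt(2).
#' db1 is the Haar wavelet; dbN has N vanishing moments and 2N taps.
#'
#' @param name One of `"db1"`, `"db2"`, `"db4"`.
#' @return Numeric vector of scaling coefficients.
#' @export
wavelet_filter <- function(name = c("db4", "db2", "db1")) {
  name <- match.arg(name)
  switch(name,
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(0.48296291314453416, 0.8365163037378079,
            0.2241438680420134, -0.12940952255126037),
    db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
            0.0328830116668852, -0.010597401785069032)
  )
}

#' DWT configuration
#'
#' @param wavelet_name Mother wavelet (see [wavelet_filter()]). Default `db4`:
#'   at fs = 128 Hz four levels give detail sub-bands roughly matching the
#'   clinical gamma/beta/alpha/theta bands with a delta approximation.
#' @param levels Number of decomposition levels (>= 1).
#' @param stats Per-sub-band statistics, any of `"mean"`, `"std"`, `"energy"`,
#'   `"mean_abs"`, computed in the declared order.
#' @return A `dwt_spec` list.
#' @export
dwt_spec <- function(wavelet_name = "db4", levels = 4L,
                     stats = c("mean", "std", "energy", "mean_abs")) {
  if (levels < 1) abort("levels must be >= 1")
  stats <- match.arg(stats, several.ok = TRUE)
  structure(list(wavelet_name = wavelet_name, levels = as.integer(levels),
                 stats = stats), class = "dwt_spec")
}

dwt_step <- function(x, h) {
  n <- length(x)
  L <- length(h)
  half <- n %/% 2
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror highpass
  a <- numeric(half)
  d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_len(L)) {
    idx <- (base + m - 1) %% n + 1
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h, n) {
  L <- length(h)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  x <- numeric(n)
  base <- 2 * (seq_along(a) - 1)
  for (m in seq_len(L)) {
    idx <- (base + m - 1) %% n + 1
    contrib <- a * h[m] + d * g[m]
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Periodized orthogonal discrete wavelet transform
#'
#' Mallat pyramid with periodic boundary handling. The transform is
#' orthonormal, so coefficient energy equals signal energy and
#' [dwt_reconstruct()] inverts it exactly.
#'
#' @param signal Numeric vector; its length must be divisible by
#'   `2^spec$levels` (periodized perfect reconstruction needs an even length
#'   at every level).
#' @param spec A [dwt_spec()].
#' @return Named list of coefficient vectors: `a<levels>` (approximation),
#'   then details `d<levels>` (coarsest) ... `d1` (finest).
#' @export
dwt_decompose <- function(signal, spec = dwt_spec()) {
  n <- length(signal)
  if (n < 2^spec$levels) abort("signal shorter than 2^levels")
  if (n %% 2^spec$levels != 0) {
    abort(sprintf("signal length (%d) must be divisible by 2^levels (%d)", n, 2^spec$levels))
  }
  check_finite(signal, "signal")
  h <- wavelet_filter(spec$wavelet_name)
  details <- vector("list", spec$levels)
  a <- signal
  for (lev in seq_len(spec$levels)) {
    st <- dwt_step(a, h)
    a <- st$a
    details[[lev]] <- st$d
  }
  out <- c(list(a), rev(details))
  names(out) <- c(paste0("a", spec$levels), paste0("d", spec$levels:1))
  out
}

#' Invert [dwt_decompose()]
#'
#' @param coeffs Coefficient list as returned by [dwt_decompose()].
#' @param spec The [dwt_spec()] used for decomposition.
#' @return The reconstructed signal.
#' @export
dwt_reconstruct <- function(coeffs, spec = dwt_spec()) {
  h <- wavelet_filter(spec$wavelet_name)
  a <- coeffs[[1]]
  levels <- length(coeffs) - 1
  for (lev in seq_len(levels)) {
    d <- coeffs[[1 + lev]]  # coarsest detail first
    a <- idwt_step(a, d, h, 2 * length(a))
  }
  a
}

#' Per-sub-band DWT statistics
#'
#' @param coeffs Sub-band coefficient list (approximation first, then details
#'   coarse to fine), e.g. from [dwt_decompose()].
#' @param stats Statistics to compute per band, in order.
#' @return Named numeric vector of length `length(coeffs) * length(stats)`.
#' @export
dwt_features <- function(coeffs, stats = c("mean", "std", "energy", "mean_abs")) {
  if (length(coeffs) == 0) abort("empty coefficient list")
  if (any(lengths(coeffs) == 0)) abort("empty sub-band in coefficient list")
  stat_fun <- list(
    mean = mean,
    std = function(x) if (length(x) > 1) sd(x) else 0,
    energy = function(x) sum(x^2),
    mean_abs = function(x) mean(abs(x))
  )
  bad <- setdiff(stats, names(stat_fun))
  if (length(bad)) abort(paste0("unknown statistic: ", paste(bad, collapse = ", ")))
  nm <- names(coeffs) %||% paste0("band", seq_along(coeffs))
  out <- unlist(lapply(seq_along(coeffs), function(i) {
    v <- vapply(stats, function(s) stat_fun[[s]](coeffs[[i]]), numeric(1))
    names(v) <- paste0("dwt_", nm[i], "_", stats)
    v
  }))
  out
}
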