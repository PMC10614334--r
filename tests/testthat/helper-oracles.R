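# Independently coded brute-force oracles. These deliberately re-derive each
# quantity from its definition with plain loops so they share no code path
# with the package implementation.

oracle_flatness <- function(y, eps = 1e-12) {
  M <- length(y)
  am <- sum(y) / M
  if (am <= eps) return(0)
  logsum <- 0
  for (v in y) logsum <- logsum + log(v + eps)
  min(exp(logsum / M) / am, 1)
}

oracle_spectral_flatness <- function(x, eps = 1e-12) {
  n <- length(x)
  nf <- n %/% 2 + 1
  y <- numeric(nf)
  for (m in 0:(nf - 1)) {
    acc <- 0 + 0i
    for (k in 0:(n - 1)) acc <- acc + x[k + 1] * exp(-2i * pi * m * k / n)
    y[m + 1] <- Mod(acc)
  }
  oracle_flatness(y, eps)
}

oracle_bernoulli <- function(n, w0, eps = 1e-12) {
  w <- numeric(n)
  for (i in seq_len(n)) {
    w0 <- 2 * w0 - floor(2 * w0)
    w[i] <- if (w0 < eps) eps else w0
  }
  w
}

oracle_improved_entropy <- function(x, b = 8, w0 = 0.7, eps = 1e-12) {
  pos <- sum(x > 0); neg <- sum(x < 0)
  lo <- min(x); hi <- max(x)
  width <- (hi - lo) / b
  wei <- oracle_bernoulli(b, w0, eps)
  total <- 0
  for (i in seq_len(b)) {
    e_lo <- lo + (i - 1) * width
    e_hi <- if (i == b) hi else lo + i * width
    in_bin <- if (i == b) x >= e_lo & x <= e_hi else x >= e_lo & x < e_hi
    n_i <- sum(in_bin)
    if (n_i == 0) next
    p_pos <- sum(x[in_bin] > 0) / n_i
    p_neg <- sum(x[in_bin] < 0) / n_i
    total <- total + p_pos * (neg / pos) *
      log2(abs(log(p_neg * (pos / neg) + eps)) + eps) / wei[i]
  }
  total
}

oracle_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) 0 else a / b
  sens <- div(tp, tp + fn); spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp); npv <- div(tn, tn + fn)
  den <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       sensitivity = sens, specificity = spec, precision = prec, npv = npv,
       f1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens),
       mcc = if (den == 0) 0 else (as.double(tp) * tn - as.double(fp) * fn) / den,
       fpr = 1 - spec, fnr = 1 - sens, fdr = 1 - prec, for_ = 1 - npv)
}

oracle_weighted_std <- function(z, w) {
  kp <- sum(w > 0)
  if (kp < 2) return(0)
  zbar <- sum(w * z) / sum(w)
  num <- 0
  for (i in seq_along(z)) num <- num + w[i] * (z[i] - zbar)^2
  sqrt(num / (((kp - 1) / kp) * sum(w)))
}

# Small fast epoch set for pipeline-level tests.
tiny_epochs <- function(n_trials = 20, n_channels = 2, trial_len_s = 4,
                        effect_size = 2, seed = 1) {
  generate_epochs(n_trials = n_trials, n_channels = n_channels, fs = 128,
                  trial_len_s = trial_len_s, effect_size = effect_size, seed = seed)
}
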