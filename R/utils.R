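#' @importFrom rlang abort warn %||%
#' @importFrom stats fft runif rnorm sd var
NULL

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded helpers have no global side effect.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Fan a global seed out to per-stage seeds. Multiplicative hash keeps streams
# distinct across stages while staying inside the 32-bit integer range.
split_seed <- function(seed, stage) {
  offsets <- c(data = 11L, init = 23L, pretrain = 37L, split = 53L,
               optimizer = 71L, eval = 97L)
  if (!stage %in% names(offsets)) abort(paste0("unknown seed stage: ", stage))
  as.integer((as.double(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x))[1]
    abort(sprintf("%s contains a non-finite value (first at position %d)", what, bad))
  }
  invisible(x)
}

softmax <- function(x) {
  if (is.matrix(x)) {
    z <- exp(x - apply(x, 1, max))
    z / rowSums(z)
  } else {
    z <- exp(x - max(x))
    z / sum(z)
  }
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clip <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# Small deterministic polynomial hash of a config object (hex string), so a
# persisted run directory is self-identifying.
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  sprintf("%08x", Reduce(function(h, ch) (h * 31 + ch) %% 2147483647, s, 17))
}
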