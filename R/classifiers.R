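unif_init <- function(nr, nc = NULL, scale = 0.1) {
  if (is.null(nc)) runif(nr, -scale, scale) else matrix(runif(nr * nc, -scale, scale), nr, nc)
}

#' LSTM parameters
#'
#' Gate recurrence (forget gate `G`, cell candidate `V`, input gate `I`,
#' output gate `L`, cell state `A`, hidden state `Y`):
#' \deqn{G_t = \sigma(P_{IG} X_t + P_{YG} Y_{t-1} + F_{IG} + F_{YG})}
#' \deqn{V_t = \tanh(F_{IV} + P_{IV} X_t + F_{YV} + P_{YV} Y_{t-1})}
#' \deqn{I_t = \sigma(P_{II} X_t + P_{YI} Y_{t-1} + F_{II} + F_{YI})}
#' \deqn{A_t = G_t A_{t-1} + I_t V_t, \quad
#'       L_t = \sigma(P_{IL} X_t + P_{YL} Y_{t-1} + F_{IL} + F_{YL}), \quad
#'       Y_t = L_t \tanh(A_t)}
#' with `A_0 = Y_0 = 0` and a softmax readout over the final hidden state.
#'
#' @param input_dim Per-step input dimension.
#' @param hidden Hidden-state size.
#' @param n_classes Number of output classes.
#' @param seed Optional seed for the uniform(-0.1, 0.1) initialisation.
#' @return An `lstm_params` list of weight matrices, gate biases, and readout.
#' @export
lstm_params <- function(input_dim, hidden = 8L, n_classes = 2L, seed = NULL) {
  with_local_seed(seed, {
    gates <- c("G", "V", "I", "L")
    p <- list(hidden = as.integer(hidden), input_dim = as.integer(input_dim),
              n_classes = as.integer(n_classes))
    for (g in gates) {
      p[[paste0("P_I", g)]] <- unif_init(hidden, input_dim)
      p[[paste0("P_Y", g)]] <- unif_init(hidden, hidden)
      p[[paste0("F_I", g)]] <- unif_init(hidden)
      p[[paste0("F_Y", g)]] <- unif_init(hidden)
    }
    p$W_out <- unif_init(n_classes, hidden)
    p$b_out <- unif_init(n_classes)
    structure(p, class = "lstm_params")
  })
}

# Batched LSTM over an n x T x d array; returns n x n_classes probabilities.
lstm_forward_batch <- function(seq_arr, params) {
  n <- dim(seq_arr)[1]; Tn <- dim(seq_arr)[2]
  h <- params$hidden
  Y <- matrix(0, n, h); A <- matrix(0, n, h)
  for (t in seq_len(Tn)) {
    Xt <- matrix(seq_arr[, t, ], nrow = n)
    G <- sigmoid(Xt %*% t(params$P_IG) + Y %*% t(params$P_YG) +
                   rep(params$F_IG + params$F_YG, each = n))
    V <- tanh(Xt %*% t(params$P_IV) + Y %*% t(params$P_YV) +
                rep(params$F_IV + params$F_YV, each = n))
    I <- sigmoid(Xt %*% t(params$P_II) + Y %*% t(params$P_YI) +
                   rep(params$F_II + params$F_YI, each = n))
    A <- G * A + I * V
    L <- sigmoid(Xt %*% t(params$P_IL) + Y %*% t(params$P_YL) +
                   rep(params$F_IL + params$F_YL, each = n))
    Y <- L * tanh(A)
  }
  softmax(Y %*% t(params$W_out) + rep(params$b_out, each = n))
}

#' LSTM forward pass
#'
#' @param sequence Numeric matrix, time steps x input dimension.
#' @param params An [lstm_params()] object.
#' @return Per-class probability vector (softmax over the final hidden state).
#' @export
lstm_forward <- function(sequence, params) {
  sequence <- as.matrix(sequence)
  if (ncol(sequence) != params$input_dim) abort("sequence width does not match params")
  arr <- array(0, dim = c(1, nrow(sequence), ncol(sequence)))
  arr[1, , ] <- sequence
  drop(lstm_forward_batch(arr, params))
}

#' Elman RNN parameters
#'
#' Hidden recurrence `wg_t = tanh(P x_t + Q wg_{t-1})` with `wg_0 = 0` and a
#' softmax readout `softmax(R wg_T + b)`.
#'
#' @inheritParams lstm_params
#' @return An `rnn_params` list.
#' @export
rnn_params <- function(input_dim, hidden = 8L, n_classes = 2L, seed = NULL) {
  with_local_seed(seed, {
    structure(list(hidden = as.integer(hidden), input_dim = as.integer(input_dim),
                   n_classes = as.integer(n_classes),
                   P = unif_init(hidden, input_dim), Q = unif_init(hidden, hidden),
                   R = unif_init(n_classes, hidden), b_out = unif_init(n_classes)),
              class = "rnn_params")
  })
}

rnn_forward_batch <- function(seq_arr, params) {
  n <- dim(seq_arr)[1]; Tn <- dim(seq_arr)[2]
  W <- matrix(0, n, params$hidden)
  for (t in seq_len(Tn)) {
    Xt <- matrix(seq_arr[, t, ], nrow = n)
    W <- tanh(Xt %*% t(params$P) + W %*% t(params$Q))
  }
  softmax(W %*% t(params$R) + rep(params$b_out, each = n))
}

#' RNN forward pass
#'
#' @param sequence Numeric matrix, time steps x input dimension.
#' @param params An [rnn_params()] object.
#' @return Per-class probability vector.
#' @export
rnn_forward <- function(sequence, params) {
  sequence <- as.matrix(sequence)
  if (ncol(sequence) != params$input_dim) abort("sequence width does not match params")
  arr <- array(0, dim = c(1, nrow(sequence), ncol(sequence)))
  arr[1, , ] <- sequence
  drop(rnn_forward_batch(arr, params))
}

#' Greedy layer-wise contrastive-divergence pretraining
#'
#' Trains a stack of restricted Boltzmann machines on `[0,1]`-normalised
#' features with CD-k; each layer's hidden probabilities feed the next layer.
#' A per-epoch reconstruction-loss curve is recorded for the first RBM using
#' either the mean-absolute-error loss ([mae_loss()], the "improved" DBN
#' criterion) or the conventional squared error, per `loss_mode`.
#'
#' @param data Numeric matrix (observations x features) with entries in
#'   `[0, 1]` (min-max normalise first).
#' @param sizes Hidden-layer sizes, e.g. `c(32, 16)` for two stacked RBMs.
#' @param cd_steps Gibbs steps per CD update.
#' @param epochs Training epochs (0 returns the seeded initialisation).
#' @param lr Learning rate.
#' @param seed Seed; training is bit-reproducible given it.
#' @param loss_mode `"mae"` or `"squared"` reconstruction monitoring.
#' @return A `dbn_params` object (stacked RBMs, no readout yet); element
#'   `recon_loss` holds the monitored curve.
#' @export
rbm_pretrain <- function(data, sizes = c(32L, 16L), cd_steps = 1L, epochs = 10L,
                         lr = 0.05, seed = NULL, loss_mode = c("mae", "squared")) {
  loss_mode <- match.arg(loss_mode)
  data <- as.matrix(data)
  if (nrow(data) == 0) abort("empty training data")
  if (min(data) < -1e-9 || max(data) > 1 + 1e-9) {
    abort("data must be min-max normalised to [0, 1] before pretraining")
  }
  with_local_seed(seed, {
    v <- data
    rbms <- vector("list", length(sizes))
    losses <- NULL
    for (layer in seq_along(sizes)) {
      nv <- ncol(v); nh <- sizes[layer]
      W <- unif_init(nv, nh); b_vis <- unif_init(nv); c_hid <- unif_init(nh)
      n <- nrow(v)
      layer_loss <- numeric(epochs)
      for (ep in seq_len(epochs)) {
        h0 <- sigmoid(v %*% W + rep(c_hid, each = n))
        hs <- (matrix(runif(n * nh), n, nh) < h0) * 1
        vk <- v; hk <- hs
        for (s in seq_len(cd_steps)) {
          vk <- sigmoid(hk %*% t(W) + rep(b_vis, each = n))
          hprob <- sigmoid(vk %*% W + rep(c_hid, each = n))
          hk <- if (s < cd_steps) (matrix(runif(n * nh), n, nh) < hprob) * 1 else hprob
        }
        W <- W + lr * (t(v) %*% h0 - t(vk) %*% hk) / n
        b_vis <- b_vis + lr * colMeans(v - vk)
        c_hid <- c_hid + lr * (colMeans(h0) - colMeans(hk))
        layer_loss[ep] <- if (loss_mode == "mae") {
          mae_loss(as.numeric(v), as.numeric(vk))
        } else {
          mean((v - vk)^2)
        }
      }
      rbms[[layer]] <- list(W = W, b_vis = b_vis, c_hid = c_hid)
      if (layer == 1) losses <- layer_loss
      v <- sigmoid(v %*% W + rep(c_hid, each = nrow(v)))
    }
    structure(list(rbms = rbms, sizes = as.integer(sizes),
                   input_dim = ncol(data), n_classes = NA_integer_,
                   W_out = NULL, b_out = NULL,
                   recon_loss = losses, loss_mode = loss_mode),
              class = "dbn_params")
  })
}

dbn_hidden_batch <- function(X, params) {
  n <- nrow(X)
  h <- X
  for (rbm in params$rbms) {
    h <- sigmoid(h %*% rbm$W + rep(rbm$c_hid, each = n))
  }
  h
}

dbn_forward_batch <- function(X, params) {
  h <- dbn_hidden_batch(X, params)
  softmax(h %*% t(params$W_out) + rep(params$b_out, each = nrow(X)))
}

#' Deterministic bottom-up DBN inference
#'
#' Sigmoid mean activations layer by layer (no sampling), then a softmax
#' readout.
#'
#' @param features Numeric feature vector.
#' @param params A `dbn_params` object with a readout attached (see
#'   [tri_classifier_params()]).
#' @return Per-class probability vector.
#' @export
dbn_forward <- function(features, params) {
  if (length(features) != params$input_dim) abort("feature length does not match params")
  if (is.null(params$W_out)) abort("DBN has no readout; attach one via tri_classifier_params()")
  drop(dbn_forward_batch(matrix(features, nrow = 1), params))
}

#' Mean absolute error loss
#'
#' `(1/N) * sum |x_i - xhat_i|` — the "improved" DBN reconstruction criterion.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return Nonnegative scalar.
#' @export
mae_loss <- function(actual, predicted) {
  if (length(actual) != length(predicted)) abort("length mismatch")
  if (length(actual) < 1) abort("empty vectors")
  mean(abs(actual - predicted))
}

#' Bundle the tri-classifier parameters
#'
#' Builds the LSTM, RNN, and DBN parameter sets over a shared feature space
#' and declares the optimizer-tuned subset: by default the three softmax
#' readouts (LSTM, DBN, RNN, in that flattening order), each weight bounded in
#' `bounds`. Feature vectors are reshaped into `seq_steps` time steps
#' (zero-padded) for the recurrent classifiers.
#'
#' @param input_dim Feature dimension.
#' @param n_classes Number of classes (2 for valence/arousal).
#' @param hidden_lstm,hidden_rnn Hidden sizes.
#' @param dbn_sizes DBN hidden-layer sizes.
#' @param seq_steps Time steps the feature vector is folded into.
#' @param seed Seed for all weight initialisation.
#' @param train_data Optional `[0,1]` feature matrix; if given, DBN weights
#'   come from [rbm_pretrain()] on it.
#' @param dbn_loss_mode Reconstruction monitoring for pretraining.
#' @param bounds Length-2 lower/upper bounds on tuned weights.
#' @param cd_epochs,cd_lr Contrastive-divergence schedule.
#' @return A `tri_classifier_params` object.
#' @export
tri_classifier_params <- function(input_dim, n_classes = 2L, hidden_lstm = 8L,
                                  hidden_rnn = 8L, dbn_sizes = c(32L, 16L),
                                  seq_steps = 4L, seed = NULL, train_data = NULL,
                                  dbn_loss_mode = c("mae", "squared"),
                                  bounds = c(-1, 1), cd_epochs = 10L, cd_lr = 0.05) {
  dbn_loss_mode <- match.arg(dbn_loss_mode)
  step_dim <- ceiling(input_dim / seq_steps)
  lstm <- lstm_params(step_dim, hidden_lstm, n_classes,
                      seed = if (is.null(seed)) NULL else seed + 1L)
  rnn <- rnn_params(step_dim, hidden_rnn, n_classes,
                    seed = if (is.null(seed)) NULL else seed + 2L)
  if (!is.null(train_data)) {
    dbn <- rbm_pretrain(train_data, dbn_sizes, epochs = cd_epochs, lr = cd_lr,
                        seed = if (is.null(seed)) NULL else seed + 3L,
                        loss_mode = dbn_loss_mode)
  } else {
    dbn <- with_local_seed(if (is.null(seed)) NULL else seed + 3L, {
      v <- input_dim
      rbms <- lapply(dbn_sizes, function(nh) {
        r <- list(W = unif_init(v, nh), b_vis = unif_init(v), c_hid = unif_init(nh))
        v <<- nh
        r
      })
      structure(list(rbms = rbms, sizes = as.integer(dbn_sizes),
                     input_dim = input_dim, n_classes = NA_integer_,
                     W_out = NULL, b_out = NULL, recon_loss = NULL,
                     loss_mode = dbn_loss_mode),
                class = "dbn_params")
    })
  }
  last_h <- dbn_sizes[length(dbn_sizes)]
  ro <- with_local_seed(if (is.null(seed)) NULL else seed + 4L,
                        list(W = unif_init(n_classes, last_h), b = unif_init(n_classes)))
  dbn$W_out <- ro$W
  dbn$b_out <- ro$b
  dbn$n_classes <- as.integer(n_classes)
  dbn$input_dim <- as.integer(input_dim)

  encoding_map <- list(
    list(clf = "lstm", field = "W_out", dim = dim(lstm$W_out)),
    list(clf = "lstm", field = "b_out", dim = length(lstm$b_out)),
    list(clf = "dbn", field = "W_out", dim = dim(dbn$W_out)),
    list(clf = "dbn", field = "b_out", dim = length(dbn$b_out)),
    list(clf = "rnn", field = "R", dim = dim(rnn$R)),
    list(clf = "rnn", field = "b_out", dim = length(rnn$b_out))
  )
  structure(list(lstm = lstm, rnn = rnn, dbn = dbn,
                 input_dim = as.integer(input_dim), n_classes = as.integer(n_classes),
                 seq_steps = as.integer(seq_steps), encoding_map = encoding_map,
                 bounds = bounds, dbn_loss_mode = dbn_loss_mode),
            class = "tri_classifier_params")
}

# Fold an n x d feature matrix into an n x seq_steps x step_dim array
# (zero-padded) for the recurrent classifiers.
fold_sequence <- function(X, seq_steps) {
  n <- nrow(X); d <- ncol(X)
  step_dim <- ceiling(d / seq_steps)
  pad <- seq_steps * step_dim - d
  if (pad > 0) X <- cbind(X, matrix(0, n, pad))
  arr <- array(0, dim = c(n, seq_steps, step_dim))
  for (t in seq_len(seq_steps)) {
    arr[, t, ] <- X[, ((t - 1) * step_dim + 1):(t * step_dim), drop = FALSE]
  }
  arr
}

ensemble_predict_batch <- function(X, params) {
  arr <- fold_sequence(X, params$seq_steps)
  p_lstm <- lstm_forward_batch(arr, params$lstm)
  p_rnn <- rnn_forward_batch(arr, params$rnn)
  p_dbn <- dbn_forward_batch(X, params$dbn)
  fused <- (p_lstm + p_rnn + p_dbn) / 3
  list(lstm = p_lstm, rnn = p_rnn, dbn = p_dbn, fused = fused,
       label = max.col(fused, ties.method = "first") - 1L)
}

#' Averaging-fusion ensemble prediction
#'
#' Runs all three classifiers on one feature vector and averages their class
#' probabilities; the label is the fused argmax, ties broken toward the lower
#' class index.
#'
#' @param features Numeric feature vector (already normalised as at training).
#' @param params A [tri_classifier_params()] bundle.
#' @param dbn_loss_mode Recorded training-monitoring mode (does not affect
#'   inference); defaults to the bundle's own.
#' @return A `prediction_result` list: `lstm`, `rnn`, `dbn`, `fused`
#'   probability vectors and integer `label` (0-based).
#' @export
ensemble_predict <- function(features, params, dbn_loss_mode = params$dbn_loss_mode) {
  if (length(features) != params$input_dim) abort("feature length does not match params")
  res <- tryCatch(
    ensemble_predict_batch(matrix(features, nrow = 1), params),
    error = function(e) abort(paste0("ensemble classifier failure: ", conditionMessage(e)))
  )
  structure(list(lstm = drop(res$lstm), rnn = drop(res$rnn), dbn = drop(res$dbn),
                 fused = drop(res$fused), label = res$label,
                 dbn_loss_mode = dbn_loss_mode),
            class = "prediction_result")
}

#' Flatten / restore the optimizer-tuned weights
#'
#' The solution vector concatenates the tuned tensors in the order declared by
#' the bundle's `encoding_map` (LSTM readout, DBN readout, RNN readout);
#' matrices are flattened column-major. `decode_solution()` is the exact
#' inverse on the tuned subset; out-of-bounds entries are clipped to the
#' declared bounds and flagged via attribute `"clipped"`.
#'
#' @param params,template A [tri_classifier_params()] bundle.
#' @param vec Numeric vector of length `sum(tuned tensor sizes)`.
#' @return `encode_solution()`: numeric vector; `decode_solution()`: a bundle.
#' @export
encode_solution <- function(params) {
  unlist(lapply(params$encoding_map, function(m) {
    as.numeric(params[[m$clf]][[m$field]])
  }))
}

#' @rdname encode_solution
#' @export
decode_solution <- function(vec, template) {
  sizes <- vapply(template$encoding_map, function(m) prod(m$dim), numeric(1))
  if (length(vec) != sum(sizes)) {
    abort(sprintf("solution length %d does not match encoding (%d)", length(vec), sum(sizes)))
  }
  clipped <- any(vec < template$bounds[1] | vec > template$bounds[2])
  vec <- clip(vec, template$bounds[1], template$bounds[2])
  out <- template
  at <- 0
  for (m in template$encoding_map) {
    k <- prod(m$dim)
    chunk <- vec[(at + 1):(at + k)]
    out[[m$clf]][[m$field]] <- if (length(m$dim) == 2) {
      matrix(chunk, m$dim[1], m$dim[2])
    } else {
      chunk
    }
    at <- at + k
  }
  attr(out, "clipped") <- clipped
  out
}
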