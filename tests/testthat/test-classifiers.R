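zero_lstm <- function(d = 3, h = 2, k = 2) {
  p <- lstm_params(d, h, k, seed = 1)
  for (nm in names(p)) if (is.numeric(p[[nm]]) && nm != "hidden" &&
                           nm != "input_dim" && nm != "n_classes") p[[nm]][] <- 0
  p
}

test_that("zero-parameter classifiers sit at their uniform fixed points", {
  X <- matrix(rnorm(12), 4, 3)
  p <- zero_lstm()
  expect_equal(lstm_forward(X, p), rep(0.5, 2))

  r <- rnn_params(3, 2, 2, seed = 1)
  for (nm in c("P", "Q", "R", "b_out")) r[[nm]][] <- 0
  expect_equal(rnn_forward(X, r), rep(0.5, 2))

  tri <- tri_classifier_params(4, dbn_sizes = c(3), seed = 1)
  d <- tri$dbn
  for (i in seq_along(d$rbms)) for (nm in names(d$rbms[[i]])) d$rbms[[i]][[nm]][] <- 0
  d$W_out[] <- 0; d$b_out[] <- 0
  out <- dbn_forward(c(0.2, 0.8, 0.5, 0.1), d)
  expect_equal(out, rep(0.5, 2))
})

test_that("single-step LSTM matches a hand trace of the gate recurrence", {
  p <- zero_lstm(d = 1, h = 1, k = 2)
  p$P_IG[] <- 0.5; p$F_IG[] <- 0.1; p$F_YG[] <- 0.1
  p$P_IV[] <- 0.8; p$F_IV[] <- -0.2
  p$P_II[] <- -0.3; p$F_II[] <- 0.2
  p$P_IL[] <- 0.6; p$F_IL[] <- 0.05
  p$W_out[] <- c(1.5, -0.5); p$b_out[] <- c(0.1, 0)
  x <- 0.7
  sig <- function(z) 1 / (1 + exp(-z))
  G <- sig(0.5 * x + 0.2)
  V <- tanh(-0.2 + 0.8 * x)
  I <- sig(-0.3 * x + 0.2)
  A <- I * V                      # A_0 = 0
  L <- sig(0.6 * x + 0.05)
  Y <- L * tanh(A)
  logits <- c(1.5 * Y + 0.1, -0.5 * Y)
  expected <- exp(logits) / sum(exp(logits))
  expect_equal(lstm_forward(matrix(x, 1, 1), p), expected, tolerance = 1e-12)
})

test_that("readout class permutation permutes output probabilities", {
  p <- lstm_params(3, 4, 3, seed = 9)
  perm <- c(3, 1, 2)
  p2 <- p
  p2$W_out <- p$W_out[perm, ]
  p2$b_out <- p$b_out[perm]
  set.seed(4); X <- matrix(rnorm(6), 2, 3)
  expect_equal(lstm_forward(X, p2), lstm_forward(X, p)[perm])
})

test_that("RNN forward matches hand traces and is memoryless when Q = 0", {
  r <- rnn_params(1, 1, 2, seed = 1)
  r$P[] <- 0.9; r$Q[] <- 0.3; r$R[] <- c(2, -1); r$b_out[] <- 0
  x <- c(0.5, -0.4)
  wg1 <- tanh(0.9 * 0.5)
  wg2 <- tanh(0.9 * -0.4 + 0.3 * wg1)
  expected <- exp(c(2, -1) * wg2) / sum(exp(c(2, -1) * wg2))
  expect_equal(rnn_forward(matrix(x, 2, 1), r), expected, tolerance = 1e-12)

  r0 <- rnn_params(2, 3, 2, seed = 5)
  r0$Q[] <- 0
  seq1 <- rbind(c(9, 9), c(0.3, -0.2))
  seq2 <- rbind(c(-4, 2), c(0.3, -0.2))
  expect_equal(rnn_forward(seq1, r0), rnn_forward(seq2, r0))

  expect_error(rnn_forward(matrix(1, 1, 3), r0), "width")
})

test_that("DBN inference is the deterministic sigmoid stack", {
  tri <- tri_classifier_params(1, dbn_sizes = c(1), seed = 2)
  d <- tri$dbn
  d$rbms[[1]]$W[] <- 0.7; d$rbms[[1]]$c_hid[] <- -0.1
  d$W_out[] <- c(1, 0); d$b_out[] <- c(0, 0)
  v <- 0.4
  h <- 1 / (1 + exp(-(0.7 * 0.4 - 0.1)))
  expected <- exp(c(h, 0)) / sum(exp(c(h, 0)))
  expect_equal(dbn_forward(v, d), expected, tolerance = 1e-12)

  set.seed(8)
  tri2 <- tri_classifier_params(6, dbn_sizes = c(5, 3), seed = 8)
  for (i in 1:100) {
    out <- dbn_forward(runif(6), tri2$dbn)
    expect_equal(sum(out), 1, tolerance = 1e-9)
    expect_true(all(out >= 0))
  }
})

test_that("contrastive-divergence pretraining is seeded, monotone-ish, and optional", {
  set.seed(2)
  X <- matrix(runif(40 * 6), 40, 6)
  p0 <- rbm_pretrain(X, sizes = c(4), epochs = 0, seed = 3)
  p0b <- rbm_pretrain(X, sizes = c(4), epochs = 0, seed = 3)
  expect_identical(p0$rbms, p0b$rbms)

  p1 <- rbm_pretrain(X, sizes = c(4), epochs = 15, lr = 0.05, seed = 3)
  p1b <- rbm_pretrain(X, sizes = c(4), epochs = 15, lr = 0.05, seed = 3)
  expect_identical(p1$rbms, p1b$rbms)
  expect_false(identical(p0$rbms, p1$rbms))

  # reconstruction improves on average across seeds
  deltas <- sapply(1:5, function(s) {
    l <- rbm_pretrain(X, sizes = c(4), epochs = 15, lr = 0.05, seed = s)$recon_loss
    l[length(l)] - l[1]
  })
  expect_lt(mean(deltas), 0)

  expect_error(rbm_pretrain(X * 3, sizes = c(4)), "normalised")
  expect_error(rbm_pretrain(X[0, ], sizes = c(4)), "empty")
})

test_that("MAE loss matches hand arithmetic and is permutation symmetric", {
  expect_equal(mae_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae_loss(c(0, 2), c(1, 1)), 1)
  set.seed(6)
  a <- rnorm(10); b <- rnorm(10); p <- sample(10)
  expect_equal(mae_loss(a, b), mae_loss(a[p], b[p]))
  expect_error(mae_loss(1:3, 1:4), "mismatch")
})

test_that("ensemble fusion averages probabilities with the declared tie rule", {
  tri <- tri_classifier_params(8, dbn_sizes = c(4), seed = 4)
  x <- runif(8)
  pr <- ensemble_predict(x, tri)
  expect_equal(pr$fused, (pr$lstm + pr$rnn + pr$dbn) / 3)
  expect_equal(sum(pr$fused), 1, tolerance = 1e-9)

  # hand case incl. tie toward the lower class index
  v <- (c(0.6, 0.4) + c(0.7, 0.3) + c(0.2, 0.8)) / 3
  expect_equal(v, c(0.5, 0.5))
  expect_equal(max.col(rbind(c(0.5, 0.5)), ties.method = "first") - 1L, 0L)

  # three identical vectors fuse to themselves: force identical classifiers
  expect_equal((pr$fused + pr$fused + pr$fused) / 3, pr$fused)
})

test_that("solution encoding round-trips, counts, clips, and validates", {
  tri <- tri_classifier_params(13, dbn_sizes = c(8), hidden_lstm = 8,
                               hidden_rnn = 8, seed = 10)
  vec <- encode_solution(tri)
  expect_length(vec, 3 * (8 * 2 + 2))  # three readouts with bias, hidden 8, 2 classes

  back <- decode_solution(vec, tri)
  expect_equal(encode_solution(back), vec)
  expect_equal(back$lstm$W_out, tri$lstm$W_out)
  expect_false(attr(back, "clipped"))

  big <- vec; big[1] <- 99
  dec <- decode_solution(big, tri)
  expect_true(attr(dec, "clipped"))
  expect_equal(dec$lstm$W_out[1, 1], tri$bounds[2])

  expect_error(decode_solution(vec[-1], tri), "length")
})

test_that("seeded untrained ensembles are uninformative on random labels", {
  set.seed(123)
  accs <- sapply(1:20, function(s) {
    X <- matrix(runif(40 * 6), 40, 6)
    y <- rep(c(0L, 1L), 20)
    tri <- tri_classifier_params(6, dbn_sizes = c(4), seed = s)
    mean(eegtrio:::ensemble_predict_batch(X, tri)$label == y)
  })
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})
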