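normalize_minmax <- function(X, ranges = NULL) {
  X <- as.matrix(X)
  if (is.null(ranges)) {
    lo <- apply(X, 2, min)
    hi <- apply(X, 2, max)
    ranges <- list(lo = lo, hi = hi)
  }
  span <- ranges$hi - ranges$lo
  span[span == 0] <- 1
  Xn <- sweep(sweep(X, 2, ranges$lo, `-`), 2, span, `/`)
  list(X = clip(Xn, 0, 1), ranges = ranges)
}

stratified_split <- function(labels, train_frac = 0.7, seed = NULL) {
  with_local_seed(seed, {
    train_idx <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      k <- max(1, round(length(idx) * train_frac))
      train_idx <- c(train_idx, sample(idx, k))
    }
    train_idx <- sort(train_idx)
    list(train = train_idx, val = setdiff(seq_along(labels), train_idx))
  })
}

#' Train the tri-classifier ensemble with metaheuristic weight tuning
#'
#' Features are min-max normalised, split into stratified train/validation
#' parts, the classifier bundle is initialised (DBN weights by
#' contrastive-divergence pretraining on the training part), and the readout
#' weights are tuned by SSU-BES (or plain BES) minimising the
#' reciprocal-accuracy objective on the validation part. With
#' `optimizer = "none"` the seeded initial bundle is evaluated as-is — the
#' no-optimization ablation arm.
#'
#' @param features Feature tibble from [extract_feature_matrix()] (columns
#'   `.trial`, `.label`, features), or a plain matrix plus `labels`.
#' @param labels Binary labels; taken from `features$.label` when omitted.
#' @param optimizer `"ssu-bes"`, `"bes"`, or `"none"`.
#' @param seed Global seed; fanned out to deterministic per-stage seeds.
#' @param train_frac Training fraction of the stratified split.
#' @param pop,iters Optimizer population and iteration budget.
#' @param bounds Bounds on tuned weights.
#' @param hidden_lstm,hidden_rnn,dbn_sizes,seq_steps Architecture knobs, see
#'   [tri_classifier_params()].
#' @param dbn_loss_mode `"mae"` (improved DBN) or `"squared"` pretraining
#'   monitoring.
#' @param cd_epochs,cd_lr Contrastive-divergence schedule.
#' @return A `tri_fit` object: tuned `params`, `optim` result (NULL when not
#'   optimized), validation `metrics` (one-row tibble), `accuracy`, `split`,
#'   normalisation `ranges`, and the call configuration.
#' @export
train_tri_classifier <- function(features, labels = NULL,
                                 optimizer = c("ssu-bes", "bes", "none"),
                                 seed = 1L, train_frac = 0.7,
                                 pop = 10L, iters = 25L, bounds = c(-1, 1),
                                 hidden_lstm = 8L, hidden_rnn = 8L,
                                 dbn_sizes = c(32L, 16L), seq_steps = 4L,
                                 dbn_loss_mode = c("mae", "squared"),
                                 cd_epochs = 10L, cd_lr = 0.05) {
  optimizer <- match.arg(optimizer)
  dbn_loss_mode <- match.arg(dbn_loss_mode)
  if (is.null(labels)) {
    if (is.data.frame(features) && ".label" %in% names(features)) {
      labels <- features$.label
    } else {
      abort("labels must be supplied when features carry no .label column")
    }
  }
  X <- if (is.data.frame(features)) feature_values(features) else as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(X) != length(labels)) abort("one label per feature row required")

  split <- stratified_split(labels, train_frac, seed = split_seed(seed, "split"))
  norm <- normalize_minmax(X[split$train, , drop = FALSE])
  X_train <- norm$X
  X_val <- normalize_minmax(X[split$val, , drop = FALSE], norm$ranges)$X
  y_val <- labels[split$val]

  template <- tri_classifier_params(
    input_dim = ncol(X), hidden_lstm = hidden_lstm, hidden_rnn = hidden_rnn,
    dbn_sizes = dbn_sizes, seq_steps = seq_steps,
    seed = split_seed(seed, "init"), train_data = X_train,
    dbn_loss_mode = dbn_loss_mode, bounds = bounds,
    cd_epochs = cd_epochs, cd_lr = cd_lr
  )

  obj <- tri_objective(X_val, y_val, template)
  optim_res <- NULL
  params <- template
  if (optimizer != "none") {
    cfg <- ssu_bes_config(dim = length(encode_solution(template)), pop = pop,
                          iters = iters, bounds = bounds,
                          seed = split_seed(seed, "optimizer"))
    optim_res <- if (optimizer == "ssu-bes") run_ssu_bes(obj, cfg) else run_bes(obj, cfg)
    params <- decode_solution(optim_res$best, template)
  }

  pred <- ensemble_predict_batch(X_val, params)$label
  metrics <- metrics_report(confusion(y_val, pred))

  structure(list(params = params, optim = optim_res, metrics = metrics,
                 accuracy = metrics$accuracy, split = split, ranges = norm$ranges,
                 optimizer = optimizer, seed = seed,
                 config = list(train_frac = train_frac, pop = pop, iters = iters,
                               bounds = bounds, dbn_loss_mode = dbn_loss_mode,
                               hidden_lstm = hidden_lstm, hidden_rnn = hidden_rnn,
                               dbn_sizes = dbn_sizes, seq_steps = seq_steps)),
            class = "tri_fit")
}

#' @export
print.tri_fit <- function(x, ...) {
  cat(sprintf("<tri_fit> optimizer=%s, validation accuracy %.3f (n=%d)\n",
              x$optimizer, x$accuracy, length(x$split$val)))
  invisible(x)
}

#' Predict with a fitted tri-classifier ensemble
#'
#' @param object A `tri_fit`.
#' @param newdata Feature tibble (as from [extract_feature_matrix()]) or
#'   numeric matrix; normalised with the training ranges.
#' @param ... Unused.
#' @return Tibble with fused class probabilities (`.prob_0`, `.prob_1`) and
#'   `.pred_label`.
#' @export
predict.tri_fit <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) feature_values(newdata) else as.matrix(newdata)
  Xn <- normalize_minmax(X, object$ranges)$X
  res <- ensemble_predict_batch(Xn, object$params)
  tibble::tibble(.prob_0 = res$fused[, 1], .prob_1 = res$fused[, 2],
                 .pred_label = res$label)
}

valid_keys <- list(
  top = c("seed", "target", "train_frac", "simulate", "input", "features",
          "train", "out_dir"),
  simulate = c("n_trials", "n_channels", "fs", "trial_len_s", "effect_size",
               "noise_exponent", "amplitude", "line_noise_hz"),
  input = c("path", "format", "fs", "trial_len_s", "baseline_s", "labels",
            "low_hz", "high_hz", "order"),
  features = c("wavelet_name", "levels", "stats", "n_bins", "w0", "entropy_mode"),
  train = c("optimizer", "pop", "iters", "bounds", "hidden_lstm", "hidden_rnn",
            "dbn_sizes", "seq_steps", "dbn_loss_mode", "cd_epochs", "cd_lr")
)

check_keys <- function(x, section) {
  bad <- setdiff(names(x), valid_keys[[section]])
  if (length(bad)) {
    abort(sprintf("unknown %s config key(s): %s", section, paste(bad, collapse = ", ")))
  }
  x
}

#' Validated end-to-end pipeline configuration
#'
#' Either a `simulate` section (arguments of [generate_epochs()]) or an
#' `input` section (path + [load_recording()]/[segment_epochs()] arguments)
#' must provide the epochs. Unknown keys in any section are rejected before
#' computation.
#'
#' @param seed Global seed fanned out to per-stage seeds.
#' @param target Label name the binary outcome represents (`"valence"` or
#'   `"arousal"`; bookkeeping only).
#' @param train_frac Stratified train fraction.
#' @param simulate,input,features,train Named lists of section parameters.
#' @param out_dir Optional run directory for persisted artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, target = c("valence", "arousal"),
                            train_frac = 0.7, simulate = NULL, input = NULL,
                            features = list(), train = list(), out_dir = NULL) {
  target <- match.arg(target)
  if (is.null(simulate) && is.null(input)) abort("one of `simulate` or `input` is required")
  if (!is.null(simulate) && !is.null(input)) abort("give either `simulate` or `input`, not both")
  if (!is.null(simulate)) check_keys(simulate, "simulate")
  if (!is.null(input)) {
    check_keys(input, "input")
    if (is.null(input$path)) abort("input section needs a `path`")
    if (!file.exists(input$path)) abort(paste0("input path does not exist: ", input$path))
  }
  check_keys(features, "features")
  check_keys(train, "train")
  if (!(train_frac > 0 && train_frac < 1)) abort("train_frac must lie in (0, 1)")
  structure(list(seed = as.integer(seed), target = target, train_frac = train_frac,
                 simulate = simulate, input = input, features = features,
                 train = train, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full recognition pipeline
#'
#' Wires epochs (simulated or loaded + band-passed + segmented) through
#' feature extraction, tri-classifier training, and evaluation. Fully
#' reproducible from the config and seed; when `out_dir` is set, the metrics,
#' convergence trace, config snapshot, and model are persisted there.
#'
#' @param cfg A [pipeline_config()].
#' @return List: `fit` (a `tri_fit`), `metrics`, `features`, `epochs`,
#'   `config`, and `out_dir` (NULL unless persisted).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$simulate)) {
    epochs <- do.call(generate_epochs,
                      c(cfg$simulate, list(seed = split_seed(cfg$seed, "data"))))
  } else {
    inp <- cfg$input
    rec <- load_recording(inp$path, format = inp$format %||% "delimited", fs = inp$fs)
    spec <- filter_spec(low_hz = inp$low_hz %||% 0.5, high_hz = inp$high_hz %||% 50,
                        order = inp$order %||% 4L)
    rec <- apply_bandpass(rec, spec)
    labels <- inp$labels %||% rec$labels
    if (is.null(labels)) abort("input section needs trial `labels`")
    epochs <- segment_epochs(rec, inp$trial_len_s, inp$baseline_s %||% 0, labels)
  }

  fe <- cfg$features
  feats <- extract_feature_matrix(
    epochs,
    dwt = dwt_spec(wavelet_name = fe$wavelet_name %||% "db4",
                   levels = fe$levels %||% 4L),
    entropy = entropy_spec(n_bins = fe$n_bins %||% 8L, w0 = fe$w0 %||% 0.7),
    entropy_mode = fe$entropy_mode %||% "improved"
  )

  fit <- do.call(train_tri_classifier,
                 c(list(features = feats, seed = cfg$seed,
                        train_frac = cfg$train_frac), cfg$train))

  out <- list(fit = fit, metrics = fit$metrics, features = feats, epochs = epochs,
              config = cfg, out_dir = NULL)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    hash <- config_hash(unclass(cfg))
    write_stamped <- function(df, file) {
      con <- file(file.path(cfg$out_dir, file), "w")
      on.exit(close(con))
      writeLines(sprintf("# config_hash: %s", hash), con)
      utils::write.csv(df, con, row.names = FALSE)
    }
    write_stamped(fit$metrics, "metrics.csv")
    if (!is.null(fit$optim)) write_stamped(fit$optim$trace, "trace.csv")
    snapshot <- utils::capture.output(utils::str(unclass(cfg), give.attr = FALSE))
    writeLines(c(sprintf("config_hash: %s", hash), snapshot),
               file.path(cfg$out_dir, "config.txt"))
    saveRDS(fit, file.path(cfg$out_dir, "model.rds"))
    out$out_dir <- cfg$out_dir
  }
  out
}
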