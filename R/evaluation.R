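#' Binary confusion matrix
#'
#' Class 1 is the positive class.
#'
#' @param labels,predictions Equal-length binary (0/1) vectors.
#' @return A `confusion_matrix` list with counts `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) abort("labels and predictions differ in length")
  if (length(labels) < 1) abort("need at least one observation")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (!all(c(labels, predictions) %in% c(0L, 1L))) abort("labels and predictions must be binary")
  structure(list(TP = sum(labels == 1 & predictions == 1),
                 FP = sum(labels == 0 & predictions == 1),
                 TN = sum(labels == 0 & predictions == 0),
                 FN = sum(labels == 1 & predictions == 0)),
            class = "confusion_matrix")
}

# 0/0 ratios resolve to 0 by convention (documented; degenerate predictions).
safe_div <- function(num, den) if (den == 0) 0 else num / den

#' F1 score from precision and sensitivity
#'
#' Harmonic mean, 0 when both are 0.
#'
#' @param precision,sensitivity Values in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Eleven-metric evaluation report
#'
#' Accuracy, sensitivity, specificity, precision, NPV, F1, MCC, FPR, FNR,
#' FDR, FOR from a binary confusion matrix. The complement identities
#' (sensitivity + FNR = 1, specificity + FPR = 1, precision + FDR = 1,
#' NPV + FOR = 1) hold exactly; 0/0 ratios resolve to 0 by convention.
#'
#' @param cm A [confusion()] result.
#' @return One-row tibble with the 11 metrics.
#' @export
metrics_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$TP; fp <- cm$FP; tn <- cm$TN; fn <- cm$FN
  total <- tp + fp + tn + fn
  if (total == 0) abort("empty confusion matrix")
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  mcc_den <- sqrt(as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (as.double(tp) * tn - as.double(fp) * fn) / mcc_den
  tibble::tibble(
    accuracy = (tp + tn) / total,
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    npv = npv,
    f1 = f1_score(prec, sens),
    mcc = mcc,
    fpr = 1 - spec,
    fnr = 1 - sens,
    fdr = 1 - prec,
    for_ = 1 - npv
  )
}

#' Multi-run statistical summary
#'
#' Mean, sample standard deviation, sample variance, best (max) and worst
#' (min) of a metric across repeated runs — the summary used for stochastic
#' optimizers.
#'
#' @param values Numeric vector of per-run metric values (length >= 2).
#' @return One-row tibble `mean`, `std`, `variance`, `best`, `worst`.
#' @export
statistical_summary <- function(values) {
  if (length(values) < 2) abort("need at least two runs to summarise")
  tibble::tibble(mean = mean(values), std = sd(values), variance = var(values),
                 best = max(values), worst = min(values))
}

#' Published comparison-table metrics
#'
#' The 11-metric classifier comparison values for the valence and arousal
#' cases as published for the method this package implements, bundled as a
#' plain-text fixture. Used by the metric-identity checks (e.g.
#' `sensitivity + FNR = 1`, `F1 =` harmonic mean of precision and
#' sensitivity) that validate this package's metric definitions against the
#' printed cells.
#'
#' @return Tibble with columns `case`, `method`, `metric`, `value`.
#' @export
reference_classifier_metrics <- function() {
  path <- system.file("extdata", "reference_classifier_metrics.csv", package = "eegtrio")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Ablation study over pipeline variants
#'
#' Evaluates configuration variants (improved vs conventional entropy,
#' MAE vs squared DBN reconstruction monitoring, SSU-BES vs no optimization)
#' on one shared stratified train/validation split and seed, one metrics row
#' per variant.
#'
#' @param epochs An [epoch_set()].
#' @param variants Data frame with columns `entropy`, `dbn_loss`, `optimizer`
#'   (defaults to the four headline variants).
#' @param seed Shared seed.
#' @param train_frac Training fraction of the split.
#' @param ... Passed to [train_tri_classifier()] (e.g. `pop`, `iters`).
#' @return Tibble: variant columns followed by the 11 metrics.
#' @export
run_ablation <- function(epochs, variants = NULL, seed = 1L, train_frac = 0.7, ...) {
  if (is.null(variants)) {
    variants <- tibble::tribble(
      ~entropy, ~dbn_loss, ~optimizer,
      "improved", "mae", "ssu-bes",
      "conventional", "mae", "ssu-bes",
      "improved", "squared", "ssu-bes",
      "improved", "mae", "none"
    )
  }
  rows <- purrr::pmap(variants, function(entropy, dbn_loss, optimizer, ...) {
    label <- sprintf("entropy=%s dbn_loss=%s optimizer=%s", entropy, dbn_loss, optimizer)
    tryCatch({
      feats <- extract_feature_matrix(epochs, entropy_mode = entropy)
      fit <- train_tri_classifier(feats, optimizer = optimizer, seed = seed,
                                  train_frac = train_frac, dbn_loss_mode = dbn_loss, ...)
      fit$metrics
    }, error = function(e) {
      abort(sprintf("ablation variant [%s] failed: %s", label, conditionMessage(e)))
    })
  })
  dplyr::bind_cols(tibble::as_tibble(variants), dplyr::bind_rows(rows))
}
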