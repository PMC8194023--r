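# Evaluation protocols: training error (MAE% on normalized outputs),
# therapy classification metrics, therapy-time RMS, the beta_int sweep,
# topology comparison, and first-layer parameter-hierarchy ranking.

#' Training error in percent
#'
#' Mean absolute error over samples and the two normalized outputs, times
#' 100. This is the reported "training error" metric; the optimization loss
#' itself remains the MSE.
#'
#' @param model a trained `lonn_model`.
#' @param X,Y normalized input and outcome matrices.
#' @return percent in \[0, 100\].
#' @export
training_error <- function(model, X, Y) {
  if (!is.matrix(X) || nrow(X) == 0L) stop("empty evaluation data")
  mean(abs(predict(model, X) - Y)) * 100
}

#' Therapy classification metrics
#'
#' Standard confusion-matrix accuracy, precision and recall on the positive
#' treatment-key class at the given threshold, in percent. Precision is
#' `NA` (absent, not zero) when no positive predictions exist; recall is
#' `NA` when no positive labels exist.
#'
#' @param tk_probs predicted treatment-key probabilities.
#' @param tk_labels binary labels of equal length.
#' @param threshold binarization threshold, default 0.5.
#' @return named numeric vector `c(accuracy, precision, recall)` in percent.
#' @export
classification_metrics <- function(tk_probs, tk_labels, threshold = 0.5) {
  if (length(tk_probs) != length(tk_labels))
    stop("prediction/label length mismatch", call. = FALSE)
  if (!length(tk_probs)) stop("empty evaluation data")
  if (!all(tk_labels %in% c(0, 1))) stop("labels must be binary")
  pred <- as.integer(tk_probs >= threshold)
  tp <- sum(pred == 1 & tk_labels == 1)
  fp <- sum(pred == 1 & tk_labels == 0)
  fn <- sum(pred == 0 & tk_labels == 1)
  tn <- sum(pred == 0 & tk_labels == 0)
  c(accuracy = 100 * (tp + tn) / length(pred),
    precision = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn))
}

#' Therapy-time RMS error in percent
#'
#' `sqrt(mean((pred - label)^2)) * 100` on the normalized time scale.
#'
#' @param time_pred_norm,time_label_norm normalized times in \[0, 1\].
#' @return percent.
#' @export
time_rms <- function(time_pred_norm, time_label_norm) {
  if (!length(time_pred_norm)) stop("empty evaluation data")
  if (length(time_pred_norm) != length(time_label_norm))
    stop("prediction/label length mismatch", call. = FALSE)
  sqrt(mean((time_pred_norm - time_label_norm)^2)) * 100
}

.metrics_report <- function(model, enc_train, enc_test) {
  pred <- predict(model, enc_test$X)
  cm <- classification_metrics(pred[, 2L], enc_test$Y[, 2L])
  c(training_error_pct = training_error(model, enc_train$X, enc_train$Y),
    therapy_accuracy_pct = cm[["accuracy"]],
    precision_pct = cm[["precision"]],
    recall_pct = cm[["recall"]],
    time_rms_pct = time_rms(pred[, 1L], enc_test$Y[, 1L]))
}

#' Sweep the logic-layer slope beta_int
#'
#' Builds and trains a fresh default-topology LONN for every (beta, seed)
#' pair on an 80/20 split of the cohort and reports the per-beta mean
#' training error after `epochs` epochs (the protocol behind the
#' flat-training-error observation: the slope has little influence on the
#' final error).
#'
#' @param cohort a cohort `data.frame`.
#' @param beta_values nonzero slopes to test (both signs allowed).
#' @param epochs training epochs per run, default 50.
#' @param seeds integer vector of replicate seeds.
#' @param config base [train_config()]; its epoch count is overridden.
#' @param train_fraction split fraction.
#' @return `data.frame` with one row per beta: `beta`,
#'   `mean_training_error_pct`, `sd_training_error_pct`, `n_runs`.
#' @export
beta_sweep <- function(cohort, beta_values, epochs = 50L, seeds = 1L,
                       config = train_config(), train_fraction = 0.8) {
  if (any(beta_values == 0))
    stop("beta values must be nonzero", call. = FALSE)
  config$epochs <- as.integer(epochs)
  rows <- lapply(beta_values, function(beta) {
    errs <- vapply(seeds, function(seed) {
      split <- split_train_test(cohort, train_fraction, seed = seed)
      enc <- encode_and_normalize(split$train)
      spec <- lonn_spec(beta_int = beta, seed = seed)
      cfg <- config
      cfg$shuffle_seed <- as.integer(seed)
      fit <- train_network(build_lonn(spec), enc$X, enc$Y, cfg)
      training_error(fit$model, enc$X, enc$Y)
    }, numeric(1))
    data.frame(beta = beta, mean_training_error_pct = mean(errs),
               sd_training_error_pct = if (length(errs) > 1) stats::sd(errs)
                 else NA_real_,
               n_runs = length(errs))
  })
  do.call(rbind, rows)
}

#' Compare network topologies on one cohort
#'
#' Trains each candidate on the same split and seeds and reports the
#' metric table (training error, therapy accuracy / precision / recall on
#' the held-out part, therapy-time RMS). The default candidates are the
#' dense ReLU baseline, the reference LONN with 4 M-nodes, and a widened
#' LONN with 10 M-nodes (AND/OR stages widened proportionally to 8 and 5).
#'
#' @param cohort a cohort `data.frame`.
#' @param specs named list; each element either the string `"dense"` or a
#'   [lonn_spec()]. `NULL` selects the default trio.
#' @param config a [train_config()].
#' @param seed split/initialization seed shared by all candidates.
#' @param train_fraction split fraction.
#' @return `data.frame`, one row per candidate.
#' @export
compare_models <- function(cohort, specs = NULL, config = train_config(),
                           seed = 1L, train_fraction = 0.8) {
  if (is.null(specs)) {
    specs <- list(
      dense = "dense",
      lonn_a = lonn_spec(seed = seed),
      lonn_b = lonn_spec(m_layer_width = 10L, and_layer_width = 8L,
                         or_stage_width = 5L, seed = seed)
    )
  }
  split <- split_train_test(cohort, train_fraction, seed = seed)
  enc_train <- encode_and_normalize(split$train)
  enc_test <- encode_and_normalize(split$test, spec = enc_train$spec)
  cfg <- config
  cfg$shuffle_seed <- as.integer(seed)
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    model <- if (identical(sp, "dense"))
      build_dense_baseline(ncol(enc_train$X), ncol(enc_train$Y), seed = seed)
    else build_lonn(sp)
    fit <- train_network(model, enc_train$X, enc_train$Y, cfg)
    cp <- count_parameters(fit$model)
    cbind(data.frame(model = nm,
                     trainable_parameters = cp[["trainable"]],
                     frozen_parameters = cp[["non_trainable"]]),
          as.data.frame(as.list(.metrics_report(fit$model, enc_train,
                                                enc_test))))
  })
  out <- do.call(rbind, rows)
  out$n_train <- nrow(split$train)
  out$n_test <- nrow(split$test)
  out
}

#' First-layer parameter hierarchy
#'
#' Importance of input j is the column sum of absolute weights of the first
#' trainable layer, normalized to sum 1 — because the deeper logic layers
#' are frozen, this ranking is the network's interpretable parameter
#' hierarchy. Ties break stably by column order.
#'
#' @param model a trained `lonn_model`.
#' @return `data.frame` of `variable` and `importance` (summing to 1),
#'   sorted by decreasing importance.
#' @export
input_importance <- function(model) {
  if (!inherits(model, "lonn_model")) stop("'model' must be a lonn_model")
  first <- NULL
  for (layer in model$layers) if (layer$trainable) { first <- layer; break }
  if (is.null(first)) stop("model has no trainable first layer",
                           call. = FALSE)
  imp <- colSums(abs(first$W))
  if (sum(imp) == 0) stop("first-layer weights are all zero (untrained?)",
                          call. = FALSE)
  imp <- imp / sum(imp)
  vars <- model$input_names %||% paste0("V", seq_along(imp))
  ord <- order(-imp)
  data.frame(variable = vars[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
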