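# Dual-model recommendation: one network trained on the whole cohort
# (model_full, "Model 1"), one on the positive-outcome subset
# (model_positive, "Model 2"); agreement of the binarized treatment keys
# yields a binary confidence flag.

#' Train the recommender pair
#'
#' Fits the normalization once on the full cohort and shares it; trains
#' `model_full` on every record and `model_positive` on the
#' [filter_positive()] subset (survivors with long therapy times). Both
#' models are built from the same [lonn_spec()], so their frozen logic
#' layers are identical.
#'
#' @param cohort a cohort `data.frame` carrying a `death` flag.
#' @param spec a [lonn_spec()] shared by both models.
#' @param config a [train_config()].
#' @param min_time_days threshold defining a long therapy (see
#'   [filter_positive()]).
#' @return object of class `recommender_pair`.
#' @export
train_pair <- function(cohort, spec = lonn_spec(), config = train_config(),
                       min_time_days = 60) {
  positive <- filter_positive(cohort, min_time_days)
  if (nrow(positive) == 0L)
    stop("positive-outcome subset is empty; lower 'min_time_days' or check the death flag",
         call. = FALSE)
  enc_full <- encode_and_normalize(cohort)
  enc_pos <- encode_and_normalize(positive, spec = enc_full$spec)
  model_full <- train_network(build_lonn(spec), enc_full$X, enc_full$Y,
                              config)$model
  model_positive <- train_network(build_lonn(spec), enc_pos$X, enc_pos$Y,
                                  config)$model
  model_full$input_names <- colnames(enc_full$X)
  model_positive$input_names <- colnames(enc_full$X)
  structure(
    list(model_full = model_full, model_positive = model_positive,
         norm_spec = enc_full$spec, lonn_spec = spec, config = config,
         min_time_days = min_time_days),
    class = "recommender_pair"
  )
}

.encode_patient <- function(patient, spec) {
  if (!is.data.frame(patient)) patient <- as.data.frame(patient)
  missing <- setdiff(.COHORT_INPUTS, names(patient))
  if (length(missing))
    stop("patient record is missing covariate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- numeric(length(.COHORT_INPUTS))
  names(x) <- .COHORT_INPUTS
  for (col in .COHORT_INPUTS) {
    v <- patient[[col]][1L]
    if (!is.finite(v)) stop(sprintf("covariate '%s' is not finite", col))
    x[col] <- if (col %in% .COHORT_BINARY) v
      else suppressWarnings(.norm_col(v, spec$mins[[col]], spec$maxs[[col]],
                                      col))
  }
  matrix(x, nrow = 1L, dimnames = list(NULL, .COHORT_INPUTS))
}

#' Recommend a therapy for one patient
#'
#' Both models predict (therapy time, treatment-key probability); the
#' treatment keys are binarized at `threshold`. If they agree the
#' recommendation comes from `model_full` with confidence 1; otherwise from
#' `model_positive` with confidence 0 and the full model's prediction
#' attached as the alternative. Predicted time is mapped back to days with
#' the shared normalization.
#'
#' @param pair a [train_pair()] result.
#' @param patient one-row `data.frame` (or named list) with all ten
#'   covariates; an `id` field is carried through if present.
#' @param threshold binarization threshold for the treatment-key output.
#' @param time_tolerance_days optional: when given, agreement additionally
#'   requires the two predicted times to differ by at most this many days
#'   (off by default).
#' @return object of class `recommendation` with fields `patient_id`,
#'   `treatment_key`, `therapy_time_days`, `confidence` (1/0), `source`
#'   (`"model_full"` or `"model_positive"`) and, when confidence is 0,
#'   `alternative` (the other model's treatment key and time).
#' @export
recommend <- function(pair, patient, threshold = 0.5,
                      time_tolerance_days = NULL) {
  if (!inherits(pair, "recommender_pair"))
    stop("'pair' must come from train_pair()", call. = FALSE)
  x <- .encode_patient(patient, pair$norm_spec)
  p_full <- predict(pair$model_full, x)
  p_pos <- predict(pair$model_positive, x)
  tk_full <- as.integer(p_full[1L, 2L] >= threshold)
  tk_pos <- as.integer(p_pos[1L, 2L] >= threshold)
  t_full <- unname(denormalize_time(pair$norm_spec, p_full[1L, 1L]))
  t_pos <- unname(denormalize_time(pair$norm_spec, p_pos[1L, 1L]))
  match <- tk_full == tk_pos
  if (!is.null(time_tolerance_days))
    match <- match && abs(t_full - t_pos) <= time_tolerance_days
  pid <- if (!is.null(patient$id)) as.character(patient$id[1L])
    else NA_character_
  if (match) {
    rec <- list(patient_id = pid, treatment_key = tk_full,
                therapy_time_days = t_full, confidence = 1L,
                source = "model_full", alternative = NULL)
  } else {
    rec <- list(patient_id = pid, treatment_key = tk_pos,
                therapy_time_days = t_pos, confidence = 0L,
                source = "model_positive",
                alternative = list(treatment_key = tk_full,
                                   therapy_time_days = t_full))
  }
  structure(rec, class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("patient %s: TK=%d, time=%.1f days, confidence=%d (%s)\n",
              x$patient_id %||% "<unknown>", x$treatment_key,
              x$therapy_time_days, x$confidence, x$source))
  if (!is.null(x$alternative))
    cat(sprintf("  alternative: TK=%d, time=%.1f days\n",
                x$alternative$treatment_key,
                x$alternative$therapy_time_days))
  invisible(x)
}

#' Append a recommendation to the log store
#'
#' Appends one timestamped row to an append-only CSV, creating the file
#' (with header) when absent. Whether the physician accepted is recorded if
#' known. An unwritable store raises a warning but the recommendation is
#' still returned to the caller.
#'
#' @param recommendation a [recommend()] result.
#' @param accepted optional logical; `NA` when unknown.
#' @param store_path path of the append-only CSV log.
#' @return the appended record as a one-row `data.frame`, invisibly.
#' @export
log_recommendation <- function(recommendation, accepted = NA,
                               store_path = "recommendations.csv") {
  if (!inherits(recommendation, "recommendation"))
    stop("'recommendation' must come from recommend()", call. = FALSE)
  row <- data.frame(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    patient_id = recommendation$patient_id,
    treatment_key = recommendation$treatment_key,
    therapy_time_days = recommendation$therapy_time_days,
    confidence = recommendation$confidence,
    alt_treatment_key = recommendation$alternative$treatment_key %||%
      NA_integer_,
    alt_therapy_time_days = recommendation$alternative$therapy_time_days %||%
      NA_real_,
    source_model = recommendation$source,
    accepted = if (is.na(accepted)) NA else as.logical(accepted),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(row, store_path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(store_path), append =
                         file.exists(store_path), qmethod = "double")
    TRUE
  }, error = function(e) {
    warning("recommendation log I/O error: ", conditionMessage(e),
            call. = FALSE)
    FALSE
  }, warning = function(w) {
    warning("recommendation log I/O error: ", conditionMessage(w),
            call. = FALSE)
    FALSE
  })
  invisible(row)
}

#' Read a recommendation log back
#'
#' @param store_path path of the append-only CSV log.
#' @return `data.frame` of logged recommendations, in append order.
#' @export
read_recommendation_log <- function(store_path) {
  utils::read.csv(store_path, stringsAsFactors = FALSE)
}
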