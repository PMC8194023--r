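# Sequential-regression synthetic cohort generator (synthpop-style):
# variable-by-variable models in a fixed visit order, norm-rank
# back-transform for continuous variables, and frequency-distribution
# distance diagnostics.

.default_visit_order <- function(cohort) {
  intersect(c(.COHORT_INPUTS, "time", "treatment_key", "death"),
            names(cohort))
}

.is_binary_var <- function(name, values) {
  name %in% .COHORT_BINARY || all(values %in% c(0, 1))
}

#' Fit the sequential-regression synthesizer
#'
#' Visits the variables in order; the first is modeled by its empirical
#' marginal, every later variable by a regression on its predecessors only:
#' logistic regression for binaries, ordinary least squares (with the
#' residual spread and the sorted empirical values retained for norm-rank
#' back-transformation) for continuous variables. Degenerate fits —
#' constant columns, separation, singular designs — fall back to the
#' marginal model for that variable, with a message.
#'
#' @param cohort a non-empty cohort `data.frame` without missing values in
#'   the modeled columns.
#' @param visit_order character vector of column names; defaults to the
#'   schema order (covariates, time, treatment key, death).
#' @return object of class `synthesizer_model`.
#' @export
fit_synthesizer <- function(cohort, visit_order = NULL) {
  if (nrow(cohort) == 0L) stop("cannot fit a synthesizer on an empty cohort")
  if (is.null(visit_order)) visit_order <- .default_visit_order(cohort)
  missing <- setdiff(visit_order, names(cohort))
  if (length(missing))
    stop("visit_order names absent from cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  models <- vector("list", length(visit_order))
  names(models) <- visit_order
  for (k in seq_along(visit_order)) {
    var <- visit_order[k]
    y <- cohort[[var]]
    if (anyNA(y)) stop(sprintf("missing values in modeled column '%s'", var))
    binary <- .is_binary_var(var, y)
    preds <- if (k > 1L) visit_order[seq_len(k - 1L)] else character(0)
    models[[var]] <- .fit_variable(y, cohort, var, preds, binary)
  }
  structure(
    list(visit_order = visit_order, models = models, n = nrow(cohort)),
    class = "synthesizer_model"
  )
}

.fit_variable <- function(y, cohort, var, preds, binary) {
  marginal <- if (binary) {
    list(type = "marginal_binary", p = mean(y == 1), binary = TRUE)
  } else {
    list(type = "marginal_empirical", values = sort(y), binary = FALSE)
  }
  if (length(preds) == 0L || length(unique(y)) == 1L) return(marginal)
  dat <- cohort[, c(var, preds), drop = FALSE]
  fml <- stats::as.formula(paste0("`", var, "` ~ ."))
  if (binary) {
    fit <- tryCatch(
      withCallingHandlers(
        stats::glm(fml, data = dat, family = stats::binomial()),
        warning = function(w) stop(conditionMessage(w), call. = FALSE)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || anyNA(stats::coef(fit))) {
      message(sprintf("synthesizer: marginal fallback for binary '%s'", var))
      return(marginal)
    }
    list(type = "logistic", coef = stats::coef(fit), preds = preds,
         binary = TRUE)
  } else {
    fit <- tryCatch(stats::lm(fml, data = dat), error = function(e) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) {
      message(sprintf("synthesizer: marginal fallback for continuous '%s'",
                      var))
      return(marginal)
    }
    list(type = "linear", coef = stats::coef(fit),
         sigma = summary(fit)$sigma, values = sort(y), preds = preds,
         binary = FALSE)
  }
}

# rank-preserving back-transform onto the empirical marginal
.norm_rank <- function(draws, values) {
  m <- length(draws)
  n <- length(values)
  r <- rank(draws, ties.method = "first")
  if (m == n) sort(values)[r]
  else stats::quantile(values, probs = (r - 0.5) / m, names = FALSE, type = 7)
}

.linpred <- function(coef, df, preds) {
  X <- cbind(1, as.matrix(df[, preds, drop = FALSE]))
  as.numeric(X %*% coef)
}

#' Draw a synthetic cohort
#'
#' Sequentially draws each variable from its fitted predictive
#' distribution: Bernoulli at the fitted probability for logistic models;
#' for linear models a normal predictive draw (mean plus residual-scale
#' noise) that is then mapped onto the original empirical marginal by rank
#' (interpolated empirical quantiles when `m` differs from the fitting
#' size), so synthetic values never leave the observed range. IDs are fresh
#' random `S`-prefixed strings, disjoint from fixture IDs by construction.
#'
#' @param model a fitted [fit_synthesizer()] object.
#' @param m number of synthetic records.
#' @param seed integer seed; the same seed reproduces the same cohort.
#' @return a synthetic cohort `data.frame` over the modeled variables.
#' @export
synthesize <- function(model, m, seed = 1L) {
  if (!inherits(model, "synthesizer_model"))
    stop("'model' must come from fit_synthesizer()", call. = FALSE)
  if (m < 0 || m != round(m)) stop("'m' must be a non-negative integer")
  m <- as.integer(m)
  if (m == 0L) {
    out <- list(id = character(0))
    for (var in model$visit_order) out[[var]] <- numeric(0)
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  set.seed(seed)
  ids <- sprintf("S%07d", sample.int(9999999L, m))
  df <- data.frame(row.names = seq_len(m))
  for (var in model$visit_order) {
    mv <- model$models[[var]]
    df[[var]] <- switch(mv$type,
      marginal_binary = stats::rbinom(m, 1, mv$p),
      marginal_empirical = sample(mv$values, m, replace = TRUE),
      logistic = stats::rbinom(m, 1, stats::plogis(
        .linpred(mv$coef, df, mv$preds))),
      linear = .norm_rank(.linpred(mv$coef, df, mv$preds) +
                            stats::rnorm(m, 0, mv$sigma), mv$values),
      stop("unknown synthesizer model type: ", mv$type)
    )
  }
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), df)
}

#' Frequency-distribution distance between cohorts for one variable
#'
#' Binary variables use the natural bins \{0, 1\}; continuous variables
#' `n_bins` equal-width bins over the pooled range. The distance is the
#' mean over bins of the absolute relative-frequency difference, in
#' percent (0 = identical histograms, 100 = maximal disagreement).
#'
#' @param original,synthetic non-empty cohort `data.frame`s.
#' @param variable column name present in both.
#' @param n_bins number of equal-width bins for continuous variables.
#' @return distance in percent.
#' @export
distribution_distance <- function(original, synthetic, variable,
                                  n_bins = 10L) {
  if (!variable %in% names(original) || !variable %in% names(synthetic))
    stop(sprintf("variable '%s' absent from cohort", variable),
         call. = FALSE)
  if (nrow(original) == 0L || nrow(synthetic) == 0L)
    stop("cohorts must be non-empty", call. = FALSE)
  xo <- original[[variable]]
  xs <- synthetic[[variable]]
  if (.is_binary_var(variable, c(xo, xs))) {
    po <- c(mean(xo == 0), mean(xo == 1))
    ps <- c(mean(xs == 0), mean(xs == 1))
    return(mean(abs(po - ps)) * 100)
  }
  rng <- range(c(xo, xs))
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  fo <- tabulate(findInterval(xo, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(xo)
  fs <- tabulate(findInterval(xs, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(xs)
  mean(abs(fo - fs)) * 100
}

#' Synthesis quality report
#'
#' Applies [distribution_distance()] to every modeled variable and both
#' outcomes, and averages.
#'
#' @inheritParams distribution_distance
#' @param variables columns to compare; defaults to the schema columns
#'   present in both cohorts.
#' @return object of class `distance_report`: `$per_variable` (data frame
#'   of variable, distance_pct) and `$overall_mean`.
#' @export
synthesis_report <- function(original, synthetic, variables = NULL,
                             n_bins = 10L) {
  if (is.null(variables))
    variables <- intersect(.default_visit_order(original), names(synthetic))
  d <- vapply(variables, function(v)
    distribution_distance(original, synthetic, v, n_bins), numeric(1))
  per_variable <- data.frame(variable = variables, distance_pct = unname(d),
                             stringsAsFactors = FALSE)
  structure(list(per_variable = per_variable, overall_mean = mean(d)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat("Frequency-distribution distance (original vs synthetic), percent\n")
  print(x$per_variable, row.names = FALSE)
  cat(sprintf("overall mean: %.3f%%\n", x$overall_mean))
  invisible(x)
}

#' Write a distance report to CSV or JSON
#'
#' @param report a `distance_report`.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_distance_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(per_variable = report$per_variable,
           overall_mean = report$overall_mean),
      path, digits = I(17), auto_unbox = TRUE)
  } else {
    utils::write.csv(rbind(report$per_variable,
                           data.frame(variable = "overall_mean",
                                      distance_pct = report$overall_mean)),
                     path, row.names = FALSE)
  }
  invisible(path)
}
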