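# Cohort schema, CSV I/O, encoding/normalization, train/test split,
# positive-outcome filtering, and a parametric heart-failure-like fixture
# generator so every stage is testable without external data.

.COHORT_INPUTS <- c("sex", "age", "creatinine_phosphokinase",
                    "ejection_fraction", "high_blood_pressure", "platelets",
                    "serum_creatinine", "serum_sodium", "smoking", "anemia")
.COHORT_BINARY <- c("sex", "high_blood_pressure", "smoking", "anemia",
                    "treatment_key", "death")
.COHORT_CONTINUOUS <- c("age", "creatinine_phosphokinase",
                        "ejection_fraction", "platelets", "serum_creatinine",
                        "serum_sodium", "time")
.COHORT_MANDATORY <- c("id", .COHORT_INPUTS, "time", "treatment_key")
.COHORT_ORDER <- c("id", .COHORT_INPUTS, "time", "treatment_key", "death")

.COLUMN_ALIASES <- list(
  id = c("id", "patient_id"),
  sex = c("sex", "v1"),
  age = c("age", "v2"),
  creatinine_phosphokinase = c("creatinine_phosphokinase", "cpk", "v3"),
  ejection_fraction = c("ejection_fraction", "ef", "v4"),
  high_blood_pressure = c("high_blood_pressure", "hbp", "v5"),
  platelets = c("platelets", "v6"),
  serum_creatinine = c("serum_creatinine", "v7"),
  serum_sodium = c("serum_sodium", "v8"),
  smoking = c("smoking", "v9"),
  anemia = c("anemia", "anaemia", "v10"),
  time = c("time", "o1", "therapy_time", "time_days"),
  treatment_key = c("treatment_key", "tk", "o2"),
  death = c("death", "death_event", "deceased")
)

.canon_names <- function(nm) {
  nm <- gsub("[^a-z0-9]+", "_", tolower(trimws(nm)))
  nm <- gsub("^_|_$", "", nm)
  for (target in names(.COLUMN_ALIASES))
    nm[nm %in% .COLUMN_ALIASES[[target]]] <- target
  nm
}

.validate_cohort <- function(cohort) {
  if (anyDuplicated(cohort$id))
    stop("duplicated ID in cohort: ",
         cohort$id[duplicated(cohort$id)][1L], call. = FALSE)
  for (col in intersect(.COHORT_BINARY, names(cohort))) {
    v <- cohort[[col]]
    if (length(v) && !all(v %in% c(0, 1)))
      stop(sprintf("column '%s' must be binary (0/1)", col), call. = FALSE)
  }
  for (col in intersect(.COHORT_CONTINUOUS, names(cohort))) {
    if (length(cohort[[col]]) && any(!is.finite(cohort[[col]])))
      stop(sprintf("column '%s' contains non-finite values", col),
           call. = FALSE)
  }
  if ("time" %in% names(cohort) && length(cohort$time) &&
      any(cohort$time < 0))
    stop("therapy time must be non-negative", call. = FALSE)
  invisible(cohort)
}

#' Read a patient cohort from CSV
#'
#' Expects a header naming the schema columns: `id`, the ten covariates
#' (sex, age, creatinine_phosphokinase, ejection_fraction,
#' high_blood_pressure, platelets, serum_creatinine, serum_sodium, smoking,
#' anemia), the outcomes `time` (therapy days) and `treatment_key`
#' (binary), and optionally `death`. Case-insensitive aliases (`V1`..`V10`,
#' `O1`, `O2`, `DEATH_EVENT`, ...) are accepted; unknown columns are kept
#' as opaque extras.
#'
#' @param path CSV file path.
#' @return a validated cohort `data.frame`, known columns first.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- .canon_names(names(raw))
  missing <- setdiff(.COHORT_MANDATORY, names(raw))
  if (length(missing))
    stop("missing mandatory cohort column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  numeric_cols <- setdiff(intersect(.COHORT_ORDER, names(raw)), "id")
  for (col in numeric_cols) {
    v <- raw[[col]]
    if (is.numeric(v)) next
    if (nrow(raw) == 0L) { raw[[col]] <- numeric(0); next }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(v) != "")
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at row %d",
                   v[bad[1L]], col, bad[1L]), call. = FALSE)
    raw[[col]] <- num
  }
  raw$id <- as.character(raw$id)
  known <- intersect(.COHORT_ORDER, names(raw))
  extras <- setdiff(names(raw), known)
  cohort <- raw[, c(known, extras), drop = FALSE]
  .validate_cohort(cohort)
}

#' Write a cohort to CSV
#'
#' @param cohort a cohort `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Fit a min-max normalization specification
#'
#' Records per-variable `min` and `max` of every continuous schema column
#' present in `cohort` (including therapy time).
#'
#' @param cohort a cohort `data.frame`.
#' @return object of class `normalization_spec`.
#' @export
fit_normalization <- function(cohort) {
  vars <- intersect(.COHORT_CONTINUOUS, names(cohort))
  if (nrow(cohort) == 0L) stop("cannot fit normalization on an empty cohort")
  structure(
    list(mins = vapply(cohort[vars], min, numeric(1)),
         maxs = vapply(cohort[vars], max, numeric(1))),
    class = "normalization_spec"
  )
}

.norm_col <- function(x, lo, hi, name) {
  if (hi == lo) {
    warning(sprintf("variable '%s' is constant on the fitting split; mapped to 0",
                    name), call. = FALSE)
    return(rep(0, length(x)))
  }
  pmin(1, pmax(0, (x - lo) / (hi - lo)))
}

#' Encode and normalize a cohort for the network
#'
#' Binary covariates pass through as 0/1; each continuous variable is
#' mapped by `(x - min) / (max - min)` with the statistics taken from
#' `spec` (or fitted on `cohort` when `spec` is `NULL`); values outside the
#' fitted range are clamped to \[0, 1\]. The outcome matrix `Y` holds
#' normalized therapy time and the binary treatment key.
#'
#' @param cohort a cohort `data.frame`.
#' @param spec optional [fit_normalization()] result to reuse (e.g. the
#'   training split's statistics applied to test data).
#' @return list with `X` (`n x 10` input matrix), `Y` (`n x 2` outcome
#'   matrix), and `spec`.
#' @export
encode_and_normalize <- function(cohort, spec = NULL) {
  if (is.null(spec)) spec <- fit_normalization(cohort)
  if (!inherits(spec, "normalization_spec"))
    stop("'spec' must be a normalization_spec")
  n <- nrow(cohort)
  X <- matrix(NA_real_, n, length(.COHORT_INPUTS),
              dimnames = list(NULL, .COHORT_INPUTS))
  for (col in .COHORT_INPUTS) {
    X[, col] <- if (col %in% .COHORT_BINARY) as.numeric(cohort[[col]])
      else .norm_col(cohort[[col]], spec$mins[[col]], spec$maxs[[col]], col)
  }
  Y <- cbind(time = .norm_col(cohort$time, spec$mins[["time"]],
                              spec$maxs[["time"]], "time"),
             treatment_key = as.numeric(cohort$treatment_key))
  list(X = X, Y = Y, spec = spec)
}

#' Map a normalized time back to days
#'
#' @param spec a `normalization_spec`.
#' @param value normalized time in \[0, 1\].
#' @return therapy time in days on the original scale.
#' @export
denormalize_time <- function(spec, value) {
  if (!inherits(spec, "normalization_spec"))
    stop("'spec' must be a normalization_spec")
  value * (spec$maxs[["time"]] - spec$mins[["time"]]) + spec$mins[["time"]]
}

#' Shuffled train/test split
#'
#' Uniform shuffle from `seed`; the training part holds
#' `ceiling(train_fraction * n)` records, the test part the remainder. The
#' two parts are disjoint and cover the cohort.
#'
#' @param cohort a cohort `data.frame` with at least 2 rows.
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed integer shuffle seed.
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(cohort, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must lie strictly between 0 and 1")
  n <- nrow(cohort)
  if (n < 2L) stop("cannot split a cohort with fewer than 2 records",
                   call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  ntr <- ceiling(train_fraction * n)
  list(train = cohort[idx[seq_len(ntr)], , drop = FALSE],
       test = cohort[idx[(ntr + 1L):n], , drop = FALSE])
}

#' Positive-outcome subset
#'
#' Keeps survivors (`death == 0`) whose therapy time is at least
#' `min_time_days` — the control population of the dual-model recommender.
#'
#' @param cohort a cohort `data.frame` carrying a `death` flag.
#' @param min_time_days minimal therapy time (days) counting as a "long"
#'   therapy; default 60 within the six-month observation window.
#' @return the filtered cohort.
#' @export
filter_positive <- function(cohort, min_time_days = 60) {
  if (!"death" %in% names(cohort))
    stop("cohort has no 'death' column; regenerate the fixture with a death flag",
         call. = FALSE)
  cohort[cohort$death == 0 & cohort$time >= min_time_days, , drop = FALSE]
}

#' Default fixture-generator parameters
#'
#' The stated world of the fixture cohort: binary covariate rates, lab
#' distributions, the ejection-fraction mixture with its 40% threshold
#' separating reduced-EF (systolic heart failure) from preserved-EF
#' patients, treatment-key probabilities 0.9 (reduced) / 0.6 (preserved),
#' a logistic death model in (EF, serum creatinine, age), and
#' outcome-dependent therapy times (deaths uniform on 4-120 days,
#' survivors on 60-183). `sodium_age_slope` (default 0) optionally plants a
#' known linear age-to-sodium coefficient for parameter-recovery checks.
#'
#' @param ... overrides of the defaults by name.
#' @return named list of parameters.
#' @export
fixture_params <- function(...) {
  defaults <- list(
    p_sex = 0.65, p_hbp = 0.35, p_smoking = 0.32, p_anemia = 0.43,
    age_mean = 60, age_sd = 12, age_min = 40, age_max = 95,
    cpk_meanlog = 5.5, cpk_sdlog = 0.9,
    scr_meanlog = log(1.1), scr_sdlog = 0.3,
    platelets_mean = 2.6e5, platelets_sd = 9.5e4,
    sodium_mean = 137, sodium_sd = 4, sodium_age_slope = 0,
    p_reduced_ef = 0.6, ef_reduced_mean = 30, ef_preserved_mean = 55,
    ef_sd = 5, ef_min = 10, ef_max = 75, ef_threshold = 40,
    tk_prob_reduced = 0.9, tk_prob_preserved = 0.6,
    death_intercept = -1.0, death_ef_coef = -0.06,
    death_scr_coef = 0.8, death_age_coef = 0.03,
    time_death_min = 4, time_death_max = 120,
    time_survivor_min = 60, time_survivor_max = 183
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown fixture parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, overrides)
}

.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a fixture cohort
#'
#' Draws a structurally heart-failure-like cohort from the parametric laws
#' of [fixture_params()]: Bernoulli binaries, truncated-normal /
#' log-normal labs, a two-component ejection-fraction mixture, a
#' treatment key whose probability depends on the EF group, a logistic
#' death model, and therapy times that are short for deaths and long for
#' survivors. Fully reproducible from `seed`; IDs are fresh random
#' `P`-prefixed strings.
#'
#' @param n number of patients (`n = 0` gives an empty cohort).
#' @param seed integer seed for every random draw.
#' @param params parameter list from [fixture_params()] (a plain list of
#'   overrides is also accepted).
#' @return a cohort `data.frame` with the schema columns plus `death`.
#' @export
generate_fixture_cohort <- function(n, seed = 1L, params = fixture_params()) {
  if (n < 0 || n != round(n)) stop("'n' must be a non-negative integer")
  params <- do.call(fixture_params, params)
  probs <- params[c("p_sex", "p_hbp", "p_smoking", "p_anemia",
                    "p_reduced_ef", "tk_prob_reduced", "tk_prob_preserved")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop("fixture probabilities must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (n == 0L) {
    empty <- stats::setNames(
      as.data.frame(c(list(character(0)),
                      rep(list(numeric(0)), length(.COHORT_ORDER) - 1L))),
      .COHORT_ORDER)
    return(empty)
  }
  set.seed(seed)
  sex <- stats::rbinom(n, 1, params$p_sex)
  age <- .rtnorm(n, params$age_mean, params$age_sd, params$age_min,
                 params$age_max)
  cpk <- stats::rlnorm(n, params$cpk_meanlog, params$cpk_sdlog)
  reduced <- stats::runif(n) < params$p_reduced_ef
  ef <- .rtnorm(n, ifelse(reduced, params$ef_reduced_mean,
                          params$ef_preserved_mean),
                params$ef_sd, params$ef_min, params$ef_max)
  hbp <- stats::rbinom(n, 1, params$p_hbp)
  platelets <- .rtnorm(n, params$platelets_mean, params$platelets_sd, lo = 0)
  scr <- stats::rlnorm(n, params$scr_meanlog, params$scr_sdlog)
  sodium <- .rtnorm(n, params$sodium_mean, params$sodium_sd) +
    params$sodium_age_slope * (age - params$age_mean)
  smoking <- stats::rbinom(n, 1, params$p_smoking)
  anemia <- stats::rbinom(n, 1, params$p_anemia)
  shf <- ef < params$ef_threshold
  tk <- stats::rbinom(n, 1, ifelse(shf, params$tk_prob_reduced,
                                   params$tk_prob_preserved))
  p_death <- stats::plogis(params$death_intercept +
                             params$death_ef_coef * (ef - 40) +
                             params$death_scr_coef * (scr - 1.4) +
                             params$death_age_coef * (age - 60))
  death <- stats::rbinom(n, 1, p_death)
  time <- ifelse(death == 1,
                 stats::runif(n, params$time_death_min,
                              params$time_death_max),
                 stats::runif(n, params$time_survivor_min,
                              params$time_survivor_max))
  id <- sprintf("P%06d", sample.int(999999L, n))
  data.frame(id = id, sex = sex, age = age,
             creatinine_phosphokinase = cpk, ejection_fraction = ef,
             high_blood_pressure = hbp, platelets = platelets,
             serum_creatinine = scr, serum_sodium = sodium,
             smoking = smoking, anemia = anemia, time = time,
             treatment_key = tk, death = death,
             stringsAsFactors = FALSE)
}
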