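test_that("cohort CSV round trip is lossless and aliases are accepted", {
  co <- generate_fixture_cohort(40, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co, tolerance = 1e-12, ignore_attr = TRUE)
  # V1..V10 / O1 / O2 / DEATH_EVENT headers map onto the schema
  alias <- co
  names(alias) <- c("ID", paste0("V", 1:10), "O1", "O2", "DEATH_EVENT")
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(alias, path2, row.names = FALSE)
  back2 <- read_cohort(path2)
  expect_identical(names(back2), names(co))
  expect_equal(back2$ejection_fraction, co$ejection_fraction,
               tolerance = 1e-12)
  # unknown columns survive as opaque extras
  extra <- co
  extra$site <- "A"
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(extra, path3)
  expect_identical(read_cohort(path3)$site, rep("A", 40))
})

test_that("cohort reading validates schema, types and IDs", {
  co <- generate_fixture_cohort(10, seed = 3)
  # empty file with header -> empty cohort
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co[0, ], path)
  expect_identical(nrow(read_cohort(path)), 0L)
  # missing mandatory column
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co[, setdiff(names(co), "ejection_fraction")], path2)
  expect_error(read_cohort(path2), "ejection_fraction")
  # duplicated ID
  dup <- co; dup$id[2] <- dup$id[1]
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dup, path3, row.names = FALSE)
  expect_error(read_cohort(path3), "duplicated ID")
  # non-numeric cell names the row
  bad <- co; bad$age <- as.character(bad$age); bad$age[3] <- "forty"
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path4, row.names = FALSE)
  expect_error(read_cohort(path4), "row 3")
})

test_that("encoding normalizes continuous variables onto [0,1] edges", {
  co <- generate_fixture_cohort(60, seed = 4)
  enc <- encode_and_normalize(co)
  expect_identical(dim(enc$X), c(60L, 10L))
  expect_true(all(enc$X >= 0 & enc$X <= 1))
  expect_true(all(enc$Y >= 0 & enc$Y <= 1))
  # lower edge -> 0, upper edge -> 1, midpoint -> 0.5
  i_min <- which.min(co$age); i_max <- which.max(co$age)
  expect_equal(unname(enc$X[i_min, "age"]), 0)
  expect_equal(unname(enc$X[i_max, "age"]), 1)
  mid <- co[1:3, ]
  mid$age <- c(min(co$age), (min(co$age) + max(co$age)) / 2, max(co$age))
  enc_mid <- encode_and_normalize(mid, spec = enc$spec)
  expect_equal(unname(enc_mid$X[, "age"]), c(0, 0.5, 1))
  # binaries pass through untouched
  expect_identical(unname(enc$X[, "sex"]), as.numeric(co$sex))
  # reusing a fitted spec clamps out-of-range values
  out <- co[1, ]; out$age <- max(co$age) + 100
  enc_out <- encode_and_normalize(out, spec = enc$spec)
  expect_equal(unname(enc_out$X[, "age"]), 1)
  # constant column maps to 0 with a warning
  cst <- co; cst$serum_sodium <- 137
  expect_warning(enc_cst <- encode_and_normalize(cst), "serum_sodium")
  expect_true(all(enc_cst$X[, "serum_sodium"] == 0))
  # time denormalization inverts the transform
  expect_equal(unname(denormalize_time(enc$spec, enc$Y[, 1])), co$time)
})

test_that("train/test split shuffles, partitions and reproduces", {
  co <- generate_fixture_cohort(299, seed = 5)
  sp <- split_train_test(co, 0.8, seed = 1)
  expect_identical(nrow(sp$train), 240L)
  expect_identical(nrow(sp$test), 59L)
  expect_identical(sort(c(sp$train$id, sp$test$id)), sort(co$id))
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  sp2 <- split_train_test(co, 0.8, seed = 1)
  expect_identical(sp$train$id, sp2$train$id)
  expect_false(identical(
    split_train_test(co, 0.8, seed = 2)$train$id, sp$train$id))
  expect_error(split_train_test(co[1, ], 0.8, 1), "fewer than 2")
  expect_error(split_train_test(co, 1.2, 1), "between 0 and 1")
})

test_that("positive-outcome filtering keeps long-surviving patients", {
  co <- generate_fixture_cohort(1000, seed = 1)
  pos <- filter_positive(co)
  expect_true(all(pos$death == 0))
  expect_true(all(pos$time >= 60))
  expect_identical(nrow(pos), sum(co$death == 0 & co$time >= 60))
  expect_gt(mean(pos$time), mean(co$time))
  # degenerate cases
  all_pos <- co[co$death == 0 & co$time >= 60, ]
  expect_identical(filter_positive(all_pos), all_pos)
  all_dead <- co[co$death == 1, ]
  expect_identical(nrow(filter_positive(all_dead)), 0L)
  expect_error(filter_positive(co[, names(co) != "death"]), "death")
  # configurable floor
  expect_true(all(filter_positive(co, 120)$time >= 120))
})

test_that("fixture generator is reproducible and honors its stated laws", {
  expect_identical(nrow(generate_fixture_cohort(0)), 0L)
  a <- generate_fixture_cohort(100, seed = 7)
  b <- generate_fixture_cohort(100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(generate_fixture_cohort(100, seed = 8), a))
  expect_error(generate_fixture_cohort(10, params = list(p_sex = 1.4)),
               "\\[0, 1\\]")
  expect_error(fixture_params(nonsense = 1), "unknown")
  # treatment mechanism: P(TK = 1 | reduced EF) = 0.90 +/- 0.02 at n = 5000
  co <- generate_fixture_cohort(5000, seed = 11)
  expect_equal(mean(co$treatment_key[co$ejection_fraction < 40]), 0.9,
               tolerance = 0.025)
  expect_lt(mean(co$treatment_key[co$ejection_fraction >= 40]), 0.75)
  # outcome-dependent times
  expect_true(all(co$time[co$death == 0] >= 60))
  expect_lt(mean(co$time[co$death == 1]), mean(co$time[co$death == 0]))
})

test_that("fixture moments converge to the configured laws at n = 20000", {
  p <- fixture_params()
  co <- generate_fixture_cohort(20000, seed = 20240101)
  n <- nrow(co)
  within3se <- function(emp, mean, sd) abs(emp - mean) <= 3 * sd / sqrt(n)
  # binary rates
  expect_true(within3se(mean(co$sex), p$p_sex,
                        sqrt(p$p_sex * (1 - p$p_sex))))
  expect_true(within3se(mean(co$high_blood_pressure), p$p_hbp,
                        sqrt(p$p_hbp * (1 - p$p_hbp))))
  expect_true(within3se(mean(co$smoking), p$p_smoking,
                        sqrt(p$p_smoking * (1 - p$p_smoking))))
  expect_true(within3se(mean(co$anemia), p$p_anemia,
                        sqrt(p$p_anemia * (1 - p$p_anemia))))
  # truncated-normal age: closed-form truncated mean as the oracle
  a <- (p$age_min - p$age_mean) / p$age_sd
  b <- (p$age_max - p$age_mean) / p$age_sd
  age_mean <- p$age_mean + p$age_sd * (dnorm(a) - dnorm(b)) /
    (pnorm(b) - pnorm(a))
  expect_true(within3se(mean(co$age), age_mean, sd(co$age)))
  # log-normal labs
  cpk_mean <- exp(p$cpk_meanlog + p$cpk_sdlog^2 / 2)
  expect_true(within3se(mean(co$creatinine_phosphokinase), cpk_mean,
                        sd(co$creatinine_phosphokinase)))
  scr_mean <- exp(p$scr_meanlog + p$scr_sdlog^2 / 2)
  expect_true(within3se(mean(co$serum_creatinine), scr_mean,
                        sd(co$serum_creatinine)))
  # sodium: plain normal
  expect_true(within3se(mean(co$serum_sodium), p$sodium_mean,
                        p$sodium_sd))
  # EF mixture mean (truncation at [10, 75] is negligible at these sds)
  ef_mean <- p$p_reduced_ef * p$ef_reduced_mean +
    (1 - p$p_reduced_ef) * p$ef_preserved_mean
  expect_true(within3se(mean(co$ejection_fraction), ef_mean,
                        sd(co$ejection_fraction)))
  # platelets: normal truncated at 0, oracle via the one-sided formula
  alpha <- -p$platelets_mean / p$platelets_sd
  plt_mean <- p$platelets_mean + p$platelets_sd *
    dnorm(alpha) / (1 - pnorm(alpha))
  expect_true(within3se(mean(co$platelets), plt_mean, sd(co$platelets)))
})
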