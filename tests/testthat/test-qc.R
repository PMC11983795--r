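# qc_conversions module: exclusions, conversions, outlier rule, audit.

test_that("ts_to_kbp implements the affine conversion", {
  expect_equal(ts_to_kbp(0), 3.274)
  expect_equal(ts_to_kbp(1.0), 5.687)
  expect_equal(ts_to_kbp(2.0), 8.100)
  expect_true(is.na(ts_to_kbp(NA_real_)))
  expect_error(ts_to_kbp(-0.1), "non-negative")
  # affine identity: differences scale by exactly 2.413 kbp per T/S unit
  a <- with_seed_test(1, runif(200, 0, 3))
  b <- with_seed_test(2, runif(200, 0, 3))
  expect_equal(ts_to_kbp(a) - ts_to_kbp(b), 2.413 * (a - b),
               tolerance = 1e-12)
})

test_that("aggregate_lymphocytes sums components and guards ranges", {
  expect_equal(aggregate_lymphocytes(0, 0, 0), 0)
  expect_equal(aggregate_lymphocytes(0.1, 0.2, 0.15), 0.45)
  expect_warning(out <- aggregate_lymphocytes(0.5, 0.5, 0.5), "exceeds 1")
  expect_equal(out, 1.5)
  expect_error(aggregate_lymphocytes(-0.1, 0.2, 0.2), "\\[0, 1\\]")
  expect_true(is.na(aggregate_lymphocytes(NA, 0.2, 0.2)))
})

test_that("exponentiate_predictions round-trips log predictions", {
  tbl <- data.frame(dnam_log_crp = c(0, log(3.2), log(0.5)))
  spec <- predictor_spec("crp")
  out <- exponentiate_predictions(tbl, spec)
  expect_equal(out$dnam_log_crp, c(1, 3.2, 0.5), tolerance = 1e-12)
  # identity specs leave the table untouched
  tbl2 <- data.frame(dnam_b2m = c(1.5, 2))
  expect_identical(exponentiate_predictions(tbl2, predictor_spec("b2m")),
                   tbl2)
})

test_that("filter_log_outliers matches the brute-force oracle", {
  for (seed in c(3, 4, 5)) {
    v <- with_seed_test(seed, rlnorm(1000, 0, 0.4))
    # inject five points far outside
    v[1:5] <- exp(mean(log(v[-(1:5)])) + c(5, -5, 6, 5.5, -6) *
                    sd(log(v[-(1:5)])))
    fl <- filter_log_outliers(v)
    expect_identical(fl$keep, oracle_log_outliers(v))
    expect_false(any(fl$keep[1:5]))  # injected points always removed
    expect_equal(fl$n_outlier, sum(!oracle_log_outliers(v)))
  }
  # larger vector, random contamination level
  v <- with_seed_test(6, rlnorm(10000, 1, 0.7))
  expect_identical(filter_log_outliers(v)$keep, oracle_log_outliers(v))
})

test_that("filter_log_outliers handles missing, ties and non-positives", {
  # all equal: sd = 0, rule vacuous
  fl <- filter_log_outliers(rep(2.5, 40))
  expect_true(all(fl$keep))
  expect_equal(fl$n_outlier, 0)
  # missing entries: keep = FALSE but counted as missing, not outlier
  v <- c(rlnorm(50, 0, 0.3), NA, NA)
  fl <- filter_log_outliers(v)
  expect_equal(fl$n_missing, 2)
  expect_false(any(fl$keep[51:52]))
  # non-positive values: error by default, excludable on request
  v2 <- c(1, 2, 0, 3)
  expect_error(filter_log_outliers(v2), "non-positive")
  fl2 <- filter_log_outliers(v2, nonpositive = "exclude")
  expect_equal(fl2$n_nonpositive, 1)
  expect_false(fl2$keep[3])
  expect_error(filter_log_outliers(v2, k = 0), "positive")
})

test_that("sex-mismatch exclusion removes exactly the discordant rows", {
  tbl <- simulate_quiet(sim_config(seed = 21))
  out <- exclude_sex_mismatch(tbl)
  expect_equal(out$report$counts[["sex_mismatch"]], 60)
  expect_equal(nrow(out$table), nrow(tbl) - 60)
  expect_true(all(out$table$sex == out$table$dnam_predicted_sex))
  # all-concordant table: nothing removed
  again <- exclude_sex_mismatch(out$table)
  expect_equal(again$report$counts[["sex_mismatch"]], 0)
  # fully discordant table: empty result with a warning
  flip <- tbl
  flip$dnam_predicted_sex <- ifelse(flip$sex == "male", "female", "male")
  expect_warning(res <- exclude_sex_mismatch(flip), "every row")
  expect_equal(nrow(res$table), 0)
  expect_error(exclude_sex_mismatch(tbl[, "id", drop = FALSE]), "must contain")
})

test_that("top-coded-age exclusion is scoped to age-using predictors", {
  tbl <- simulate_quiet(sim_config(seed = 22))
  clean <- exclude_sex_mismatch(tbl)$table
  a_clock <- build_analysis_set(clean, predictor_spec("zhang"))
  expect_equal(a_clock$report$counts[["topcoded_age"]], 126)
  expect_true(all(a_clock$data$phenotype < 85))
  # telomere analysis: rule not applied (uses_age = FALSE)
  a_tel <- build_analysis_set(clean, predictor_spec("dnamtl"))
  expect_false("topcoded_age" %in% names(a_tel$report$counts))
  step <- exclude_topcoded_age(tbl)
  expect_equal(step$report$counts[["topcoded_age"]], 126)
  expect_equal(exclude_topcoded_age(step$table)$report$counts[["topcoded_age"]],
               0)
})

test_that("build_analysis_set composes the audit exactly", {
  cfg <- sim_config(seed = 23)
  tbl <- simulate_quiet(cfg)
  clean <- exclude_sex_mismatch(tbl)$table
  a <- build_analysis_set(clean, predictor_spec("cystatin_c"))
  expect_equal(a$report$counts[["missing_cystatin_c"]], 28)
  expect_equal(a$report$counts[["outlier_cystatin_c"]],
               unname(cfg$n_outliers["cystatin_c"]))
  # composition audit: rows_in = rows_out + distinct removals
  expect_equal(a$report$n_input,
               nrow(a$data) + length(unique(unlist(a$report$removed))))
  # transforms applied on the analysis scale
  a_tel <- build_analysis_set(clean, predictor_spec("dnamtl"))
  raw <- clean$telomere_ts_ratio[match(a_tel$data$id, clean$id)]
  expect_equal(a_tel$data$phenotype, ts_to_kbp(raw))
  a_crp <- build_analysis_set(clean, predictor_spec("crp"))
  raw_log <- clean$dnam_log_crp[match(a_crp$data$id, clean$id)]
  expect_equal(a_crp$data$prediction, exp(raw_log), tolerance = 1e-12)
  # lymphocyte prediction is the B + CD4 + CD8 sum
  a_l <- build_analysis_set(clean, predictor_spec("lymphocytes"))
  i <- match(a_l$data$id, clean$id)
  expect_equal(a_l$data$prediction,
               clean$dnam_b[i] + clean$dnam_cd4t[i] + clean$dnam_cd8t[i])
  # refuses a sex-discordant table
  expect_error(build_analysis_set(tbl, predictor_spec("crp")),
               "exclude_sex_mismatch")
})

test_that("QC reporting is invariant to row order", {
  tbl <- simulate_quiet(sim_config(seed = 24))
  clean <- exclude_sex_mismatch(tbl)$table
  shuf <- clean[with_seed_test(9, sample(nrow(clean))), ]
  a1 <- build_analysis_set(clean, predictor_spec("b2m"))
  a2 <- build_analysis_set(shuf, predictor_spec("b2m"))
  expect_identical(a1$report$counts, a2$report$counts)
  expect_identical(a1$report$removed, a2$report$removed)
})

test_that("clean tables produce an all-zero audit", {
  tbl <- simulate_quiet(clean_config(seed = 25, predictors = "cystatin_c"))
  a <- build_analysis_set(tbl, predictor_spec("cystatin_c"))
  expect_true(all(unlist(a$report$counts) == 0))
  expect_equal(a$report$n_analysable, nrow(tbl))
})

test_that("qc reports serialize to text and TSV", {
  tbl <- simulate_quiet(clean_config(seed = 26, predictors = "b2m"))
  a <- build_analysis_set(tbl, predictor_spec("b2m"))
  dir <- withr_local_tempdir()
  df <- write_qc_report(a$report, file.path(dir, "qc.txt"),
                        file.path(dir, "qc.tsv"))
  expect_true(file.exists(file.path(dir, "qc.txt")))
  back <- read.delim(file.path(dir, "qc.tsv"))
  expect_equal(back$count[back$rule == "analysable_n"], nrow(tbl))
})
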