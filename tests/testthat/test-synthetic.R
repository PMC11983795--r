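# synthetic_data module: correlated-pair primitive, population generator,
# truth table, determinism and defect accounting.

test_that("generate_correlated_pair enforces its preconditions", {
  x <- with_seed_test(1, rnorm(50))
  expect_error(generate_correlated_pair(x, 1.0), "inside \\(-1, 1\\)")
  expect_error(generate_correlated_pair(x, -1.0), "inside \\(-1, 1\\)")
  expect_silent(generate_correlated_pair(x, 0.999, noise_seed = 2))
  expect_error(generate_correlated_pair(rep(3, 50), 0.5),
               "degenerate phenotype vector")
  expect_error(generate_correlated_pair(c(1), 0.5), "at least two")
})

test_that("generate_correlated_pair hits its target correlation", {
  # Fisher-z bound: SE = 1/sqrt(n - 3); +-0.02 at n = 10000 is ~2 SE in r
  x <- with_seed_test(42, rnorm(10000))
  y <- generate_correlated_pair(x, 0.9, noise_seed = 7)
  expect_lt(abs(cor(x, y) - 0.9), 0.02)
  y0 <- generate_correlated_pair(x, 0.0, noise_seed = 8)
  expect_lt(abs(cor(x, y0)), 0.03)
  # deterministic given seed
  expect_identical(y, generate_correlated_pair(x, 0.9, noise_seed = 7))
  # bias shifts location without touching correlation
  yb <- generate_correlated_pair(x, 0.9, bias = 5, noise_seed = 7)
  expect_equal(yb, y + 5)
})

test_that("simulate_population reproduces the configured cohort structure", {
  cfg <- sim_config(seed = 11)
  tbl <- simulate_quiet(cfg)
  expect_equal(nrow(tbl), 2472)  # 694+159+1005+533+81
  expect_equal(as.vector(table(tbl$race_ethnicity)[names(cfg$group_sizes)]),
               unname(cfg$group_sizes))
  expect_equal(sum(tbl$age_topcoded), 126)
  expect_true(all(tbl$age_years[tbl$age_topcoded] == 85))
  expect_true(all(tbl$age_years >= 50))
  expect_equal(sum(tbl$sex != tbl$dnam_predicted_sex), 60)
  # per-measure missingness counts
  expect_equal(sum(is.na(tbl$cystatin_c_mg_l)), 28)
  expect_equal(sum(is.na(tbl$b2m_mg_l)), 31)
  expect_equal(sum(is.na(tbl$hba1c_pct)), 1)
  expect_equal(sum(is.na(tbl$telomere_ts_ratio)), 2)
  expect_equal(sum(is.na(tbl$lymphocyte_prop)), 13)
  expect_equal(sum(is.na(tbl$monocyte_prop)), 13)
  # proportions stay in range
  expect_true(all(tbl$lymphocyte_prop >= 0 & tbl$lymphocyte_prop <= 1,
                  na.rm = TRUE))
})

test_that("same seed and config give byte-identical output", {
  cfg <- clean_config(seed = 5)
  t1 <- simulate_quiet(cfg)
  t2 <- simulate_quiet(cfg)
  expect_identical(t1, t2)
  t3 <- simulate_quiet(clean_config(seed = 6))
  expect_false(identical(t1$age_years, t3$age_years))
})

test_that("random streams are split per predictor", {
  # dropping one predictor must not perturb the others' draws
  cfg_all <- clean_config(seed = 9,
                          predictors = c("horvath", "hannum", "cystatin_c"))
  cfg_sub <- clean_config(seed = 9, predictors = c("horvath", "cystatin_c"))
  t_all <- simulate_quiet(cfg_all)
  t_sub <- simulate_quiet(cfg_sub)
  expect_identical(t_all$dnam_horvath, t_sub$dnam_horvath)
  expect_identical(t_all$dnam_cystatin_c, t_sub$dnam_cystatin_c)
})

test_that("zero-defect config yields nothing for QC to remove", {
  tbl <- simulate_quiet(clean_config(seed = 2))
  expect_equal(sum(tbl$sex != tbl$dnam_predicted_sex), 0)
  expect_equal(sum(tbl$age_topcoded), 0)
  expect_equal(sum(is.na(tbl$cystatin_c_mg_l)), 0)
})

test_that("infeasible defect counts are rejected", {
  expect_error(sim_config(group_sizes = c("NH White" = 50L),
                          n_sex_mismatch = 60L), "exceeds cohort size")
  expect_error(sim_config(group_sizes = c("NH White" = 100L),
                          n_topcoded = 90L, n_sex_mismatch = 20L),
               "infeasible")
  expect_error(sim_config(target_correlation = 1.0), "inside \\(-1, 1\\)")
  expect_error(sim_config(group_sizes = c("NH White" = 1L)), ">= 2")
})

test_that("truth_table echoes the generating parameters", {
  cfg <- sim_config(seed = 1, target_correlation = 0.8)
  tt <- truth_table(cfg)
  expect_equal(nrow(tt), 15 * 5)  # 15 predictors x 5 groups
  expect_true(all(tt$true_rho == 0.8))
  cfg2 <- clean_config(predictors = c("horvath", "zhang"))
  tt2 <- truth_table(cfg2)
  expect_setequal(unique(tt2$predictor), c("horvath", "zhang"))
  expect_equal(nrow(tt2), 2 * 2)
})

test_that("per-group correlation calibration recovers the truth", {
  # property: at n = 5000/group, per-group r within 3 Fisher-z SEs of truth
  cfg <- clean_config(seed = 31, n = 5000,
                      groups = c("NH White", "NH Black"),
                      predictors = c("horvath", "cystatin_c"),
                      target_correlation = list(
                        horvath = c("NH White" = 0.6, "NH Black" = 0.9),
                        cystatin_c = c("NH White" = 0.9, "NH Black" = 0.3)))
  tbl <- simulate_quiet(cfg)
  tt <- truth_table(cfg)
  for (p in cfg$predictors) {
    a <- build_analysis_set(tbl, predictor_spec(p))
    m <- stratified_metrics(a, "race_ethnicity")
    for (g in c("NH White", "NH Black")) {
      r <- m$pearson_r[m$stratum == g]
      n <- m$n[m$stratum == g]
      truth <- tt$true_rho[tt$predictor == p & tt$group == g]
      expect_lt(abs(atanh(r) - atanh(truth)), 3 / sqrt(n - 3),
                label = sprintf("|z(%s, %s) - z(truth)|", p, g))
    }
  }
})

test_that("injected outliers land beyond 3 log-scale SDs", {
  cfg <- sim_config(seed = 17)
  tbl <- simulate_quiet(cfg)
  v <- tbl$cystatin_c_mg_l
  fl <- filter_log_outliers(v)
  expect_equal(fl$n_outlier, unname(cfg$n_outliers["cystatin_c"]))
})

test_that("write_simulation round-trips table, truth and config", {
  dir <- withr_local_tempdir()
  cfg <- clean_config(seed = 3, n = 60)
  tbl <- suppressWarnings(write_simulation(cfg, dir))
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  back <- read_population(file.path(dir, "participants.tsv"))
  expect_equal(nrow(back), nrow(tbl))
  expect_equal(back$age_years, tbl$age_years, tolerance = 1e-12)
  cfg2 <- read_sim_config(file.path(dir, "config.json"))
  expect_equal(cfg2$target_correlation, cfg$target_correlation)
  expect_equal(cfg2$group_sizes, cfg$group_sizes)
  expect_identical(simulate_quiet(cfg2), tbl)
})
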