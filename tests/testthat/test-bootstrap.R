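# bootstrap_inference module: percentile CIs on metric differences.

test_that("percentile extraction matches a sort-based brute force", {
  pa <- make_pairs(300, 0.8, seed = 11)
  pb <- make_pairs(300, 0.5, seed = 13)
  b <- bootstrap_group_difference(pa, pb, "pearson_r", n_iter = 500,
                                  seed = 3, labels = c("a", "b"))
  d <- sort(attr(b, "iterations"))
  # type-7 quantile by hand: linear interpolation between order statistics
  q_hand <- function(d, p) {
    h <- (length(d) - 1) * p + 1
    lo <- floor(h)
    d[lo] + (h - lo) * (d[min(lo + 1, length(d))] - d[lo])
  }
  expect_equal(b$ci_low, q_hand(d, 0.025), tolerance = 1e-12)
  expect_equal(b$ci_high, q_hand(d, 0.975), tolerance = 1e-12)
  expect_equal(b$median_diff, median(d))
  expect_true(b$ci_low <= b$median_diff && b$median_diff <= b$ci_high)
})

test_that("bootstrap comparisons are deterministic and antisymmetric", {
  pa <- make_pairs(200, 0.9, seed = 21)
  pb <- make_pairs(250, 0.6, seed = 23)
  b1 <- bootstrap_group_difference(pa, pb, "mae", n_iter = 400, seed = 7,
                                   labels = c("A", "B"))
  b2 <- bootstrap_group_difference(pa, pb, "mae", n_iter = 400, seed = 7,
                                   labels = c("A", "B"))
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  # swapping groups (same per-row seed) negates the difference and CI
  b3 <- bootstrap_group_difference(pb, pa, "mae", n_iter = 400, seed = 7,
                                   labels = c("B", "A"))
  expect_equal(b3$median_diff, -b1$median_diff)
  expect_equal(b3$ci_low, -b1$ci_high)
  expect_equal(b3$ci_high, -b1$ci_low)
})

test_that("a correlation difference is recovered with its sign", {
  pa <- make_pairs(1000, 0.9, seed = 31)
  pb <- make_pairs(1000, 0.6, seed = 33)
  b <- bootstrap_group_difference(pa, pb, "pearson_r", n_iter = 1000,
                                  seed = 9, labels = c("hi", "lo"))
  expect_gt(b$median_diff, 0.2)
  expect_lt(b$median_diff, 0.4)
  expect_true(b$significant)
  expect_equal(b$n_degenerate, 0)
})

test_that("null self-comparison with a shared stream gives exactly zero", {
  pa <- make_pairs(150, 0.7, seed = 41)
  # identical data and identical labels -> identical resampling streams
  b <- bootstrap_group_difference(pa, pa, "mae", n_iter = 300, seed = 5,
                                  labels = c("same", "same"))
  expect_equal(b$median_diff, 0)
  expect_equal(b$ci_low, 0)
  expect_false(b$significant)
  # independent streams: CI straddles 0
  b2 <- bootstrap_group_difference(pa, pa, "mae", n_iter = 300, seed = 5,
                                   labels = c("one", "two"))
  expect_true(b2$ci_low <= 0 && b2$ci_high >= 0)
})

test_that("equal-n variant caps the resample size", {
  pa <- make_pairs(400, 0.8, seed = 51)
  pb <- make_pairs(150, 0.8, seed = 53)
  b <- bootstrap_equal_n(pa, pb, "pearson_r", n_iter = 300, seed = 11,
                         labels = c("big", "small"))
  expect_equal(b$variant, "equal_n")
  expect_equal(b$n_cap, 150L)
  expect_error(bootstrap_group_difference(pa, pb, "pearson_r",
                                          n_cap = 2, seed = 1),
               "at least 3")
  expect_error(bootstrap_group_difference(pa, pb, "pearson_r",
                                          n_cap = 200, seed = 1),
               "smallest group")
  # capping at a small n widens the CI (averaged over seeds)
  w_std <- w_cap <- numeric(20)
  for (i in 1:20) {
    b_s <- bootstrap_group_difference(pa, pb, "pearson_r", n_iter = 200,
                                      seed = 100 + i, labels = c("x", "y"))
    b_c <- bootstrap_group_difference(pa, pb, "pearson_r", n_iter = 200,
                                      seed = 100 + i, n_cap = 20,
                                      labels = c("x", "y"))
    w_std[i] <- b_s$ci_high - b_s$ci_low
    w_cap[i] <- b_c$ci_high - b_c$ci_low
  }
  expect_gt(mean(w_cap), mean(w_std))
})

test_that("degenerate resamples are dropped and counted", {
  # phenotype almost constant: many resamples have zero variance
  pa <- data.frame(phenotype = c(rep(1, 30), 2, 3),
                   prediction = rnorm(32))
  pb <- make_pairs(30, 0.5, seed = 61)
  expect_warning(
    b <- bootstrap_group_difference(pa, pb, "pearson_r", n_iter = 200,
                                    seed = 13, labels = c("d", "e")),
    "degenerate")
  expect_gt(b$n_degenerate, 0)
})

test_that("all_pairwise_comparisons emits the expected grid", {
  tbl <- simulate_quiet(clean_config(
    seed = 71, n = 120,
    groups = c("Mexican American", "NH White", "NH Black"),
    predictors = c("horvath", "cystatin_c")))
  asets <- lapply(predictor_specs(c("horvath", "cystatin_c")),
                  function(sp) build_analysis_set(tbl, sp))
  grid <- all_pairwise_comparisons(asets,
                                   groups = c("Mexican American", "NH White",
                                              "NH Black"),
                                   n_iter = 100, seed = 17)
  # 2 predictors x 2 metrics x 3 pairs
  expect_equal(nrow(grid), 12)
  expect_setequal(paste(grid$group_a, grid$group_b),
                  c("Mexican American NH White", "NH Black NH White",
                    "Mexican American NH Black"))
  expect_true(all(grid$status == "ok"))
  # reruns are byte-identical
  grid2 <- all_pairwise_comparisons(asets,
                                    groups = c("Mexican American", "NH White",
                                               "NH Black"),
                                    n_iter = 100, seed = 17)
  expect_identical(grid, grid2)
  # sex grid: 1 pair, male - female orientation
  gsex <- all_pairwise_comparisons(asets["horvath"],
                                   groups = c("male", "female"),
                                   strata_var = "sex",
                                   n_iter = 100, seed = 17)
  expect_equal(nrow(gsex), 2)
  expect_true(all(gsex$group_a == "male" & gsex$group_b == "female"))
})

test_that("unanalysable strata are flagged, not dropped", {
  df <- data.frame(
    phenotype = rnorm(103), prediction = rnorm(103),
    race_ethnicity = c(rep("NH White", 50), rep("NH Black", 51),
                       rep("Mexican American", 2)))
  grid <- all_pairwise_comparisons(list(x = df),
                                   groups = c("Mexican American", "NH White",
                                              "NH Black"),
                                   n_iter = 50, seed = 19)
  expect_equal(sum(grid$status == "unanalysable"), 4)  # 2 metrics x 2 pairs
  expect_equal(sum(grid$status == "ok"), 2)
})
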