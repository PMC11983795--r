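# Shared fixtures, built in code.

# A defect-free cohort: no top-coding, mismatches, outliers or missingness.
clean_config <- function(seed = 1L, n = 400L,
                         groups = c("NH White", "NH Black"),
                         predictors = c("horvath", "cystatin_c"),
                         target_correlation = 0.8, ...) {
  sim_config(seed = seed,
             group_sizes = stats::setNames(rep(as.integer(n), length(groups)),
                                           groups),
             predictors = predictors,
             target_correlation = target_correlation,
             n_topcoded = 0L, n_sex_mismatch = 0L,
             n_outliers = stats::setNames(integer(0), character(0)),
             missingness = stats::setNames(integer(0), character(0)),
             ...)
}

simulate_quiet <- function(cfg) suppressWarnings(simulate_population(cfg))

# Paired vectors with a known correlation, for bootstrap/regression tests.
make_pairs <- function(n, rho, seed, mean = 66, sd = 10) {
  x <- with_seed_test(seed, stats::rnorm(n, mean, sd))
  data.frame(phenotype = x,
             prediction = generate_correlated_pair(x, rho,
                                                   noise_seed = seed + 1L))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("epiperform_test_")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# Brute-force Pearson correlation: the independent oracle.
oracle_pearson <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx2 <- dx2 + (x[i] - xb)^2
    dy2 <- dy2 + (y[i] - yb)^2
  }
  num / sqrt(dx2 * dy2)
}

# Sort-based median-absolute-error oracle.
oracle_mae <- function(x, y) {
  d <- sort(abs(y - x))
  n <- length(d)
  if (n %% 2 == 1) d[(n + 1) / 2] else (d[n / 2] + d[n / 2 + 1]) / 2
}

# Brute-force single-pass log-outlier rule.
oracle_log_outliers <- function(v, k = 3) {
  ok <- which(!is.na(v) & v > 0)
  lv <- log(v[ok])
  mu <- mean(lv)
  s <- sqrt(sum((lv - mu)^2) / (length(lv) - 1))
  keep <- rep(FALSE, length(v))
  for (i in seq_along(ok)) {
    keep[ok[i]] <- abs(lv[i] - mu) < k * s
  }
  keep
}

# Analysis-set-shaped data with known group-specific slopes.
make_slope_data <- function(n_per, slopes, seed, noise_sd = 0.5,
                            modifier = "race_ethnicity") {
  groups <- names(slopes)
  with_seed_test(seed, {
    df <- do.call(rbind, lapply(groups, function(g) {
      x <- rnorm(n_per, 10, 3)
      data.frame(phenotype = x,
                 prediction = slopes[[g]] * x + rnorm(n_per, 0, noise_sd),
                 g = g,
                 other = sample(c("male", "female"), n_per, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    names(df)[names(df) == "g"] <- modifier
    names(df)[names(df) == "other"] <-
      if (modifier == "race_ethnicity") "sex" else "race_ethnicity"
    df
  })
}
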