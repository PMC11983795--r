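# Synthetic cohort generator with known, controllable statistical structure.

# --- truncated-normal helpers -------------------------------------------------

# Draw from a standard normal truncated to |z| <= a (inverse-CDF method).
rtnorm_std <- function(n, a) {
  stats::qnorm(stats::runif(n, stats::pnorm(-a), stats::pnorm(a)))
}

tn_var <- function(a) 1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1)

# E[exp(s * T)] for T ~ N(0,1) truncated to |T| <= a.
tn_mgf <- function(s, a) {
  exp(s^2 / 2) * (stats::pnorm(a - s) - stats::pnorm(-a - s)) /
    (2 * stats::pnorm(a) - 1)
}

# Raw-scale Pearson correlation between A = exp(sx * T) and
# B = exp(b * T + c * E), T truncated standard normal, E standard normal,
# when the log-scale construction uses correlation rho_log and the
# prediction's log-scale spread is sy. Closed form via the truncated-normal
# moment generating function.
lognormal_link_corr <- function(rho_log, sx, sy, a) {
  v <- tn_var(a)
  b <- sy * rho_log / sqrt(v)
  c2 <- sy^2 * (1 - rho_log^2)
  m <- function(s) tn_mgf(s, a)
  cov_ab <- exp(c2 / 2) * (m(sx + b) - m(sx) * m(b))
  var_a <- m(2 * sx) - m(sx)^2
  var_b <- m(2 * b) * exp(2 * c2) - m(b)^2 * exp(c2)
  cov_ab / sqrt(var_a * var_b)
}

# Invert the link: log-scale construction correlation achieving a target
# raw-scale (analysis-scale) correlation.
lognormal_link_rho <- function(rho_raw, sx, sy, a) {
  if (abs(rho_raw) >= 1) {
    stop("target correlation must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (rho_raw == 0) return(0)
  lim <- 1 - 1e-9
  f <- function(r) lognormal_link_corr(r, sx, sy, a) - rho_raw
  if (f(lim) < 0 || f(-lim) > 0) {
    stop(sprintf(
      "target raw-scale correlation %.3f unattainable for sdlog (%.2f, %.2f)",
      rho_raw, sx, sy), call. = FALSE)
  }
  stats::uniroot(f, c(-lim, lim), tol = 1e-12)$root
}

# --- exported primitive -------------------------------------------------------

#' Generate a prediction vector with a target correlation to a phenotype
#'
#' Standard Gaussian construction: the phenotype is standardized (optionally
#' on a reference subset, e.g. the rows that will survive QC), independent
#' noise is mixed in as `rho * z + sqrt(1 - rho^2) * noise`, and the result
#' is rescaled to the requested location/scale plus an additive bias. The
#' expected sample correlation with `x` (over the reference subset) is
#' `rho`, for any distribution of `x`.
#'
#' @param x phenotype vector, length >= 2, positive variance.
#' @param rho target Pearson correlation, strictly inside (-1, 1).
#' @param bias additive offset in phenotype units.
#' @param noise_seed integer seed for the noise stream (deterministic).
#' @param location,scale location/scale of the output; default mean/sd of
#'   `x` over `reference`.
#' @param reference logical vector marking rows used for standardization.
#' @return numeric vector of predictions, `length(x)`.
#' @examples
#' x <- rnorm(500, 66, 10)
#' y <- generate_correlated_pair(x, rho = 0.8, noise_seed = 7)
#' cor(x, y)  # ~0.8
#' @export
generate_correlated_pair <- function(x, rho, bias = 0, noise_seed = 1L,
                                     location = NULL, scale = NULL,
                                     reference = NULL) {
  if (length(x) < 2) stop("need at least two phenotype values", call. = FALSE)
  if (!is.finite(rho) || abs(rho) >= 1) {
    stop("target correlation must lie strictly inside (-1, 1)", call. = FALSE)
  }
  reference <- reference %||% rep(TRUE, length(x))
  z <- standardize_on(x, reference)
  eps <- with_seed(noise_seed, stats::rnorm(length(x)))
  u <- rho * z + sqrt(1 - rho^2) * eps
  location <- location %||% mean(x[reference])
  scale <- scale %||% stats::sd(x[reference])
  location + bias + scale * u
}

# Log-scale construction targeting a raw-scale correlation; returns the
# prediction on the raw (exponentiated) scale.
gen_link_pair <- function(x_log, sx, a, rho_target, meanlog_p, sdlog_p, seed) {
  rho_log <- lognormal_link_rho(rho_target, sx, sdlog_p, a)
  t_hat <- standardize_on(x_log)
  eps <- with_seed(seed, stats::rnorm(length(x_log)))
  u <- rho_log * t_hat + sqrt(1 - rho_log^2) * eps
  exp(meanlog_p + sdlog_p * u)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  colnames(g) <- names(alpha)
  g / rowSums(g)
}

# --- defect placement ---------------------------------------------------------

# Values to inject as outliers for one measure: placed z_inj pre-injection
# log-scale SDs from the pre-injection log mean, alternating sides; for
# proportion measures the high side is abandoned when it would exceed 0.95.
outlier_values <- function(v_clean, k, z_inj, proportion = FALSE) {
  lv <- log(v_clean)
  mu <- mean(lv)
  s <- stats::sd(lv)
  sides <- rep(c(1, -1), length.out = k)
  vals <- exp(mu + sides * z_inj * s)
  if (proportion) {
    hi_bad <- sides > 0 & vals > 0.95
    vals[hi_bad] <- exp(mu - z_inj * s)
  }
  vals
}

# Single-pass log-scale outlier mask (the QC rule), over non-missing values.
log_outlier_flag <- function(v, k = 3) {
  ok <- !is.na(v) & v > 0
  lv <- log(v[ok])
  s <- stats::sd(lv)
  flag <- rep(FALSE, length(v))
  if (!is.finite(s) || s == 0) return(flag)
  flag[ok] <- abs(lv - mean(lv)) >= k * s
  flag
}

# --- population simulation ----------------------------------------------------

#' Simulate a participant table
#'
#' Generates one row per participant with demographics, laboratory
#' phenotypes, DNAm predictions and QC defects exactly as configured:
#' row counts per group equal `group_sizes`; exactly `n_topcoded` records
#' carry age 85; exactly `n_sex_mismatch` records have a discordant
#' DNAm-predicted sex; injected outliers are the only observations beyond
#' 3 log-scale SDs of their measure; missing values are placed per the
#' configured counts. Defect row sets are disjoint where the QC audit
#' requires exact reproduction (mismatches never overlap other defects;
#' within a measure, missing and outlier rows never overlap).
#'
#' Deterministic: the same config (including seed) yields a byte-identical
#' table. Random streams are split per (predictor, group) so adding a
#' predictor does not perturb the others' draws.
#'
#' @param config a [sim_config()].
#' @return a `data.frame`, one row per participant, with attribute
#'   `truth` = [truth_table()] of the generating parameters.
#' @export
simulate_population <- function(config) {
  config <- validate_sim_config(config)
  master <- config$seed
  groups <- names(config$group_sizes)
  n_g <- config$group_sizes
  n <- sum(n_g)
  group_rows <- split(seq_len(n), rep(seq_along(groups), n_g))
  names(group_rows) <- groups

  specs <- predictor_specs(config$predictors)
  measures_needed <- unique(vapply(specs, `[[`, "", "measure"))
  need_cells <- any(cell_measures() %in% measures_needed)

  tbl <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    race_ethnicity = rep(groups, times = n_g),
    stringsAsFactors = FALSE
  )

  # demographics, per group
  sex <- character(n)
  age_true <- numeric(n)
  education <- character(n)
  pir <- numeric(n)
  for (g in groups) {
    r <- group_rows[[g]]
    k <- length(r)
    n_male <- round(k * config$sex_fraction_male)
    sx <- rep("female", k)
    sx[with_seed(derive_seed(master, "sex", g), sample.int(k, n_male))] <- "male"
    sex[r] <- sx
    age_true[r] <- with_seed(derive_seed(master, "age", g),
                             stats::runif(k, config$age_range[1],
                                          config$age_range[2]))
    education[r] <- with_seed(
      derive_seed(master, "education", g),
      sample(education_levels(), k, replace = TRUE,
             prob = c(0.22, 0.20, 0.26, 0.18, 0.10, 0.04)))
    pir[r] <- with_seed(derive_seed(master, "pir", g),
                        pmin(5, stats::rlnorm(k, log(2), 0.6)))
  }

  # defect rows (pooled): mismatches first, everything else from the rest
  mm_rows <- with_seed(derive_seed(master, "defect", "sexmismatch"),
                       sort(sample.int(n, config$n_sex_mismatch)))
  pool <- setdiff(seq_len(n), mm_rows)
  top_rows <- with_seed(derive_seed(master, "defect", "topcode"),
                        sort(sample(pool, config$n_topcoded)))
  topcoded <- seq_len(n) %in% top_rows
  if (config$n_topcoded > 0) {
    age_true[top_rows] <- with_seed(derive_seed(master, "topage"),
                                    stats::runif(config$n_topcoded, 85, 95))
  }

  miss_rows <- list()
  out_rows <- list()
  n_missing_of <- function(m) {
    key <- if (m %in% cell_measures()) "cells" else m
    unname(config$missingness[key]) %||% 0L
  }
  n_miss <- vapply(lab_measures(), function(m) {
    v <- n_missing_of(m); if (is.na(v)) 0L else as.integer(v)
  }, 1L)
  n_out <- vapply(lab_measures(), function(m) {
    v <- unname(config$n_outliers[m]); if (is.na(v)) 0L else as.integer(v)
  }, 1L)

  # cells: one missing set shared by the three proportions, outlier sets
  # per measure, all mutually disjoint
  cm <- cell_measures()
  k_cells <- n_miss[cm[1]] + sum(n_out[cm])
  cell_defect <- with_seed(derive_seed(master, "defect", "cells"),
                           sample(pool, k_cells))
  cell_miss <- cell_defect[seq_len(n_miss[cm[1]])]
  rest <- setdiff(cell_defect, cell_miss)
  for (m in cm) {
    miss_rows[[m]] <- sort(cell_miss)
    out_rows[[m]] <- sort(rest[seq_len(n_out[m])])
    rest <- setdiff(rest, out_rows[[m]])
  }
  for (m in setdiff(lab_measures(), cm)) {
    k <- n_miss[m] + n_out[m]
    rows <- with_seed(derive_seed(master, "defect", m), sample(pool, k))
    miss_rows[[m]] <- sort(rows[seq_len(n_miss[m])])
    out_rows[[m]] <- sort(setdiff(rows, miss_rows[[m]]))
  }

  # laboratory phenotypes (clean base values first)
  pheno <- list()
  dists <- config$phenotype_distributions
  for (m in intersect(c("b2m", "cystatin_c", "crp", "hba1c", "telomere"),
                      measures_needed)) {
    d <- dists[[m]]
    v <- numeric(n)
    for (g in groups) {
      r <- group_rows[[g]]
      t <- with_seed(derive_seed(master, "pheno", m, g),
                     rtnorm_std(length(r), d$trunc))
      v[r] <- exp(d$meanlog + d$sdlog * t)
    }
    pheno[[m]] <- v
  }
  if (need_cells) {
    alpha <- dists$cells$alpha
    props <- matrix(NA_real_, n, 3,
                    dimnames = list(NULL, cm))
    for (g in groups) {
      r <- group_rows[[g]]
      p <- with_seed(derive_seed(master, "pheno", "cells", g),
                     rdirichlet(length(r), alpha))
      props[r, ] <- p[, cm]
    }
    props <- clean_cell_draws(props, miss_rows, out_rows, mm_rows, alpha,
                              master)
    for (m in cm) pheno[[m]] <- props[, m]
  }

  # planned injected outlier values, computed from the clean base values
  # visible to the QC rule (non-missing, sex-concordant rows)
  inject <- list()
  for (m in intersect(lab_measures(), measures_needed)) {
    if (n_out[m] == 0) next
    visible <- setdiff(seq_len(n), union(miss_rows[[m]], mm_rows))
    clean_vis <- setdiff(visible, out_rows[[m]])
    z_inj <- if (m %in% cm) 4.5 else 6
    inject[[m]] <- outlier_values(pheno[[m]][clean_vis], n_out[m], z_inj,
                                  proportion = m %in% cm)
  }

  # DNAm predictions, per (predictor, group), built on the clean base.
  # When any cell measure is in play the full six-column DNAm cell panel is
  # emitted (needed as covariates by the fully-adjusted regressions), using
  # registry-default correlations for cell predictors not under study.
  gen_predictors <- config$predictors
  if (need_cells) {
    extra <- setdiff(cell_measures(), gen_predictors)
    gen_predictors <- c(gen_predictors, extra)
  }
  full_rho <- config$target_correlation
  full_bias <- config$prediction_bias
  for (p in setdiff(gen_predictors, rownames(full_rho))) {
    full_rho <- rbind(full_rho, matrix(default_target_correlations()[p],
                                       1, ncol(full_rho),
                                       dimnames = list(p, colnames(full_rho))))
    full_bias <- rbind(full_bias, matrix(0, 1, ncol(full_bias),
                                         dimnames = list(p, colnames(full_bias))))
  }
  pred <- list()
  scales <- config$prediction_scales
  for (p in gen_predictors) {
    spec <- predictor_spec(p)
    rho <- full_rho[p, ]
    bias <- full_bias[p, ]
    col <- numeric(n)
    for (g in groups) {
      r <- group_rows[[g]]
      sd_pg <- derive_seed(master, "pred", p, g)
      if (spec$family == "clock") {
        ref <- !topcoded[r]
        col[r] <- generate_correlated_pair(age_true[r], rho[g], bias[g],
                                           noise_seed = sd_pg,
                                           reference = ref)
      } else if (spec$measure %in% cm) {
        sc <- scales[[p]]
        x <- pheno[[spec$measure]][r]
        col[r] <- pmax(0.001, generate_correlated_pair(
          x, rho[g], bias[g], noise_seed = sd_pg,
          location = sc$mean, scale = sc$sd))
      } else {
        d <- dists[[spec$measure]]
        sc <- scales[[p]]
        x_log <- log(pheno[[spec$measure]][r])
        raw <- gen_link_pair(x_log, d$sdlog, d$trunc, rho[g],
                             sc$meanlog, sc$sdlog, sd_pg)
        if (spec$family == "telomere") {
          # bias is in analysis units (kbp); the kbp map is affine so the
          # target correlation is unaffected
          col[r] <- (3274 + 2413 * raw) / 1000 + bias[g]
        } else {
          raw <- raw + bias[g]
          if (any(raw <= 0)) {
            stop("prediction_bias drives ", p, " predictions non-positive",
                 call. = FALSE)
          }
          col[r] <- raw
        }
      }
    }
    pred[[p]] <- col
  }

  # inject outliers and blank missing values in the emitted phenotypes
  for (m in names(pheno)) {
    if (!is.null(inject[[m]])) pheno[[m]][out_rows[[m]]] <- inject[[m]]
    pheno[[m]][miss_rows[[m]]] <- NA_real_
  }

  # assemble emitted columns
  tbl$sex <- sex
  tbl$age_years <- ifelse(topcoded, 85, age_true)
  tbl$age_topcoded <- topcoded
  tbl$education <- education
  tbl$pir <- pir
  lab_cols <- c(b2m = "b2m_mg_l", cystatin_c = "cystatin_c_mg_l",
                crp = "crp_mg_l", hba1c = "hba1c_pct",
                telomere = "telomere_ts_ratio",
                lymphocytes = "lymphocyte_prop", monocytes = "monocyte_prop",
                neutrophils = "neutrophil_prop")
  for (m in names(pheno)) tbl[[lab_cols[m]]] <- pheno[[m]]

  for (p in names(pred)) {
    spec <- predictor_spec(p)
    if (p == "lymphocytes") next  # emitted as split components below
    v <- pred[[p]]
    if (spec$prediction_transform == "exponentiate") {
      v <- log(v)  # stored on the log scale, exponentiated during QC
    }
    tbl[[spec$prediction_column]] <- v
  }

  if ("lymphocytes" %in% names(pred)) {
    split_alpha <- scales$lymphocyte_split
    frac <- matrix(NA_real_, n, 3, dimnames = list(NULL, names(split_alpha)))
    for (g in groups) {
      r <- group_rows[[g]]
      frac[r, ] <- with_seed(derive_seed(master, "split", g),
                             rdirichlet(length(r), split_alpha))
    }
    total <- pred[["lymphocytes"]]
    tbl$dnam_b <- total * frac[, "b"]
    tbl$dnam_cd4t <- total * frac[, "cd4t"]
    tbl$dnam_cd8t <- total * frac[, "cd8t"]
  }
  if (need_cells) {
    nk <- scales$nk
    v <- numeric(n)
    for (g in groups) {
      r <- group_rows[[g]]
      v[r] <- with_seed(derive_seed(master, "pred", "nk", g),
                        stats::rlnorm(length(r), nk$meanlog, nk$sdlog))
    }
    tbl$dnam_nk <- v
  }

  tbl$dnam_predicted_sex <- tbl$sex
  tbl$dnam_predicted_sex[mm_rows] <- ifelse(tbl$sex[mm_rows] == "male",
                                            "female", "male")

  validate_participants(tbl)
  attr(tbl, "truth") <- truth_table(config)
  tbl
}

# Redraw Dirichlet rows until the only observations at or beyond
# (3 - margin) log-scale SDs are the planned injected outliers. The margin
# keeps natural draws clear of the QC threshold even after the small moment
# shifts caused by removing sex-mismatched rows downstream.
clean_cell_draws <- function(props, miss_rows, out_rows, mm_rows, alpha,
                             master, margin = 0.15, max_iter = 50L) {
  cm <- colnames(props)
  n <- nrow(props)
  for (iter in seq_len(max_iter)) {
    bad <- integer(0)
    for (m in cm) {
      visible <- setdiff(seq_len(n), union(miss_rows[[m]], mm_rows))
      clean_vis <- setdiff(visible, out_rows[[m]])
      v <- props[, m]
      # provisional injected values for this iteration's moment estimates
      if (length(out_rows[[m]])) {
        v[out_rows[[m]]] <- outlier_values(v[clean_vis],
                                           length(out_rows[[m]]), 4.5,
                                           proportion = TRUE)
      }
      lv <- log(v[visible])
      s <- stats::sd(lv)
      flagged <- visible[abs(lv - mean(lv)) >= (3 - margin) * s]
      bad <- union(bad, setdiff(flagged, out_rows[[m]]))
    }
    bad <- setdiff(bad, unique(unlist(miss_rows[cm])))
    if (!length(bad)) return(props)
    redraw <- with_seed(derive_seed(master, "clean", "cells", iter),
                        rdirichlet(length(bad), alpha))
    props[bad, ] <- redraw[, cm, drop = FALSE]
  }
  stop("cell-draw cleaning did not converge", call. = FALSE)
}

# Invariant checks on an emitted participant table.
validate_participants <- function(tbl) {
  prop_cols <- intersect(c("lymphocyte_prop", "monocyte_prop",
                           "neutrophil_prop"), names(tbl))
  for (cl in prop_cols) {
    v <- tbl[[cl]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("proportion column ", cl, " outside [0, 1]", call. = FALSE)
    }
  }
  if (any(tbl$age_years < 50)) stop("ages below 50 generated", call. = FALSE)
  if (any(tbl$age_topcoded & tbl$age_years != 85)) {
    stop("top-coded rows must carry age 85", call. = FALSE)
  }
  dnam_cells <- intersect(c("dnam_b", "dnam_cd4t", "dnam_cd8t", "dnam_nk",
                            "dnam_monocyte", "dnam_neutrophil"), names(tbl))
  if (length(dnam_cells) == 6) {
    s <- rowSums(tbl[dnam_cells])
    n_off <- sum(s < 0.95 | s > 1.05)
    if (n_off > 0) {
      warning(sprintf(
        "%d of %d rows have DNAm cell-proportion sums outside [0.95, 1.05] %s",
        n_off, nrow(tbl),
        "(deconvolution-style estimates are not constrained to sum to 1)"),
        call. = FALSE)
    }
  }
  invisible(tbl)
}

#' Generating parameters of a simulated cohort
#'
#' One row per (predictor, group) with the analysis-scale correlation and
#' additive bias the generator targeted, for parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns predictor, group, true_rho, true_bias.
#' @export
truth_table <- function(config) {
  config <- validate_sim_config(config)
  groups <- names(config$group_sizes)
  out <- expand.grid(predictor = config$predictors, group = groups,
                     stringsAsFactors = FALSE)
  out$true_rho <- config$target_correlation[cbind(out$predictor, out$group)]
  out$true_bias <- config$prediction_bias[cbind(out$predictor, out$group)]
  out
}

#' Run a simulation and write its artefacts to a directory
#'
#' Writes `participants.tsv` (tab-delimited, one-line header, missing values
#' as empty fields), `truth.tsv`, and the round-trippable `config.json`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the participant table.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- simulate_population(config)
  write_tsv(tbl, file.path(dir, "participants.tsv"))
  write_tsv(attr(tbl, "truth"), file.path(dir, "truth.tsv"))
  write_sim_config(config, file.path(dir, "config.json"))
  invisible(tbl)
}

#' Read a participant table written by [write_simulation()]
#'
#' @param path path to a tab-delimited participant table.
#' @return data.frame.
#' @export
read_population <- function(path) {
  read_tsv(path)
}
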