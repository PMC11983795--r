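# Simulation configuration: the stated world the generator emulates.

# Laboratory measures subject to missingness and the log-scale outlier rule.
lab_measures <- function() {
  c("b2m", "cystatin_c", "crp", "hba1c", "telomere",
    "lymphocytes", "monocytes", "neutrophils")
}

cell_measures <- function() c("lymphocytes", "monocytes", "neutrophils")

#' Default marginal distributions of the laboratory phenotypes
#'
#' Positive-valued measures are log-normal with the underlying normal
#' truncated at `trunc` standard deviations (so that, by construction, no
#' un-injected draw can trip the 3-SD log-scale outlier rule). The three
#' complete-blood-count proportions come from one Dirichlet draw over
#' (lymphocytes, monocytes, neutrophils, other granulocytes). Locations and
#' scales are realistic for US adults 50+ but are placeholders: within-group
#' phenotype distributions are not published for the emulated cohort.
#'
#' @return named list of per-measure distribution parameters.
#' @export
default_phenotype_distributions <- function() {
  list(
    b2m        = list(type = "lognormal", meanlog = log(1.9),  sdlog = 0.30, trunc = 2.6),
    cystatin_c = list(type = "lognormal", meanlog = log(0.95), sdlog = 0.25, trunc = 2.6),
    crp        = list(type = "lognormal", meanlog = log(2.0),  sdlog = 1.00, trunc = 2.6),
    hba1c      = list(type = "lognormal", meanlog = log(5.5),  sdlog = 0.12, trunc = 2.6),
    telomere   = list(type = "lognormal", meanlog = log(1.0),  sdlog = 0.18, trunc = 2.6),
    cells      = list(type = "dirichlet",
                      alpha = c(lymphocytes = 0.30, monocytes = 0.08,
                                neutrophils = 0.58, other = 0.04) * 70)
  )
}

#' Default location/scale of the DNAm predictions
#'
#' Predictions of positive lab measures are generated on the log scale
#' (location `meanlog`, scale `sdlog`); cell-proportion predictions on the
#' raw scale (`mean`, `sd`). Clock predictions take their location/scale
#' from the observed age distribution and have no entry here.
#' `lymphocyte_split` is the Dirichlet concentration used to split the
#' total lymphocyte prediction into B / CD4+ T / CD8+ T components; `nk`
#' parameterises the independent natural-killer-cell estimate.
#'
#' @return named list of per-predictor scale parameters.
#' @export
default_prediction_scales <- function() {
  list(
    dnamtl      = list(meanlog = log(1.0),  sdlog = 0.18),
    b2m         = list(meanlog = log(1.9),  sdlog = 0.30),
    crp         = list(meanlog = log(2.0),  sdlog = 1.00),
    cystatin_c  = list(meanlog = log(0.95), sdlog = 0.25),
    hba1c       = list(meanlog = log(5.5),  sdlog = 0.12),
    lymphocytes = list(mean = 0.30, sd = 0.055),
    monocytes   = list(mean = 0.08, sd = 0.020),
    neutrophils = list(mean = 0.58, sd = 0.060),
    nk          = list(meanlog = log(0.045), sdlog = 0.25),
    lymphocyte_split = c(b = 0.20, cd4t = 0.55, cd8t = 0.25) * 200
  )
}

# Expand a correlation/bias specification into a predictor x group matrix.
normalize_param_matrix <- function(x, predictors, groups, defaults, what) {
  out <- matrix(NA_real_, length(predictors), length(groups),
                dimnames = list(predictors, groups))
  if (is.null(x)) {
    out[] <- defaults[predictors]
  } else if (is.matrix(x)) {
    if (!all(predictors %in% rownames(x)) || !all(groups %in% colnames(x))) {
      stop(what, " matrix must have predictor rownames and group colnames",
           call. = FALSE)
    }
    out[] <- x[predictors, groups]
  } else if (is.list(x)) {
    out[] <- defaults[predictors]
    for (p in intersect(names(x), predictors)) {
      v <- x[[p]]
      if (is.null(names(v))) out[p, ] <- v else {
        out[p, names(v)] <- unlist(v)
      }
    }
  } else if (is.numeric(x) && !is.null(names(x))) {
    out[] <- defaults[predictors]
    keep <- intersect(names(x), predictors)
    out[keep, ] <- x[keep]
  } else if (is.numeric(x) && length(x) == 1L) {
    out[] <- x
  } else {
    stop("cannot interpret ", what, " specification", call. = FALSE)
  }
  if (anyNA(out)) stop(what, " has unresolved entries", call. = FALSE)
  out
}

#' Build a simulation configuration
#'
#' Describes a synthetic cohort with the demographic structure of the
#' NHANES 1999-2002 DNAm subsample: five race/ethnicity groups, two sexes,
#' ages 50-84 plus a block of top-coded 85s, per-predictor and per-group
#' target correlations between each laboratory phenotype and its DNAm
#' prediction, injected extreme outliers, sex-prediction mismatches, and
#' per-measure missingness.
#'
#' `target_correlation` is the Pearson correlation on the *analysis* scale
#' (after the QC transforms: kbp conversion, exponentiation of log-scale
#' predictions) and may be given as a single number, a named per-predictor
#' vector, a predictor-by-group matrix, or a nested list.
#'
#' @param seed master seed; every random stream is derived from it.
#' @param group_sizes named counts per race/ethnicity group (default: the
#'   emulated cohort's 694/159/1005/533/81).
#' @param sex_fraction_male proportion male (default 1255/2472).
#' @param age_range numeric length-2, observed (non-top-coded) age range.
#' @param n_topcoded number of records recorded as exactly 85 years.
#' @param predictors subset of [predictor_names()] to generate.
#' @param target_correlation see above; default [default_target_correlations()].
#' @param prediction_bias additive offset, phenotype units (default 0).
#' @param phenotype_distributions see [default_phenotype_distributions()].
#' @param prediction_scales see [default_prediction_scales()].
#' @param n_outliers named per-measure counts of injected log-scale outliers.
#' @param n_sex_mismatch records whose DNAm-predicted sex is flipped.
#' @param missingness named per-measure counts of missing lab values; the
#'   key `cells` blanks all three blood-count proportions jointly.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       group_sizes = c("Mexican American" = 694L,
                                       "Other Hispanic" = 159L,
                                       "NH White" = 1005L,
                                       "NH Black" = 533L,
                                       "Other/Multiracial" = 81L),
                       sex_fraction_male = 1255 / 2472,
                       age_range = c(50, 84),
                       n_topcoded = 126L,
                       predictors = predictor_names(),
                       target_correlation = NULL,
                       prediction_bias = NULL,
                       phenotype_distributions = default_phenotype_distributions(),
                       prediction_scales = default_prediction_scales(),
                       n_outliers = c(b2m = 43L, cystatin_c = 39L, crp = 10L,
                                      hba1c = 63L, telomere = 13L,
                                      lymphocytes = 21L, monocytes = 22L,
                                      neutrophils = 27L),
                       n_sex_mismatch = 60L,
                       missingness = c(cystatin_c = 28L, b2m = 31L,
                                       hba1c = 1L, telomere = 2L,
                                       cells = 13L)) {
  groups <- names(group_sizes)
  cfg <- list(
    seed = as.integer(seed),
    group_sizes = stats::setNames(as.integer(group_sizes), groups),
    sex_fraction_male = sex_fraction_male,
    age_range = as.numeric(age_range),
    n_topcoded = as.integer(n_topcoded),
    predictors = predictors,
    target_correlation = normalize_param_matrix(
      target_correlation, predictors, groups,
      default_target_correlations(), "target_correlation"),
    prediction_bias = normalize_param_matrix(
      prediction_bias, predictors, groups,
      stats::setNames(rep(0, length(predictor_names())), predictor_names()),
      "prediction_bias"),
    phenotype_distributions = phenotype_distributions,
    prediction_scales = prediction_scales,
    n_outliers = stats::setNames(as.integer(n_outliers), names(n_outliers)),
    n_sex_mismatch = as.integer(n_sex_mismatch),
    missingness = stats::setNames(as.integer(missingness), names(missingness))
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks the invariants of the stated world: correlations strictly inside
#' (-1, 1), group sizes >= 2, proportions in \[0, 1\], and feasibility of
#' the requested defect counts given that defect row sets must be disjoint
#' enough for the QC audit to reproduce them exactly.
#'
#' @param cfg a `sim_config`.
#' @return the config, invisibly amended (counts coerced to integer).
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$group_sizes) < 1 || is.null(names(cfg$group_sizes))) {
    stop("group_sizes must be a named vector", call. = FALSE)
  }
  if (any(cfg$group_sizes < 2L)) stop("group sizes must be >= 2", call. = FALSE)
  if (cfg$sex_fraction_male < 0 || cfg$sex_fraction_male > 1) {
    stop("sex_fraction_male must be in [0, 1]", call. = FALSE)
  }
  if (any(abs(cfg$target_correlation) >= 1)) {
    stop("target correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  unknown <- setdiff(cfg$predictors, predictor_names())
  if (length(unknown)) {
    stop("unknown predictors: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(cfg$age_range) != 2 || cfg$age_range[1] < 50 ||
      cfg$age_range[2] >= 85 || diff(cfg$age_range) <= 0) {
    stop("age_range must be increasing and within [50, 85)", call. = FALSE)
  }
  bad <- setdiff(names(cfg$n_outliers), lab_measures())
  if (length(bad)) stop("unknown outlier measures: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(names(cfg$missingness), c(lab_measures(), "cells"))
  if (length(bad)) stop("unknown missingness measures: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(cfg$n_outliers < 0) || any(cfg$missingness < 0) ||
      cfg$n_sex_mismatch < 0 || cfg$n_topcoded < 0) {
    stop("defect counts must be non-negative", call. = FALSE)
  }
  n_total <- sum(cfg$group_sizes)
  if (cfg$n_sex_mismatch > n_total) {
    stop("n_sex_mismatch exceeds cohort size", call. = FALSE)
  }
  pool <- n_total - cfg$n_sex_mismatch
  if (cfg$n_topcoded > pool) {
    stop("infeasible counts: n_topcoded exceeds available rows", call. = FALSE)
  }
  # cells-missing plus the three cell outlier sets are mutually disjoint
  n_cell_defects <- sum(cfg$missingness["cells"], na.rm = TRUE) +
    sum(cfg$n_outliers[intersect(names(cfg$n_outliers), cell_measures())])
  if (n_cell_defects > pool) {
    stop("infeasible counts: cell defects exceed available rows", call. = FALSE)
  }
  for (m in setdiff(lab_measures(), cell_measures())) {
    k <- sum(cfg$missingness[m], na.rm = TRUE) +
      sum(cfg$n_outliers[m], na.rm = TRUE)
    if (k > pool) {
      stop("infeasible counts for measure ", m, call. = FALSE)
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes),
                                 x$group_sizes), collapse = ", "), "\n")
  cat(sprintf("  %d predictors; %d top-coded; %d sex mismatches\n",
              length(x$predictors), x$n_topcoded, x$n_sex_mismatch))
  invisible(x)
}

#' Write / read a simulation configuration as JSON
#'
#' The round trip is lossless: `read_sim_config(write_sim_config(cfg, f))`
#' reproduces `cfg` exactly.
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `write_sim_config` the path; `read_sim_config` a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  ser <- unclass(cfg)
  ser$target_correlation <- matrix_to_nested(cfg$target_correlation)
  ser$prediction_bias <- matrix_to_nested(cfg$prediction_bias)
  # named atomic vectors must go out as objects, not bare arrays
  ser$group_sizes <- as.list(cfg$group_sizes)
  ser$n_outliers <- as.list(cfg$n_outliers)
  ser$missingness <- as.list(cfg$missingness)
  # digits = I(17): significant digits, enough for a lossless double
  # round trip (digits = NA truncates to 15 in some jsonlite versions)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(
    seed = ser$seed,
    group_sizes = unlist(ser$group_sizes),
    sex_fraction_male = ser$sex_fraction_male,
    age_range = ser$age_range,
    n_topcoded = ser$n_topcoded,
    predictors = ser$predictors,
    target_correlation = nested_to_matrix(ser$target_correlation),
    prediction_bias = nested_to_matrix(ser$prediction_bias),
    phenotype_distributions = rebuild_distributions(ser$phenotype_distributions),
    prediction_scales = rebuild_scales(ser$prediction_scales),
    n_outliers = unlist(ser$n_outliers),
    n_sex_mismatch = ser$n_sex_mismatch,
    missingness = unlist(ser$missingness)
  )
}

matrix_to_nested <- function(m) {
  out <- lapply(rownames(m), function(p) as.list(m[p, ]))
  names(out) <- rownames(m)
  out
}

nested_to_matrix <- function(x) {
  groups <- names(x[[1]])
  m <- do.call(rbind, lapply(x, function(row) unlist(row)[groups]))
  rownames(m) <- names(x)
  colnames(m) <- groups
  m
}

rebuild_distributions <- function(x) {
  lapply(x, function(d) {
    d <- as.list(d)
    if (!is.null(d$alpha)) d$alpha <- unlist(d$alpha)
    d
  })
}

rebuild_scales <- function(x) {
  out <- lapply(x, function(d) if (is.list(d)) as.list(d) else unlist(d))
  out$lymphocyte_split <- unlist(x$lymphocyte_split)
  out
}
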