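# Interaction OLS models (minimal and fully adjusted) with a fixed-budget
# Bonferroni correction.

# Fixed test budgets: 15 predictors x 5 race groups x 2 sexes for the
# minimal adjustment; 12 non-cell predictors x 5 x 2 for the full one.
bonferroni_budgets <- c(minimal = 150L, full = 120L)

#' Bonferroni adjustment with a fixed test budget
#'
#' @param p unadjusted p-value(s) in \[0, 1\].
#' @param m test budget, integer >= 1.
#' @return `min(1, p * m)`, vectorised over `p`.
#' @examples
#' bonferroni(0.0002, 150)  # 0.03
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (m < 1 || m != round(m)) stop("m must be a positive integer",
                                   call. = FALSE)
  pmin(1, p * m)
}

dnam_cell_covariates <- function() {
  c("dnam_cd8t", "dnam_cd4t", "dnam_nk", "dnam_b", "dnam_monocyte",
    "dnam_neutrophil")
}

#' Fit an interaction model for effect modification by race/ethnicity or sex
#'
#' Ordinary least squares with the DNAm prediction as the outcome and the
#' phenotypic trait, the modifier (dummy-coded, reference NH White or
#' female), and their interaction as predictors. The minimal adjustment
#' adds the other demographic variable (sex for the race models, race for
#' the sex models); the full adjustment further adds education category,
#' poverty-to-income ratio, and the six DNAm cell-proportion estimates,
#' and is refused for the cell-proportion predictors themselves. The
#' phenotype main effect is the reference-group slope; each interaction
#' term is the additional slope in that group. Variables enter on their
#' converted natural scales (a slope of 1 = perfect linear association).
#'
#' Rows with missing covariates are dropped listwise for this model only,
#' with the count recorded. Bonferroni-adjusted p-values use the fixed
#' budget (150 minimal / 120 full) unless `m_tests` overrides it.
#'
#' @param aset analysis set from [build_analysis_set()] (list or `data`).
#' @param modifier `"race_ethnicity"` or `"sex"`.
#' @param adjustment `"minimal"` or `"full"`.
#' @param spec the predictor's [predictor_spec()] (or its name).
#' @param m_tests optional Bonferroni budget override (e.g. the number of
#'   tests actually run).
#' @param alpha significance level for the CI and tiers.
#' @return object of class `regression_fit` with a tidy coefficient table
#'   (`$coefficients`: term, role, estimate, ci_low, ci_high, p_value,
#'   bonferroni_p), `$n_used`, `$n_dropped`, `$model`.
#' @export
fit_interaction_model <- function(aset,
                                  modifier = c("race_ethnicity", "sex"),
                                  adjustment = c("minimal", "full"),
                                  spec, m_tests = NULL, alpha = 0.05) {
  modifier <- match.arg(modifier)
  adjustment <- match.arg(adjustment)
  if (is.character(spec)) spec <- predictor_spec(spec)
  if (is.list(aset) && !is.data.frame(aset) && !is.null(aset$data)) {
    aset <- aset$data
  }
  if (adjustment == "full" && spec$family == "cell") {
    stop("full adjustment is not defined for cell-proportion predictors ",
         "(they are excluded from the fully-adjusted analysis)",
         call. = FALSE)
  }
  other <- if (modifier == "race_ethnicity") "sex" else "race_ethnicity"
  covars <- other
  if (adjustment == "full") {
    covars <- c(covars, "education", "pir", dnam_cell_covariates())
  }
  need <- c("phenotype", "prediction", modifier, covars)
  missing_cols <- setdiff(need, names(aset))
  if (length(missing_cols)) {
    stop("analysis set lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  df <- aset[need]
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]

  ref <- if (modifier == "race_ethnicity") "NH White" else "female"
  if (!ref %in% df[[modifier]]) {
    stop("reference group '", ref, "' absent from the data", call. = FALSE)
  }
  df[[modifier]] <- stats::relevel(factor(df[[modifier]]), ref = ref)
  if (other %in% names(df)) df[[other]] <- factor(df[[other]])
  if ("education" %in% names(df)) {
    df$education <- factor(df$education, levels = education_levels())
  }
  empty <- names(which(table(df[[modifier]]) == 0))
  if (length(empty)) {
    stop("rank-deficient design: empty modifier category ",
         paste(empty, collapse = ", "), call. = FALSE)
  }

  fml <- stats::as.formula(paste(
    "prediction ~ phenotype *", modifier, "+",
    paste(covars, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; offending term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 1 - alpha)
  m <- m_tests %||% bonferroni_budgets[[adjustment]]
  terms <- rownames(sm)
  role <- ifelse(terms == "phenotype", "phenotype_main",
          ifelse(grepl("^phenotype:", terms), "interaction",
          ifelse(grepl(paste0("^", modifier), terms), "group_main",
          ifelse(terms == "(Intercept)", "intercept", "covariate"))))
  coefs <- data.frame(
    term = terms, role = role,
    estimate = sm[, "Estimate"], std_error = sm[, "Std. Error"],
    ci_low = ci[, 1], ci_high = ci[, 2],
    p_value = sm[, "Pr(>|t|)"],
    bonferroni_p = bonferroni(sm[, "Pr(>|t|)"], m),
    stringsAsFactors = FALSE)
  rownames(coefs) <- NULL

  out <- list(predictor = spec$name, modifier = modifier,
              adjustment = adjustment, reference_group = ref,
              m_tests = m, alpha = alpha, coefficients = coefs,
              n_used = nrow(df), n_dropped = n_dropped, model = fit)
  class(out) <- "regression_fit"
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s | modifier: %s | adjustment: %s (m = %d)\n",
              x$predictor, x$modifier, x$adjustment, x$m_tests))
  cat(sprintf("  reference: %s; n = %d (%d dropped listwise)\n",
              x$reference_group, x$n_used, x$n_dropped))
  show <- x$coefficients[x$coefficients$role %in%
                           c("phenotype_main", "interaction"), ]
  print(show[, c("term", "estimate", "ci_low", "ci_high", "p_value",
                 "bonferroni_p")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Significance tiers for the coefficient table
#'
#' `significant` if the Bonferroni-adjusted p-value is below `alpha`,
#' `suggestive` if only the unadjusted p-value is, else `null` — the
#' "**"/"*" annotation convention for interaction terms.
#'
#' @param fit a `regression_fit`.
#' @param alpha significance level (default 0.05).
#' @return the coefficient table with a `tier` column appended.
#' @export
significance_tiers <- function(fit, alpha = 0.05) {
  coefs <- if (inherits(fit, "regression_fit")) fit$coefficients else fit
  coefs$tier <- ifelse(coefs$bonferroni_p < alpha, "significant",
                ifelse(coefs$p_value < alpha, "suggestive", "null"))
  coefs
}
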