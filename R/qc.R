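# Exclusion rules, unit conversions and derived variables, with a full
# removal audit trail.

new_qc_report <- function() {
  structure(list(counts = integer(0), removed = list()), class = "qc_report")
}

qc_record <- function(report, rule, ids) {
  report$counts[rule] <- length(ids)
  report$removed[[rule]] <- sort(ids)
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  if (!length(x$counts)) {
    cat("  no removals recorded\n")
    return(invisible(x))
  }
  for (rule in names(x$counts)) {
    cat(sprintf("  %-28s %6d removed\n", rule, x$counts[[rule]]))
  }
  if (!is.null(x$n_analysable)) {
    cat(sprintf("  %-28s %6d\n", "analysable n", x$n_analysable))
  }
  invisible(x)
}

#' Remove participants whose DNAm-predicted sex disagrees with reported sex
#'
#' Mislabeled-sample guard: rows where `dnam_predicted_sex != sex` are
#' dropped before any analysis.
#'
#' @param tbl participant table with `sex` and `dnam_predicted_sex` columns.
#' @return list with `table` (concordant rows) and `report` (a `qc_report`
#'   fragment with the removal count and ids).
#' @export
exclude_sex_mismatch <- function(tbl) {
  if (!all(c("sex", "dnam_predicted_sex") %in% names(tbl))) {
    stop("table must contain 'sex' and 'dnam_predicted_sex' columns",
         call. = FALSE)
  }
  bad <- tbl$dnam_predicted_sex != tbl$sex
  report <- qc_record(new_qc_report(), "sex_mismatch", tbl$id[bad])
  out <- tbl[!bad, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("every row was sex-discordant; empty table returned",
            call. = FALSE)
  }
  list(table = out, report = report)
}

#' Remove top-coded ages
#'
#' Ages recorded as exactly the top-code value (85) are censored and would
#' distort clock-fit assessment; this rule is applied only to analyses of
#' predictors with `uses_age = TRUE` (the seven clocks).
#'
#' @param tbl participant table with `age_years` (and optionally an
#'   `age_topcoded` flag, trusted when present).
#' @return list with `table` and `report` as in [exclude_sex_mismatch()].
#' @export
exclude_topcoded_age <- function(tbl) {
  if (!("age_years" %in% names(tbl))) {
    stop("table must contain 'age_years'", call. = FALSE)
  }
  bad <- if ("age_topcoded" %in% names(tbl)) {
    tbl$age_topcoded | tbl$age_years >= 85
  } else {
    tbl$age_years >= 85
  }
  report <- qc_record(new_qc_report(), "topcoded_age", tbl$id[bad])
  list(table = tbl[!bad, , drop = FALSE], report = report)
}

#' Convert a telomere T/S ratio to kilobase pairs
#'
#' `kbp = (3274 + 2413 * ts) / 1000`. Missing values propagate; negative
#' ratios are an error.
#'
#' @param ts numeric T/S ratio(s), >= 0 or NA.
#' @return telomere length in kilobase pairs.
#' @examples
#' ts_to_kbp(1.0)  # 5.687
#' @export
ts_to_kbp <- function(ts) {
  if (any(ts < 0, na.rm = TRUE)) {
    stop("T/S ratio must be non-negative", call. = FALSE)
  }
  (3274 + 2413 * ts) / 1000
}

#' Aggregate DNAm lymphocyte sub-populations
#'
#' The laboratory blood count reports total lymphocytes; the DNAm
#' deconvolution reports B cells and CD4+/CD8+ T cells separately. Their
#' sum is the comparable prediction. Sums above 1 are possible on noisy
#' deconvolution output and are returned with a warning.
#'
#' @param b,cd4,cd8 component proportions, each in \[0, 1\] (NA propagates).
#' @return summed proportion; NA where any component is missing.
#' @export
aggregate_lymphocytes <- function(b, cd4, cd8) {
  for (v in list(b, cd4, cd8)) {
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("component proportions must lie in [0, 1]", call. = FALSE)
    }
  }
  out <- b + cd4 + cd8
  if (any(out > 1, na.rm = TRUE)) {
    warning("aggregated lymphocyte proportion exceeds 1 for ",
            sum(out > 1, na.rm = TRUE), " row(s)", call. = FALSE)
  }
  out
}

#' Flag laboratory values beyond k standard deviations on the log scale
#'
#' Single-pass rule: the mean and SD of `log(values)` are computed once
#' over all non-missing entries; entries at or beyond `k` SDs from that
#' mean (inclusive, matching ">= k SD") are flagged for removal. Missing
#' entries get `keep = FALSE` but are counted as missing, not as outliers.
#' If the log-scale SD is zero the rule is vacuous and removes nothing.
#'
#' @param values numeric vector, possibly with NA.
#' @param k SD multiplier (default 3).
#' @param nonpositive what to do with values <= 0 (log undefined):
#'   `"error"` (default) or `"exclude"` (dropped with reason
#'   `nonpositive-for-log`, not counted as outliers).
#' @return list with `keep` (logical mask, same length), `n_outlier`,
#'   `n_missing`, `n_nonpositive`.
#' @export
filter_log_outliers <- function(values, k = 3,
                                nonpositive = c("error", "exclude")) {
  nonpositive <- match.arg(nonpositive)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  miss <- is.na(values)
  npos <- !miss & values <= 0
  if (any(npos) && nonpositive == "error") {
    stop("non-positive values present where log is required; ",
         "set nonpositive = \"exclude\" to drop them", call. = FALSE)
  }
  usable <- !miss & !npos
  keep <- usable
  lv <- log(values[usable])
  s <- stats::sd(lv)
  n_outlier <- 0L
  if (length(lv) >= 2 && is.finite(s) && s > 0) {
    flag <- abs(lv - mean(lv)) >= k * s
    keep[usable] <- !flag
    n_outlier <- sum(flag)
  }
  list(keep = keep, n_outlier = n_outlier, n_missing = sum(miss),
       n_nonpositive = sum(npos))
}

#' Exponentiate a log-scale prediction column
#'
#' Predictors trained on log-scale targets (CRP, HbA1c) store log-scale
#' predictions; they are exponentiated before analysis. Identity-transform
#' specs return the table unchanged.
#'
#' @param tbl participant table.
#' @param spec a [predictor_spec()].
#' @return the table with the prediction column exponentiated.
#' @export
exponentiate_predictions <- function(tbl, spec) {
  if (spec$prediction_transform != "exponentiate") return(tbl)
  tbl[[spec$prediction_column]] <- exp(tbl[[spec$prediction_column]])
  tbl
}

#' Build the analysable (phenotype, prediction) pairs for one predictor
#'
#' Composes the exclusion rules in the order used throughout: the table
#' must already be sex-concordant (see [exclude_sex_mismatch()]); then
#' top-coded ages are dropped iff the predictor uses age; rows missing the
#' phenotype or the prediction are dropped; the log-scale outlier rule is
#' applied to the laboratory-derived phenotype (never to DNAm predictions,
#' and not to chronological age); finally the unit transforms are applied
#' (T/S to kbp, exponentiation, lymphocyte aggregation).
#'
#' @param tbl sex-concordant participant table.
#' @param spec a [predictor_spec()].
#' @param k outlier SD multiplier (default 3).
#' @param nonpositive policy for non-positive lab values under the log rule
#'   (default `"exclude"`, reason `nonpositive-for-log`).
#' @return list with `data` (data.frame: id, phenotype, prediction, strata
#'   and covariate columns) and `report` (a `qc_report` with per-rule
#'   counts, removed ids, and `n_analysable`).
#' @export
build_analysis_set <- function(tbl, spec, k = 3, nonpositive = "exclude") {
  if (is.character(spec)) spec <- predictor_spec(spec)
  stopifnot(inherits(spec, "predictor_spec"))
  if (all(c("sex", "dnam_predicted_sex") %in% names(tbl)) &&
      any(tbl$sex != tbl$dnam_predicted_sex)) {
    stop("table contains sex-discordant rows; run exclude_sex_mismatch() ",
         "first", call. = FALSE)
  }
  report <- new_qc_report()
  n_in <- nrow(tbl)

  if (spec$uses_age) {
    step <- exclude_topcoded_age(tbl)
    tbl <- step$table
    report <- qc_record(report, "topcoded_age", step$report$removed[[1]])
  }

  # derive the prediction vector
  prediction <- if (spec$phenotype_transform == "sum_lymphocytes") {
    aggregate_lymphocytes(tbl$dnam_b, tbl$dnam_cd4t, tbl$dnam_cd8t)
  } else {
    tbl[[spec$prediction_column]]
  }
  if (is.null(prediction)) {
    stop("prediction column '", spec$prediction_column, "' absent",
         call. = FALSE)
  }
  phenotype <- tbl[[spec$phenotype_column]]
  if (is.null(phenotype)) {
    stop("phenotype column '", spec$phenotype_column, "' absent",
         call. = FALSE)
  }

  miss_ph <- is.na(phenotype)
  report <- qc_record(report, paste0("missing_", spec$measure),
                      tbl$id[miss_ph])
  miss_pr <- !miss_ph & is.na(prediction)
  report <- qc_record(report, "missing_prediction", tbl$id[miss_pr])
  keep <- !miss_ph & !miss_pr
  tbl <- tbl[keep, , drop = FALSE]
  phenotype <- phenotype[keep]
  prediction <- prediction[keep]

  if (spec$outlier_rule) {
    fl <- filter_log_outliers(phenotype, k = k, nonpositive = nonpositive)
    out_ids <- tbl$id[!fl$keep & phenotype > 0]
    np_ids <- tbl$id[phenotype <= 0]
    report <- qc_record(report, paste0("outlier_", spec$measure), out_ids)
    if (length(np_ids)) {
      report <- qc_record(report, "nonpositive-for-log", np_ids)
    }
    tbl <- tbl[fl$keep, , drop = FALSE]
    phenotype <- phenotype[fl$keep]
    prediction <- prediction[fl$keep]
  }

  # unit transforms on the analysis scale
  if (spec$phenotype_transform == "ts_to_kbp") phenotype <- ts_to_kbp(phenotype)
  if (spec$prediction_transform == "exponentiate") prediction <- exp(prediction)

  covars <- intersect(c("race_ethnicity", "sex", "education", "pir",
                        "dnam_cd8t", "dnam_cd4t", "dnam_nk", "dnam_b",
                        "dnam_monocyte", "dnam_neutrophil"), names(tbl))
  data <- cbind(data.frame(id = tbl$id, phenotype = phenotype,
                           prediction = prediction,
                           stringsAsFactors = FALSE),
                tbl[covars])
  rownames(data) <- NULL

  report$n_analysable <- nrow(data)
  report$n_input <- n_in
  report$predictor <- spec$name
  stopifnot(n_in == nrow(data) + length(unique(unlist(report$removed))))

  # flag strata too small to analyse
  if ("race_ethnicity" %in% names(data)) {
    cnt <- table(data$race_ethnicity)
    small <- names(cnt)[cnt < 3]
    if (length(small)) {
      warning("strata with fewer than 3 analysable rows: ",
              paste(small, collapse = ", "), call. = FALSE)
      report$unanalysable_strata <- small
    }
  }
  list(data = data, report = report)
}

#' Serialize a QC report
#'
#' Writes the removal audit both as human-readable text and as a
#' machine-readable key-value (TSV) file.
#'
#' @param report a `qc_report`.
#' @param path_txt,path_tsv output paths (either may be NULL to skip).
#' @return invisibly, a data.frame of (rule, count).
#' @export
write_qc_report <- function(report, path_txt = NULL, path_tsv = NULL) {
  df <- data.frame(rule = names(report$counts),
                   count = as.integer(report$counts),
                   stringsAsFactors = FALSE)
  if (!is.null(report$n_analysable)) {
    df <- rbind(df, data.frame(rule = "analysable_n",
                               count = report$n_analysable))
  }
  if (!is.null(path_txt)) {
    con <- file(path_txt, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
  }
  if (!is.null(path_tsv)) write_tsv(df, path_tsv)
  invisible(df)
}
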