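# Performance metrics: Pearson correlation and median absolute error,
# overall and per stratum.

#' Pearson product-moment correlation
#'
#' Computed from the direct formula; symmetric in its arguments. Zero
#' variance in either vector raises a classed error
#' (`epiperform_zero_variance`) rather than returning NaN.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed here; ",
                                 "build the analysis set first",
                                 call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx * dx)
  vy <- sum(dy * dy)
  if (vx == 0 || vy == 0) {
    stop(structure(class = c("epiperform_zero_variance", "error",
                             "condition"),
                   list(message = "zero variance: correlation undefined",
                        call = sys.call(-1))))
  }
  sum(dx * dy) / sqrt(vx * vy)
}

#' Median absolute error
#'
#' `median(|y - x|)`, in the units of `x`; the median of an even count is
#' the midpoint of the two central order statistics.
#'
#' @param x phenotype vector.
#' @param y prediction vector, same length >= 1.
#' @return non-negative scalar.
#' @export
median_abs_error <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  stats::median(abs(y - x))
}

grimage_threshold <- 0.35

#' Stratified performance metrics for one analysis set
#'
#' One row per stratum plus the overall population: n, Pearson r, MAE, and
#' the 0.35 correlation-threshold flag (meaningful for the plasma-protein
#' family, computed for all). Strata with fewer than 3 analysable rows are
#' flagged unanalysable (NA metrics) rather than reported.
#'
#' @param aset analysis set from [build_analysis_set()] (the `data`
#'   element, or the list itself).
#' @param strata_var `"race_ethnicity"`, `"sex"`, or `"overall"`.
#' @param predictor label recorded in the output (defaults to the report's
#'   predictor when `aset` is a [build_analysis_set()] result).
#' @return data.frame: predictor, stratum, n, pearson_r, mae,
#'   passes_grimage_threshold, analysable.
#' @export
stratified_metrics <- function(aset, strata_var = c("race_ethnicity", "sex",
                                                    "overall"),
                               predictor = NULL) {
  strata_var <- match.arg(strata_var)
  if (is.list(aset) && !is.data.frame(aset) && !is.null(aset$data)) {
    predictor <- predictor %||% aset$report$predictor
    aset <- aset$data
  }
  predictor <- predictor %||% NA_character_
  one <- function(stratum, x, y) {
    n <- length(x)
    if (n < 3) {
      return(data.frame(predictor = predictor, stratum = stratum, n = n,
                        pearson_r = NA_real_, mae = NA_real_,
                        passes_grimage_threshold = NA,
                        analysable = FALSE, stringsAsFactors = FALSE))
    }
    r <- tryCatch(pearson_r(x, y),
                  epiperform_zero_variance = function(e) NA_real_)
    data.frame(predictor = predictor, stratum = stratum, n = n,
               pearson_r = r, mae = median_abs_error(x, y),
               passes_grimage_threshold = if (is.na(r)) NA else
                 r > grimage_threshold,
               analysable = !is.na(r), stringsAsFactors = FALSE)
  }
  out <- one("overall", aset$phenotype, aset$prediction)
  if (strata_var != "overall") {
    if (!strata_var %in% names(aset)) {
      stop("unknown strata variable '", strata_var, "'", call. = FALSE)
    }
    for (s in unique(aset[[strata_var]])) {
      i <- aset[[strata_var]] == s
      out <- rbind(out, one(s, aset$phenotype[i], aset$prediction[i]))
    }
  }
  rownames(out) <- NULL
  out
}
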