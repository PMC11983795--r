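# Percentile-bootstrap inference on between-group differences in
# correlation and MAE, including the equal-n sensitivity variant.

# Metric values over resamples given an index matrix (n_draw x B).
# Pearson is fully vectorised over columns; MAE resamples the precomputed
# absolute errors. Degenerate (zero-variance) resamples yield NA.
boot_metric_values <- function(x, y, idx, metric) {
  if (metric == "mae") {
    d <- abs(y - x)
    dm <- matrix(d[idx], nrow(idx), ncol(idx))
    return(apply(dm, 2, stats::median))
  }
  xm <- matrix(x[idx], nrow(idx), ncol(idx))
  ym <- matrix(y[idx], nrow(idx), ncol(idx))
  n <- nrow(idx)
  sx <- colSums(xm); sy <- colSums(ym)
  sxx <- colSums(xm * xm); syy <- colSums(ym * ym)
  sxy <- colSums(xm * ym)
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cv <- sxy - sx * sy / n
  r <- cv / sqrt(vx * vy)
  r[vx <= 0 | vy <= 0] <- NA_real_
  r
}

# One group's bootstrap metric distribution: n_iter resamples of size
# n_draw (with replacement), chunked to bound memory, seeded per group.
boot_one_group <- function(x, y, metric, n_iter, n_draw, seed,
                           chunk = 2000L) {
  n <- length(x)
  out <- numeric(n_iter)
  with_seed(seed, {
    done <- 0L
    while (done < n_iter) {
      b <- min(chunk, n_iter - done)
      idx <- matrix(sample.int(n, n_draw * b, replace = TRUE), n_draw, b)
      out[done + seq_len(b)] <- boot_metric_values(x, y, idx, metric)
      done <- done + b
    }
  })
  out
}

#' Bootstrap the between-group difference of a performance metric
#'
#' Participants (phenotype/prediction pairs, jointly) are resampled with
#' replacement within each group, the metric is computed in each group per
#' iteration, and the difference `group_a - group_b` is summarised by its
#' median and 2.5th/97.5th percentiles (95% percentile CI, linear
#' interpolation between order statistics). A difference is significant
#' when the CI excludes 0. Iterations where the metric is undefined
#' (zero-variance resample) are dropped and counted, never imputed.
#'
#' Each group's resampling stream is seeded from `(seed, its label)`, so
#' swapping the two groups exactly negates the median difference and CI.
#'
#' @param pairs_a,pairs_b data.frames with `phenotype` and `prediction`
#'   columns (each group n >= 3).
#' @param metric `"pearson_r"` or `"mae"`.
#' @param n_iter bootstrap iterations (default 10000).
#' @param seed integer seed for this comparison.
#' @param n_cap resample size per group; defaults to each group's own size
#'   (the standard variant). Setting it to the smallest group's size gives
#'   the equal-n sensitivity variant.
#' @param labels length-2 character, group labels (also seed the per-group
#'   streams).
#' @return object of class `bootstrap_comparison`: a one-row data.frame
#'   with median_diff, ci_low, ci_high, significant, n_degenerate, etc.
#' @export
bootstrap_group_difference <- function(pairs_a, pairs_b,
                                       metric = c("pearson_r", "mae"),
                                       n_iter = 10000L, seed = 1L,
                                       n_cap = NULL,
                                       labels = c("A", "B")) {
  metric <- match.arg(metric)
  for (p in list(pairs_a, pairs_b)) {
    if (nrow(p) < 3) stop("each group needs at least 3 pairs", call. = FALSE)
  }
  variant <- if (is.null(n_cap)) "standard" else "equal_n"
  if (!is.null(n_cap)) {
    if (n_cap < 3) stop("n_cap must be at least 3", call. = FALSE)
    if (n_cap > min(nrow(pairs_a), nrow(pairs_b))) {
      stop("n_cap exceeds the smallest group's size", call. = FALSE)
    }
  }
  draw_a <- n_cap %||% nrow(pairs_a)
  draw_b <- n_cap %||% nrow(pairs_b)
  ma <- boot_one_group(pairs_a$phenotype, pairs_a$prediction, metric,
                       n_iter, draw_a, derive_seed(seed, "group", labels[1]))
  mb <- boot_one_group(pairs_b$phenotype, pairs_b$prediction, metric,
                       n_iter, draw_b, derive_seed(seed, "group", labels[2]))
  diffs <- ma - mb
  ok <- !is.na(diffs)
  n_degenerate <- sum(!ok)
  if (n_degenerate > 0.01 * n_iter) {
    warning(sprintf("%d of %d bootstrap iterations degenerate (>1%%)",
                    n_degenerate, n_iter), call. = FALSE)
  }
  d <- diffs[ok]
  qs <- stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
  out <- data.frame(
    group_a = labels[1], group_b = labels[2], metric = metric,
    n_a = nrow(pairs_a), n_b = nrow(pairs_b),
    n_iter = n_iter, variant = variant,
    n_cap = if (is.null(n_cap)) NA_integer_ else as.integer(n_cap),
    median_diff = stats::median(d), ci_low = qs[1], ci_high = qs[2],
    significant = qs[1] > 0 | qs[2] < 0,
    n_degenerate = n_degenerate, seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bootstrap_comparison", class(out))
  attr(out, "iterations") <- diffs
  out
}

#' Equal-n sensitivity bootstrap
#'
#' Identical to [bootstrap_group_difference()] but every group is resampled
#' at the size of the smallest group under comparison, removing sample-size
#' effects on metric precision (e.g. cap 533 for the race/ethnicity trio,
#' 1217 for the sex comparison, in the emulated cohort).
#'
#' @inheritParams bootstrap_group_difference
#' @param n_cap resample size; default the smaller of the two groups.
#' @return a `bootstrap_comparison`.
#' @export
bootstrap_equal_n <- function(pairs_a, pairs_b, metric = c("pearson_r", "mae"),
                              n_iter = 10000L,
                              n_cap = min(nrow(pairs_a), nrow(pairs_b)),
                              seed = 1L, labels = c("A", "B")) {
  bootstrap_group_difference(pairs_a, pairs_b, metric, n_iter = n_iter,
                             seed = seed, n_cap = n_cap, labels = labels)
}

# Fixed comparison orientations (sign conventions of the reported
# differences): minority groups minus NH White, Mexican American minus
# NH Black, male minus female.
canonical_pairs <- function(groups) {
  known <- list(c("Mexican American", "NH White"),
                c("NH Black", "NH White"),
                c("Mexican American", "NH Black"),
                c("male", "female"))
  pairs <- list()
  for (kp in known) {
    if (all(kp %in% groups)) pairs[[length(pairs) + 1]] <- kp
  }
  covered <- unique(unlist(pairs))
  extra <- utils::combn(groups, 2, simplify = FALSE)
  for (e in extra) {
    dup <- any(vapply(pairs, function(kp) setequal(kp, e), TRUE))
    if (!dup) pairs[[length(pairs) + 1]] <- e
  }
  pairs
}

#' All pairwise bootstrap comparisons for a set of predictors
#'
#' One row per (predictor x metric x group pair), with a fixed comparison
#' orientation and a per-row seed derived from the master seed, so any row
#' is independently reproducible. Unanalysable strata (n < 3) yield a row
#' with `status = "unanalysable"` rather than being dropped silently.
#'
#' @param analysis_sets named list (by predictor) of analysis sets from
#'   [build_analysis_set()].
#' @param groups strata to compare (e.g. the NH White / NH Black /
#'   Mexican American trio, or male/female).
#' @param strata_var column defining the groups (`"race_ethnicity"` or
#'   `"sex"`).
#' @param metrics metrics to bootstrap.
#' @param variant `"standard"` or `"equal_n"`.
#' @param n_iter iterations per comparison.
#' @param seed master seed.
#' @param n_cap equal-n cap; default, per predictor, the smallest compared
#'   group's analysable n.
#' @return data.frame of comparisons (one per row) with a `status` column.
#' @export
all_pairwise_comparisons <- function(analysis_sets, groups,
                                     strata_var = "race_ethnicity",
                                     metrics = c("pearson_r", "mae"),
                                     variant = c("standard", "equal_n"),
                                     n_iter = 10000L, seed = 1L,
                                     n_cap = NULL) {
  variant <- match.arg(variant)
  pairs <- canonical_pairs(groups)
  rows <- list()
  for (pname in names(analysis_sets)) {
    aset <- analysis_sets[[pname]]
    if (is.list(aset) && !is.data.frame(aset) && !is.null(aset$data)) {
      aset <- aset$data
    }
    sizes <- vapply(groups, function(g) sum(aset[[strata_var]] == g), 1L)
    cap_p <- if (variant == "equal_n") n_cap %||% min(sizes) else NULL
    for (metric in metrics) {
      for (pr in pairs) {
        row_seed <- derive_seed(seed, pname, metric, pr[1], pr[2], variant)
        pa <- aset[aset[[strata_var]] == pr[1], , drop = FALSE]
        pb <- aset[aset[[strata_var]] == pr[2], , drop = FALSE]
        if (nrow(pa) < 3 || nrow(pb) < 3 ||
            (!is.null(cap_p) && cap_p > min(nrow(pa), nrow(pb)))) {
          row <- data.frame(
            group_a = pr[1], group_b = pr[2], metric = metric,
            n_a = nrow(pa), n_b = nrow(pb), n_iter = n_iter,
            variant = variant, n_cap = NA_integer_,
            median_diff = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
            significant = NA, n_degenerate = NA_integer_,
            seed = row_seed, stringsAsFactors = FALSE)
          row$status <- "unanalysable"
        } else {
          row <- bootstrap_group_difference(pa, pb, metric, n_iter = n_iter,
                                            seed = row_seed, n_cap = cap_p,
                                            labels = pr)
          attr(row, "iterations") <- NULL
          class(row) <- "data.frame"
          row$status <- "ok"
        }
        row <- cbind(data.frame(predictor = pname, stringsAsFactors = FALSE),
                     row)
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
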