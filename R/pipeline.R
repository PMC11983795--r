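# End-to-end pipeline: simulate/load -> QC -> metrics -> bootstrap ->
# regression -> tidy tables, audit and manifest.

#' Build a study configuration
#'
#' Describes one end-to-end run: the input (a simulation config or a
#' participant table on disk), the predictor set, bootstrap settings,
#' regression settings, and the output directory.
#'
#' @param simulation a [sim_config()] (ignored when `input_table` given).
#' @param input_table optional path to a tab-delimited participant table.
#' @param predictors predictor names to evaluate.
#' @param race_groups strata compared in the race/ethnicity bootstrap
#'   (the three groups with adequate n, by default).
#' @param bootstrap list: `n_iter`, `variants` (subset of
#'   `c("standard", "equal_n")`), `seed`.
#' @param regression list: `modifiers`, `adjustments`, `alpha`, `budgets`.
#' @param output_dir directory for result tables.
#' @param render_figures also write figure files (default FALSE).
#' @return object of class `study_config`.
#' @export
study_config <- function(simulation = sim_config(),
                         input_table = NULL,
                         predictors = NULL,
                         race_groups = c("Mexican American", "NH White",
                                         "NH Black"),
                         bootstrap = list(),
                         regression = list(),
                         output_dir = tempfile("epiperform_run_"),
                         render_figures = FALSE) {
  bootstrap <- utils::modifyList(
    list(n_iter = 10000L, variants = "standard", seed = 1L), bootstrap)
  regression <- utils::modifyList(
    list(modifiers = c("race_ethnicity", "sex"),
         adjustments = c("minimal", "full"), alpha = 0.05,
         budgets = as.list(bonferroni_budgets)), regression)
  cfg <- list(simulation = simulation, input_table = input_table,
              predictors = predictors %||% simulation$predictors,
              race_groups = race_groups, bootstrap = bootstrap,
              regression = regression, output_dir = output_dir,
              render_figures = render_figures)
  class(cfg) <- "study_config"
  cfg
}

#' Run the full evaluation pipeline
#'
#' Executes QC, stratified metrics, bootstrap comparisons and interaction
#' regressions, writing tidy tab-delimited tables, the QC audit and a run
#' manifest (seed, versions, row counts, file checksums) to the configured
#' output directory. Idempotent for a fixed seed: re-running a config
#' reproduces byte-identical tables.
#'
#' @param config a [study_config()].
#' @return invisibly, the result bundle: a list with the participant
#'   table, analysis sets, metric/bootstrap/regression tables, QC audit
#'   and manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  tbl <- stage("input", {
    if (!is.null(config$input_table)) read_population(config$input_table)
    else suppressWarnings(simulate_population(config$simulation))
  })

  qc_global <- stage("qc", exclude_sex_mismatch(tbl))
  clean <- qc_global$table

  specs <- predictor_specs(config$predictors)
  asets <- stage("qc", lapply(specs, function(sp) {
    suppressWarnings(build_analysis_set(clean, sp))
  }))

  metrics_tbl <- stage("metrics", {
    do.call(rbind, c(
      lapply(asets, stratified_metrics, strata_var = "race_ethnicity"),
      lapply(asets, function(a) {
        m <- stratified_metrics(a, strata_var = "sex")
        m[m$stratum != "overall", , drop = FALSE]
      })))
  })
  rownames(metrics_tbl) <- NULL

  boots <- stage("bootstrap", {
    out <- list()
    for (variant in config$bootstrap$variants) {
      out[[paste0("race_", variant)]] <- all_pairwise_comparisons(
        asets, groups = config$race_groups, strata_var = "race_ethnicity",
        variant = variant, n_iter = config$bootstrap$n_iter,
        seed = config$bootstrap$seed)
      out[[paste0("sex_", variant)]] <- all_pairwise_comparisons(
        asets, groups = c("male", "female"), strata_var = "sex",
        variant = variant, n_iter = config$bootstrap$n_iter,
        seed = config$bootstrap$seed)
    }
    out
  })

  regs <- stage("regression", {
    rows <- list()
    for (mod in config$regression$modifiers) {
      for (adj in config$regression$adjustments) {
        for (pname in names(specs)) {
          if (adj == "full" && specs[[pname]]$family == "cell") next
          fit <- fit_interaction_model(
            asets[[pname]], modifier = mod, adjustment = adj,
            spec = specs[[pname]],
            m_tests = config$regression$budgets[[adj]],
            alpha = config$regression$alpha)
          tab <- significance_tiers(fit, config$regression$alpha)
          tab <- cbind(data.frame(predictor = pname, modifier = mod,
                                  adjustment = adj, n_used = fit$n_used,
                                  stringsAsFactors = FALSE), tab)
          rows[[length(rows) + 1]] <- tab
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  audit <- stage("qc", {
    rows <- lapply(names(asets), function(pname) {
      rep <- asets[[pname]]$report
      df <- data.frame(predictor = pname, rule = names(rep$counts),
                       count = as.integer(rep$counts),
                       stringsAsFactors = FALSE)
      rbind(df, data.frame(predictor = pname, rule = "analysable_n",
                           count = rep$n_analysable))
    })
    global <- data.frame(predictor = "(global)", rule = "sex_mismatch",
                         count = qc_global$report$counts[["sex_mismatch"]],
                         stringsAsFactors = FALSE)
    out <- rbind(global, do.call(rbind, rows))
    rownames(out) <- NULL
    out
  })

  files <- list(metrics = "metrics.tsv", regression = "regression.tsv",
                qc_audit = "qc_audit.tsv")
  write_tsv(metrics_tbl, file.path(config$output_dir, files$metrics))
  write_tsv(regs, file.path(config$output_dir, files$regression))
  write_tsv(audit, file.path(config$output_dir, files$qc_audit))
  for (nm in names(boots)) {
    f <- paste0("bootstrap_", nm, ".tsv")
    files[[paste0("bootstrap_", nm)]] <- f
    write_tsv(boots[[nm]], file.path(config$output_dir, f))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("epiperform")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$bootstrap$seed,
    simulation_seed = if (is.null(config$input_table))
      config$simulation$seed else NA,
    n_participants = nrow(tbl),
    n_after_sex_qc = nrow(clean),
    predictors = names(specs),
    bootstrap_n_iter = config$bootstrap$n_iter,
    stages = c("qc", "metrics", "bootstrap", "regression"),
    files = lapply(files, function(f) {
      list(name = f,
           md5 = unname(tools::md5sum(file.path(config$output_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  bundle <- list(table = tbl, analysis_sets = asets, metrics = metrics_tbl,
                 bootstrap = boots, regression = regs, qc_audit = audit,
                 manifest = manifest, output_dir = config$output_dir)
  class(bundle) <- "epiperform_bundle"

  if (isTRUE(config$render_figures)) render_figures(bundle)
  invisible(bundle)
}

#' @export
print.epiperform_bundle <- function(x, ...) {
  cat("<epiperform_bundle>\n")
  cat(sprintf("  %d participants (%d after sex QC), %d predictors\n",
              x$manifest$n_participants, x$manifest$n_after_sex_qc,
              length(x$manifest$predictors)))
  cat(sprintf("  outputs in %s\n", x$output_dir))
  invisible(x)
}

#' Render the result surfaces as figure files
#'
#' Writes a correlation/MAE heatmap by stratum, bootstrap difference grids
#' with significance annotation, and an interaction forest plot, as PNG
#' files in the bundle's output directory. Missing tables are listed and
#' their figures skipped.
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory (default the bundle's).
#' @return invisibly, character vector of files written.
#' @export
render_figures <- function(bundle, dir = bundle$output_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  skip <- character(0)

  if (!is.null(bundle$metrics)) {
    f <- file.path(dir, "fig_metrics_heatmap.png")
    grDevices::png(f, width = 1200, height = 700, res = 110)
    op <- graphics::par(mfrow = c(1, 2), mar = c(9, 6, 3, 1))
    m <- bundle$metrics[bundle$metrics$analysable %in% TRUE, ]
    for (what in c("pearson_r", "mae")) {
      wide <- stats::xtabs(stats::as.formula(paste(what,
                                                   "~ predictor + stratum")),
                           data = m) /
        pmax(1, stats::xtabs(~ predictor + stratum, data = m))
      z <- as.matrix(unclass(wide))
      graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z),
                      col = grDevices::hcl.colors(25, "viridis"),
                      axes = FALSE, xlab = "", ylab = "",
                      main = if (what == "pearson_r") "Pearson r" else "MAE")
      graphics::axis(1, seq_len(ncol(z)), colnames(z), las = 2,
                     cex.axis = 0.7)
      graphics::axis(2, seq_len(nrow(z)), rownames(z), las = 2,
                     cex.axis = 0.7)
    }
    graphics::par(op)
    grDevices::dev.off()
    written <- c(written, f)
  } else skip <- c(skip, "metrics")

  if (length(bundle$bootstrap)) {
    for (nm in names(bundle$bootstrap)) {
      b <- bundle$bootstrap[[nm]]
      b <- b[b$status == "ok", ]
      if (!nrow(b)) next
      f <- file.path(dir, sprintf("fig_bootstrap_%s.png", nm))
      grDevices::png(f, width = 1100, height = 650, res = 110)
      op <- graphics::par(mar = c(9, 6, 3, 1))
      b$pair <- paste(b$group_a, "-", b$group_b, b$metric)
      cell <- interaction(b$predictor, b$pair)
      graphics::plot(as.integer(factor(b$predictor)), b$median_diff,
                     pch = ifelse(b$significant, 19, 1),
                     col = ifelse(b$metric == "pearson_r", "#2c7fb8",
                                  "#d95f0e"),
                     xaxt = "n", xlab = "", ylab = "median difference",
                     main = paste("Bootstrap differences:", nm))
      graphics::abline(h = 0, lty = 2)
      lv <- levels(factor(b$predictor))
      graphics::axis(1, seq_along(lv), lv, las = 2, cex.axis = 0.7)
      if (any(b$significant)) {
        sig <- b[b$significant, ]
        graphics::text(as.integer(factor(sig$predictor,
                                         levels = lv)),
                       sig$median_diff,
                       sprintf("%.2f", sig$median_diff), pos = 3,
                       cex = 0.6)
      }
      graphics::par(op)
      grDevices::dev.off()
      written <- c(written, f)
    }
  } else skip <- c(skip, "bootstrap")

  if (!is.null(bundle$regression)) {
    r <- bundle$regression[bundle$regression$role == "interaction" &
                             bundle$regression$adjustment == "minimal", ]
    if (nrow(r)) {
      f <- file.path(dir, "fig_interaction_forest.png")
      grDevices::png(f, width = 1000,
                     height = 200 + 18 * nrow(r), res = 110)
      op <- graphics::par(mar = c(4, 18, 2, 6))
      lab <- paste(r$predictor, sub("^phenotype:", "", r$term),
                   sep = " | ")
      ord <- order(lab)
      r <- r[ord, ]; lab <- lab[ord]
      y <- seq_len(nrow(r))
      graphics::plot(r$estimate, y, xlim = range(c(r$ci_low, r$ci_high, 0)),
                     pch = 19, cex = 0.6, yaxt = "n", ylab = "",
                     xlab = "interaction estimate (95% CI)",
                     main = "Interaction terms, minimally adjusted")
      graphics::segments(r$ci_low, y, r$ci_high, y)
      graphics::abline(v = 0, lty = 2)
      graphics::axis(2, y, lab, las = 2, cex.axis = 0.55)
      stars <- ifelse(r$tier == "significant", "**",
               ifelse(r$tier == "suggestive", "*", ""))
      graphics::mtext(stars, side = 4, at = y, las = 2, line = 0.5,
                      cex = 0.7)
      graphics::par(op)
      grDevices::dev.off()
      written <- c(written, f)
    }
  } else skip <- c(skip, "regression")

  if (length(skip)) {
    warning("tables missing, figures skipped: ",
            paste(skip, collapse = ", "), call. = FALSE)
  }
  invisible(written)
}
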