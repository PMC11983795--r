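# Registry of the 15 evaluated DNAm predictors and their target phenotypes.

# Canonical demographic labels used throughout.
race_levels <- function() {
  c("Mexican American", "Other Hispanic", "NH White", "NH Black",
    "Other/Multiracial")
}

sex_levels <- function() c("female", "male")

education_levels <- function() {
  c("<9th grade", "9-11th grade", "High school/GED", "Some college/AA",
    "College graduate+", "Don't know")
}

#' Names of the default predictor set
#'
#' Seven epigenetic clocks, the DNAm telomere-length estimator, four
#' plasma-protein surrogates, and three leukocyte-proportion estimators.
#'
#' @return character vector of 15 predictor names.
#' @export
predictor_names <- function() {
  c("horvath", "hannum", "skin_blood", "lin", "weidner", "vidal_bralo",
    "zhang", "dnamtl", "b2m", "crp", "cystatin_c", "hba1c",
    "lymphocytes", "monocytes", "neutrophils")
}

# Internal registry table. `measure` keys the laboratory phenotype used for
# missingness/outlier bookkeeping ("age" for clocks, which have no lab
# measure and are exempt from the log-outlier rule).
predictor_registry <- function() {
  clocks <- c("horvath", "hannum", "skin_blood", "lin", "weidner",
              "vidal_bralo", "zhang")
  reg <- data.frame(
    name = predictor_names(),
    family = c(rep("clock", 7), "telomere", rep("protein", 4), rep("cell", 3)),
    prediction_column = c(paste0("dnam_", clocks), "dnamtl_kbp", "dnam_b2m",
                          "dnam_log_crp", "dnam_cystatin_c", "dnam_log_hba1c",
                          "dnam_lymphocytes", "dnam_monocyte",
                          "dnam_neutrophil"),
    phenotype_column = c(rep("age_years", 7), "telomere_ts_ratio", "b2m_mg_l",
                         "crp_mg_l", "cystatin_c_mg_l", "hba1c_pct",
                         "lymphocyte_prop", "monocyte_prop",
                         "neutrophil_prop"),
    prediction_transform = c(rep("identity", 7), "identity", "identity",
                             "exponentiate", "identity", "exponentiate",
                             "identity", "identity", "identity"),
    phenotype_transform = c(rep("identity", 7), "ts_to_kbp", rep("identity", 4),
                            "sum_lymphocytes", "identity", "identity"),
    uses_age = c(rep(TRUE, 7), rep(FALSE, 8)),
    units = c(rep("years", 7), "kbp", "mg/L", "mg/L", "mg/L", "%",
              rep("proportion", 3)),
    measure = c(rep("age", 7), "telomere", "b2m", "crp", "cystatin_c",
                "hba1c", "lymphocytes", "monocytes", "neutrophils"),
    stringsAsFactors = FALSE
  )
  reg$outlier_rule <- reg$family != "clock"
  reg
}

#' Look up the specification of one predictor
#'
#' A `predictor_spec` binds a DNAm prediction column to its target phenotype
#' column, the transform each side needs before analysis, the units of the
#' analysis scale, and whether top-coded ages must be excluded (`uses_age`,
#' true exactly for the seven clocks).
#'
#' @param name one of [predictor_names()].
#' @return an object of class `predictor_spec` (a named list).
#' @examples
#' predictor_spec("dnamtl")$phenotype_transform  # "ts_to_kbp"
#' @export
predictor_spec <- function(name) {
  reg <- predictor_registry()
  i <- match(name, reg$name)
  if (is.na(i)) {
    stop("unknown predictor '", name, "'; see predictor_names()",
         call. = FALSE)
  }
  spec <- as.list(reg[i, , drop = FALSE])
  spec <- lapply(spec, unname)
  class(spec) <- "predictor_spec"
  spec
}

#' Specifications for a set of predictors
#'
#' @param names predictor names; defaults to the full 15-predictor set.
#' @return named list of `predictor_spec` objects.
#' @export
predictor_specs <- function(names = predictor_names()) {
  out <- lapply(names, predictor_spec)
  names(out) <- names
  out
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat(sprintf("<predictor_spec> %s [%s]\n", x$name, x$family))
  cat(sprintf("  %s ~ %s  (pred transform: %s, pheno transform: %s)\n",
              x$prediction_column, x$phenotype_column,
              x$prediction_transform, x$phenotype_transform))
  cat(sprintf("  units: %s; uses_age: %s; log-outlier rule: %s\n",
              x$units, x$uses_age, x$outlier_rule))
  invisible(x)
}

# Default analysis-scale correlation per predictor, applied to every group
# unless the simulation config overrides. Values are the overall-population
# correlations typical for these predictors in US adult cohorts.
default_target_correlations <- function() {
  c(horvath = 0.80, hannum = 0.82, skin_blood = 0.87, lin = 0.76,
    weidner = 0.55, vidal_bralo = 0.62, zhang = 0.89, dnamtl = 0.38,
    b2m = 0.46, crp = 0.35, cystatin_c = 0.43, hba1c = 0.41,
    lymphocytes = 0.88, monocytes = 0.75, neutrophils = 0.88)
}
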