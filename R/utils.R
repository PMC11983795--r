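# Internal utilities: seed derivation and scoped RNG.

#' Derive a reproducible child seed from a master seed and string tags
#'
#' Hashes the master seed together with an arbitrary list of tags into a
#' 32-bit non-negative integer. Used to split independent random-number
#' streams per (predictor, group), per bootstrap comparison row, etc., so
#' that adding one stream never perturbs another.
#'
#' @param master integer master seed.
#' @param ... character or numeric tags identifying the stream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  tags <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                collapse = "\x1f")
  codes <- utf8ToInt(tags)
  h <- 0
  for (ch in codes) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Standardize to mean 0 / sd 1 using the moments of a reference subset.
standardize_on <- function(x, reference = rep(TRUE, length(x))) {
  m <- mean(x[reference])
  s <- stats::sd(x[reference])
  if (!is.finite(s) || s <= 0) stop("degenerate phenotype vector", call. = FALSE)
  (x - m) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
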