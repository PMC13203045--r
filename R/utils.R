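#' @useDynLib gutcog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd cor pnorm pt pbinom phyper rnorm runif rbinom
#'   rnbinom quantile median complete.cases as.formula setNames predict
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Derive a child seed from a master seed
#'
#' Deterministic arithmetic derivation used throughout the pipeline so a
#' single master seed fixes split seeds, Boruta seeds, forest seeds and
#' permutation seeds. Result always lies in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param k integer stream index (>= 0).
#' @return an integer usable with [set.seed()].
#' @export
derive_seed <- function(master, k = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- abs(as.numeric(master)) %% 1e6
  as.integer(((m + 1) * 48271 + as.numeric(k) * 7919) %% 2147483629 + 1)
}

# internal: write a data.frame as deterministic TSV (no quotes, no rownames)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
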