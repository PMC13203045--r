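#' Compositional abundance table
#'
#' Container for a samples x features matrix of per-sample proportions
#' (species, MetaCyc pathways or KEGG-ortholog terms). Every constructor in
#' the package closes each sample to sum 1; samples whose selected features
#' sum to zero are rejected at read time.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   unique dimnames. Non-negative; each row is renormalized to sum 1 unless
#'   `normalize = FALSE` (in which case closure is asserted).
#' @param feature_kind one of `"species"`, `"pathway"`, `"ko"`.
#' @param stratified optional named list: feature id -> (contributor taxon ->
#'   named per-sample proportion vector). Never enters the model matrix.
#' @param normalize renormalize rows to sum 1 (default TRUE).
#' @return object of class `abundance_table` with fields `values`,
#'   `feature_kind`, `stratified`, `sample_ids`, `feature_ids`.
#' @export
abundance_table <- function(values, feature_kind = c("species", "pathway", "ko"),
                            stratified = NULL, normalize = TRUE) {
  feature_kind <- match.arg(feature_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample (row) and feature (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids")
  if (anyNA(values) || any(values < 0)) stop("abundances must be non-negative")
  rs <- rowSums(values)
  if (any(rs <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(rownames(values)[rs <= 0], collapse = ", "))
  if (normalize) {
    values <- values / rs
  } else if (any(abs(rs - 1) > 1e-6)) {
    stop("per-sample sums deviate from 1 beyond 1e-6")
  }
  structure(list(values = values, feature_kind = feature_kind,
                 stratified = stratified,
                 sample_ids = rownames(values),
                 feature_ids = colnames(values)),
            class = "abundance_table")
}

#' @method print abundance_table
#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table [%s]: %d samples x %d features%s\n",
              x$feature_kind, nrow(x$values), ncol(x$values),
              if (is.null(x$stratified)) "" else
                sprintf(" (+%d stratified)", length(x$stratified))))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Subset an abundance table by sample and/or feature, re-closing samples
#'
#' @param x an `abundance_table`.
#' @param samples,features character vectors of ids to keep (NULL = all).
#' @param renormalize re-close rows after subsetting features (default TRUE).
#' @return a new `abundance_table`.
#' @export
subset_table <- function(x, samples = NULL, features = NULL,
                         renormalize = TRUE) {
  v <- x$values
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(v))
    if (length(missing)) stop("unknown sample ids: ",
                              paste(missing, collapse = ", "))
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  abundance_table(v, x$feature_kind, stratified = x$stratified,
                  normalize = renormalize)
}

#' Prevalence filter
#'
#' Keeps features present (abundance > 0) in at least `min_prevalence` of the
#' samples, then re-closes each sample. Mirrors the pre-modeling filter
#' applied before species- and pathway-level model fitting.
#'
#' @param x an `abundance_table`.
#' @param min_prevalence fraction of samples in `(0, 1]` (default 0.1).
#' @return filtered `abundance_table`.
#' @export
prevalence_filter <- function(x, min_prevalence = 0.1) {
  prev <- colMeans(x$values > 0)
  keep <- names(prev)[prev >= min_prevalence]
  if (!length(keep)) stop("no feature passes the prevalence filter")
  subset_table(x, features = keep)
}
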