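# Readers/writers for the standard table dialects every downstream module
# consumes: MetaPhlAn-style taxonomic profiles, HUMAnN-style functional
# abundance tables (with optional stratified rows), and per-visit cohort
# metadata TSV.

ADAS_SUBTESTS <- c("adas_word_recall", "adas_word_recognition",
                   "adas_orientation", "adas_remember_instructions",
                   "adas_delayed_recall", "adas_maze_time",
                   "adas_maze_mistakes")
TOOLBOX_SUBTESTS <- c("tb_card_sort", "tb_pattern_comparison")

METADATA_COLUMNS <- c("subject_id", "visit_index", "days_since_enrollment",
                      "sample_id", "sex", "age", "education_years",
                      "antibiotics_6mo", "hospitalized_6mo", "polypharmacy",
                      "medications", "cfs", "mis", "cdr",
                      "dementia_diagnosis", "normal_daily_function",
                      ADAS_SUBTESTS, TOOLBOX_SUBTESTS, "adas_total")

#' Read MetaPhlAn-style taxonomic profiles
#'
#' Each input file is a single-sample profile TSV: pipe-delimited clade
#' strings in the first column, relative abundances (percent, 0-100) in the
#' first fully numeric column. Comment lines starting with `#` are skipped.
#' Only rows whose deepest clade segment matches `taxonomic_level` are kept;
#' the deepest segment becomes the feature id. The percent scale is
#' auto-detected (per-sample totals near 100 vs near 1) and each sample is
#' re-closed to sum 1. Features absent from a sample are 0.
#'
#' @param paths character vector of profile file paths; the sample id is the
#'   file base name without extension.
#' @param taxonomic_level clade prefix selecting the level (default `"s__"`,
#'   species).
#' @return an [abundance_table] with `feature_kind = "species"`.
#' @export
read_metaphlan_profiles <- function(paths, taxonomic_level = "s__") {
  if (!length(paths)) stop("no input files")
  sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  per_sample <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stop("unreadable file: ", paths[i])
    df <- read.delim(paths[i], header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (!ncol(df) >= 2) stop("not a profile TSV: ", paths[i])
    abcol <- NULL
    for (j in 2:ncol(df)) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      if (!anyNA(v)) { abcol <- v; break }
    }
    if (is.null(abcol)) stop("no numeric abundance column in ", paths[i])
    clades <- as.character(df[[1]])
    deepest <- vapply(strsplit(clades, "|", fixed = TRUE),
                      function(s) s[length(s)], character(1))
    keep <- startsWith(deepest, taxonomic_level)
    ab <- abcol[keep]
    names(ab) <- deepest[keep]
    if (anyDuplicated(names(ab))) stop("duplicate clades in ", paths[i])
    if (sum(ab) <= 0)
      stop("sample '", sample_ids[i], "' has zero total abundance at level ",
           taxonomic_level)
    per_sample[[i]] <- ab
  }
  features <- sort(unique(unlist(lapply(per_sample, names))))
  values <- matrix(0, length(paths), length(features),
                   dimnames = list(sample_ids, features))
  for (i in seq_along(per_sample))
    values[i, names(per_sample[[i]])] <- per_sample[[i]]
  # percent vs proportion dialect: totals near 100 => divide by 100
  if (median(rowSums(values)) > 2) values <- values / 100
  abundance_table(values, "species")
}

#' Write MetaPhlAn-style per-sample profiles
#'
#' Inverse of [read_metaphlan_profiles()]: one TSV per sample under `dir`,
#' percent scale, named `<sample_id>.tsv`.
#'
#' @param x an `abundance_table`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_metaphlan_profiles <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(x$sample_ids, ".tsv"))
  for (i in seq_along(x$sample_ids)) {
    v <- x$values[i, ]
    v <- v[v > 0]
    con <- file(paths[i], "w")
    writeLines("#clade_name\trelative_abundance", con)
    writeLines(sprintf("%s\t%.10g", names(v), 100 * v), con)
    close(con)
  }
  invisible(paths)
}

#' Read a HUMAnN-style functional abundance table
#'
#' Feature x sample TSV (first column feature id, one column per sample).
#' Stratified rows carry a `|` taxon suffix; they never enter the model
#' matrix. Unstratified rows form the matrix after dropping
#' `exclude_features`, then each sample is closed to sum 1.
#'
#' @param path TSV path.
#' @param feature_kind `"pathway"` (default) or `"ko"`.
#' @param exclude_features feature ids dropped before closure (default
#'   `UNMAPPED` and `UNINTEGRATED`).
#' @param keep_stratified when TRUE, stratified rows populate
#'   `stratified`: feature id -> contributor taxon -> per-sample share of the
#'   feature's unstratified abundance.
#' @return an [abundance_table].
#' @export
read_humann_table <- function(path, feature_kind = c("pathway", "ko"),
                              exclude_features = c("UNMAPPED", "UNINTEGRATED"),
                              keep_stratified = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("unreadable file: ", path)
  first <- readLines(path, n = 1L)
  header <- strsplit(sub("^#\\s*", "", first), "\t", fixed = TRUE)[[1]]
  df <- read.delim(path, header = FALSE, skip = 1L, stringsAsFactors = FALSE)
  if (ncol(df) != length(header)) stop("header/sample column count mismatch")
  samples <- header[-1]
  if (anyDuplicated(samples)) stop("duplicate sample IDs in header")
  feats <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("non-numeric abundance value")
  if (any(mat < 0)) stop("negative abundance value")
  stratified_rows <- grepl("|", feats, fixed = TRUE)

  base <- feats[!stratified_rows]
  vals <- t(mat[!stratified_rows, , drop = FALSE])
  dimnames(vals) <- list(samples, base)
  strat <- NULL
  if (keep_stratified && any(stratified_rows)) {
    parts <- strsplit(feats[stratified_rows], "|", fixed = TRUE)
    parent <- vapply(parts, `[[`, character(1), 1L)
    taxon <- vapply(parts, function(s) {
      seg <- strsplit(s[2], ".", fixed = TRUE)[[1]]
      seg[length(seg)]
    }, character(1))
    sm <- mat[stratified_rows, , drop = FALSE]
    strat <- list()
    for (k in seq_along(parent)) {
      pf <- parent[k]
      if (!pf %in% base) next
      tot <- vals[, pf]
      share <- ifelse(tot > 0, sm[k, ] / tot, 0)
      names(share) <- samples
      strat[[pf]] <- c(strat[[pf]], setNames(list(share), taxon[k]))
    }
    if (!length(strat)) strat <- NULL
  }
  keep <- setdiff(base, exclude_features)
  if (!length(keep)) stop("all features excluded")
  abundance_table(vals[, keep, drop = FALSE], feature_kind,
                  stratified = strat)
}

#' Write a HUMAnN-style functional abundance table
#'
#' @param x an `abundance_table`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_humann_table <- function(x, path) {
  con <- file(path, "w")
  writeLines(paste(c("# Feature", x$sample_ids), collapse = "\t"), con)
  for (f in x$feature_ids)
    writeLines(paste(c(f, sprintf("%.10g", x$values[, f])), collapse = "\t"),
               con)
  close(con)
  invisible(path)
}

# coerce metadata columns to their documented types, validating ranges
coerce_logical <- function(v, col) {
  if (is.logical(v)) return(v)
  s <- tolower(as.character(v))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes")] <- TRUE
  out[s %in% c("false", "f", "0", "no")] <- FALSE
  if (any(is.na(out) & !is.na(s) & s != "na" & s != ""))
    stop("column '", col, "' is not interpretable as logical")
  out
}

#' Read per-visit cohort metadata
#'
#' One row per subject-visit. Recognized columns (all TSV, header required):
#' `subject_id`, `visit_index`, `days_since_enrollment`, `sample_id`, `sex`
#' (`female`/`male`), `age` (years), `education_years`, `antibiotics_6mo`,
#' `hospitalized_6mo`, `polypharmacy` (logicals), `medications`
#' (`;`-separated drug-class labels), `cfs` (clinical frailty scale, 1-7),
#' `mis` (malnutrition indicator score), `cdr` (clinical dementia rating),
#' `dementia_diagnosis`, `normal_daily_function` (logicals), the ADAS-Cog-13
#' subtests `adas_word_recall`, `adas_word_recognition`, `adas_orientation`,
#' `adas_remember_instructions`, `adas_delayed_recall`, `adas_maze_time`,
#' `adas_maze_mistakes`, the NIH Toolbox subtests `tb_card_sort`,
#' `tb_pattern_comparison`, and `adas_total` (0-85). `subject_id` and
#' `days_since_enrollment` are mandatory; `visit_index` is derived from
#' within-subject day order when absent.
#'
#' @param path TSV path.
#' @return data.frame of visit records, ordered by subject then visit.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  df <- read_tsv(path)
  validate_visit_records(df)
}

#' Validate (and complete) a visit-record data.frame
#'
#' Applies the same typing, range checks and visit-index derivation as
#' [read_metadata()] to an in-memory data.frame.
#'
#' @param df data.frame with the metadata columns.
#' @return validated data.frame.
#' @export
validate_visit_records <- function(df) {
  for (col in c("subject_id", "days_since_enrollment"))
    if (!col %in% names(df)) stop("missing mandatory column: ", col)
  df$subject_id <- as.character(df$subject_id)
  df$days_since_enrollment <- as.numeric(df$days_since_enrollment)
  if (any(is.na(df$days_since_enrollment)) ||
      any(df$days_since_enrollment < 0))
    stop("days_since_enrollment must be >= 0")
  for (col in c("antibiotics_6mo", "hospitalized_6mo", "polypharmacy",
                "dementia_diagnosis", "normal_daily_function"))
    if (col %in% names(df)) df[[col]] <- coerce_logical(df[[col]], col)
  if ("sex" %in% names(df)) {
    df$sex <- tolower(as.character(df$sex))
    if (!all(df$sex %in% c("female", "male", NA)))
      stop("sex must be 'female' or 'male'")
  }
  if ("sample_id" %in% names(df)) {
    df$sample_id <- as.character(df$sample_id)
    df$sample_id[df$sample_id %in% c("", "NA")] <- NA_character_
    sid <- df$sample_id[!is.na(df$sample_id)]
    if (anyDuplicated(sid)) stop("duplicate sample_id")
  }
  if ("cfs" %in% names(df)) {
    df$cfs <- as.numeric(df$cfs)
    bad <- !is.na(df$cfs) & (df$cfs < 1 | df$cfs > 7)
    if (any(bad)) stop("cfs out of range [1, 7]")
  }
  if ("cdr" %in% names(df)) {
    df$cdr <- as.numeric(df$cdr)
    if (any(!is.na(df$cdr) & df$cdr < 0)) stop("cdr out of range")
  }
  if ("adas_total" %in% names(df)) {
    df$adas_total <- as.numeric(df$adas_total)
    bad <- !is.na(df$adas_total) & (df$adas_total < 0 | df$adas_total > 85)
    if (any(bad)) stop("adas_total out of range [0, 85]")
  }
  # visit_index: derive from day order when absent, check consistency else
  ord <- order(df$subject_id, df$days_since_enrollment)
  df <- df[ord, , drop = FALSE]
  derived <- stats::ave(df$days_since_enrollment, df$subject_id,
                        FUN = function(d) rank(d, ties.method = "first"))
  if (!"visit_index" %in% names(df)) {
    df$visit_index <- as.integer(derived)
  } else {
    df$visit_index <- as.integer(df$visit_index)
    chk <- stats::ave(seq_len(nrow(df)), df$subject_id, FUN = function(i) {
      all(order(df$visit_index[i]) == order(df$days_since_enrollment[i],
                                            df$visit_index[i]))
    })
    if (!all(chk == 1))
      stop("visit_index inconsistent with within-subject day ordering")
  }
  if (anyDuplicated(df[, c("subject_id", "visit_index")]))
    stop("duplicate (subject, visit) pair")
  rownames(df) <- NULL
  df
}

#' Write per-visit cohort metadata
#'
#' Inverse of [read_metadata()]; a read of the written file round-trips.
#'
#' @param df visit-record data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_metadata <- function(df, path) {
  write_tsv(df, path)
}
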