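# Subject classification, composite cognitive z-scores, alpha diversity, and
# the two random-intercept linear mixed models used for diversity and
# cognitive-score stability.

MEMORY_COMPONENTS <- c("adas_word_recall", "adas_word_recognition",
                       "adas_orientation", "adas_remember_instructions",
                       "adas_delayed_recall")
# executive function: maze scores are already higher-is-worse; the two NIH
# Toolbox scores are higher-is-better and get sign-flipped before summation so
# that the composite is higher = more impaired.
EF_COMPONENTS <- c(adas_maze_time = 1, adas_maze_mistakes = 1,
                   tb_card_sort = -1, tb_pattern_comparison = -1)

#' Classify subjects into HC / MCI / AD from baseline
#'
#' Assignment uses the baseline visit (`visit_index == 1`) of each subject:
#' dementia diagnosis => `AD`; otherwise CDR < 1 together with normal daily
#' function and an ADAS-Cog-13 word-list delayed-recall score >= 4 => `MCI`;
#' everyone else => `HC`.
#'
#' @param records visit-record data.frame (see [read_metadata()]).
#' @return data.frame with `subject_id`, `status` (factor HC/MCI/AD), `basis`
#'   (rule identifier).
#' @export
classify_subjects <- function(records) {
  base <- records[records$visit_index == 1L, , drop = FALSE]
  missing <- setdiff(unique(records$subject_id), base$subject_id)
  if (length(missing))
    stop("subject(s) without a baseline visit: ",
         paste(missing, collapse = ", "))
  status <- character(nrow(base))
  basis <- character(nrow(base))
  ad <- isTRUE_vec(base$dementia_diagnosis)
  status[ad] <- "AD"; basis[ad] <- "self_reported_diagnosis"
  rest <- !ad
  if (any(rest)) {
    dr <- base$adas_delayed_recall
    if (any(rest & is.na(dr)))
      stop("missing delayed-recall score for non-AD subject(s): ",
           paste(base$subject_id[rest & is.na(dr)], collapse = ", "))
    mci <- rest & !is.na(base$cdr) & base$cdr < 1 &
      isTRUE_vec(base$normal_daily_function) & dr >= 4
    status[mci] <- "MCI"; basis[mci] <- "cdr_function_delayed_recall"
    hc <- rest & !mci
    status[hc] <- "HC"; basis[hc] <- "no_impairment_criteria_met"
  }
  data.frame(subject_id = base$subject_id,
             status = factor(status, levels = c("HC", "MCI", "AD")),
             basis = basis, stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE

#' Composite cognitive scores standardized within visit
#'
#' The memory composite sums the ADAS-Cog-13 word recall, word recognition,
#' orientation, remembering-word-recognition-instructions and delayed recall
#' scores. The executive-function composite sums maze time, maze mistakes and
#' the (sign-flipped) NIH Toolbox dimensional card sort and pattern comparison
#' scores. Each composite is z-standardized within visit index across all
#' subjects assessed at that visit, using the sample (n-1) standard deviation
#' by default. Higher z means worse performance.
#'
#' @param records visit-record data.frame.
#' @param domain `"memory"` or `"executive_function"`.
#' @param ddof degrees-of-freedom correction for the visit SD: 1 (sample SD,
#'   default) or 0 (population SD).
#' @param on_undefined what to do with visit groups of size 1 or zero SD:
#'   `"error"` (default, listing the offending visit) or `"drop"` (exclude
#'   those visits, for whole-cohort pipelines where a sparse tail visit may
#'   hold a single subject).
#' @return data.frame `subject_id`, `visit_index`, `domain`, `raw_sum`, `z`.
#' @export
composite_zscore <- function(records, domain = c("memory",
                                                 "executive_function"),
                             ddof = 1, on_undefined = c("error", "drop")) {
  domain <- match.arg(domain)
  on_undefined <- match.arg(on_undefined)
  if (domain == "memory") {
    cols <- MEMORY_COMPONENTS
    signs <- rep(1, length(cols))
  } else {
    cols <- names(EF_COMPONENTS)
    signs <- unname(EF_COMPONENTS)
  }
  miss <- setdiff(cols, names(records))
  if (length(miss)) stop("missing subtest column(s): ",
                         paste(miss, collapse = ", "))
  comp <- as.matrix(records[, cols, drop = FALSE])
  ok <- complete.cases(comp)
  raw <- as.numeric(comp[ok, , drop = FALSE] %*% signs)
  out <- data.frame(subject_id = records$subject_id[ok],
                    visit_index = records$visit_index[ok],
                    domain = domain, raw_sum = raw, z = NA_real_,
                    stringsAsFactors = FALSE)
  drop <- logical(nrow(out))
  for (v in unique(out$visit_index)) {
    i <- out$visit_index == v
    n <- sum(i)
    if (n < 2) {
      if (on_undefined == "error")
        stop("visit group of size ", n, " at visit ", v,
             ": z-score undefined")
      drop[i] <- TRUE
      next
    }
    m <- mean(out$raw_sum[i])
    s <- sqrt(sum((out$raw_sum[i] - m)^2) / (n - ddof))
    if (s == 0) {
      if (on_undefined == "error")
        stop("zero standard deviation at visit ", v, ": z-score undefined")
      drop[i] <- TRUE
      next
    }
    out$z[i] <- (out$raw_sum[i] - m) / s
  }
  out[!drop, , drop = FALSE]
}

#' Inverse Simpson diversity
#'
#' `1 / sum(p_k^2)` for a closed proportion vector; equals the species count
#' for a uniform community.
#'
#' @param p numeric vector of proportions summing to 1 (within 1e-6).
#' @return a single number.
#' @export
inverse_simpson <- function(p) {
  if (!length(p)) stop("empty proportion vector")
  if (anyNA(p) || any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("input is not closed (sum != 1)")
  1 / sum(p^2)
}

#' Inverse Simpson diversity for every sample of a table
#'
#' @param x an [abundance_table].
#' @return data.frame `sample_id`, `inverse_simpson`.
#' @export
sample_diversity <- function(x) {
  data.frame(sample_id = x$sample_ids,
             inverse_simpson = apply(x$values, 1, inverse_simpson),
             stringsAsFactors = FALSE)
}

#' Fit a random-intercept linear mixed model
#'
#' REML fit (via `lme4::lmer`) of `response ~ fixed_terms + (1 | cluster)`,
#' returning fixed-effect Wald z-tests and variance components. Serves both
#' study formulas: diversity ~ sex + age + education + antibiotics + time +
#' cognitive status, and cognitive score ~ time + cognitive status, each with
#' a subject random intercept.
#'
#' @param data data.frame holding all variables.
#' @param response name of the response column.
#' @param fixed_terms character vector of fixed-effect terms (right-hand
#'   side); categorical variables are treatment-coded by R's defaults (use
#'   factors with HC as the first level for cognitive status).
#' @param cluster name of the grouping column (subject id).
#' @return object of class `gc_lmm`: list with `fixed` (data.frame term,
#'   estimate, se, z, p), `sigma2_b`, `sigma2_e`, `logLik`, `converged`,
#'   `formula`, `n_clusters`, `fit` (the underlying `lmerMod`).
#' @export
fit_random_intercept_lmm <- function(data, response, fixed_terms, cluster) {
  if (!cluster %in% names(data)) stop("unknown cluster column: ", cluster)
  ncl <- length(unique(data[[cluster]]))
  if (ncl < 2) stop("at least 2 clusters are required")
  rhs <- paste(c(fixed_terms, sprintf("(1 | %s)", cluster)), collapse = " + ")
  fml <- as.formula(paste(response, "~", rhs))
  # rank check on the fixed design
  Xf <- stats::model.matrix(
    as.formula(paste(response, "~", paste(fixed_terms, collapse = " + "))),
    data)
  if (qr(Xf)$rank < ncol(Xf)) stop("fixed design is rank deficient")
  fit <- lme4::lmer(fml, data = data, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_b <- vc$vcov[vc$grp == cluster][1]
  sigma2_e <- vc$vcov[vc$grp == "Residual"][1]
  co <- summary(fit)$coefficients
  z <- co[, "Estimate"] / co[, "Std. Error"]
  fixed <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], z = z,
                      p = 2 * pnorm(-abs(z)), row.names = NULL,
                      stringsAsFactors = FALSE)
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  structure(list(fixed = fixed, sigma2_b = sigma2_b, sigma2_e = sigma2_e,
                 logLik = as.numeric(stats::logLik(fit)), converged = conv,
                 formula = deparse(fml), n_clusters = ncl, fit = fit),
            class = "gc_lmm")
}

#' @method print gc_lmm
#' @export
print.gc_lmm <- function(x, ...) {
  cat("Random-intercept LMM:", x$formula, "\n")
  cat(sprintf("  sigma2_b = %.4g, sigma2_e = %.4g, logLik = %.2f (%s)\n",
              x$sigma2_b, x$sigma2_e, x$logLik,
              if (x$converged) "converged" else "NOT converged"))
  print(x$fixed, digits = 4)
  invisible(x)
}
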