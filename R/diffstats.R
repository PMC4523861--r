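#' Keep peptides quantified in enough replicates
#'
#' @param mat Peptides x replicates matrix of normalized log2 ratios
#'   (see [ratio_matrix()]); NA marks a missing replicate.
#' @param min_replicates Minimum number of non-missing replicate ratios a
#'   peptide needs to be testable (default 3).
#' @return List with `mat` (filtered matrix) and `n_excluded`.
#' @export
filter_min_replicates <- function(mat, min_replicates = 3) {
  if (min_replicates < 2)
    stop("min_replicates must be at least 2")
  n_ok <- rowSums(!is.na(mat))
  keep <- n_ok >= min_replicates
  list(mat = mat[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' One-sample location tests of log2 ratios against zero
#'
#' For each peptide (row), tests whether the mean normalized log2
#' treated/control ratio differs from 0. The default is a two-sided one-sample
#' Student t test, computed rowwise in vectorised form. `method =
#' "moderated"` instead uses limma's empirical-Bayes moderated t
#' (shrinking per-peptide variances toward a common prior), useful with few
#' replicates.
#'
#' Degenerate rows are flagged: zero variance with zero mean gives p = 1;
#' zero variance with nonzero mean gives the smallest representable p.
#'
#' @param mat Filtered peptides x replicates matrix.
#' @param method `"t"` (default) or `"moderated"`.
#' @return data.frame with `peptide_key`, `n_replicates_quantified`,
#'   `mean_log2`, `p_value`, `degenerate`.
#' @export
test_peptides <- function(mat, method = c("t", "moderated")) {
  method <- match.arg(method)
  n <- rowSums(!is.na(mat))
  if (any(n < 2)) stop("all rows must have at least 2 observations; filter first")
  m <- rowMeans(mat, na.rm = TRUE)
  if (method == "t") {
    dev <- mat - m
    v <- rowSums(dev * dev, na.rm = TRUE) / (n - 1)
    s <- sqrt(v)
    tstat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  } else {
    if (!requireNamespace("limma", quietly = TRUE))
      stop("method = 'moderated' requires the limma package")
    fit <- limma::eBayes(limma::lmFit(mat, design = matrix(1, ncol(mat), 1)))
    p <- fit$p.value[, 1]
    s <- fit$sigma
  }
  degenerate <- is.na(p) | s == 0
  p[degenerate & m == 0] <- 1
  p[degenerate & m != 0] <- .Machine$double.xmin
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  keys <- rownames(mat)
  if (is.null(keys)) keys <- as.character(seq_len(nrow(mat)))
  data.frame(peptide_key = keys,
             n_replicates_quantified = as.integer(n),
             mean_log2 = m, p_value = p, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Computes BH q-values (adjusted p-values) and pass/fail flags at the given
#' FDR threshold. q-values are monotone non-decreasing in p-value rank and
#' invariant to input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param fdr FDR threshold (default 0.10).
#' @return data.frame with `p_value`, `q_value`, `pass` in input order.
#' @export
bh_fdr <- function(p_values, fdr = 0.10) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  data.frame(p_value = p_values, q_value = q, pass = q <= fdr)
}

#' Classify tested peptides into up / down / unchanged
#'
#' A peptide is `up` when it passes the FDR threshold with positive mean log2
#' ratio, `down` when it passes with negative mean, otherwise `unchanged`
#' (the volcano-plot colouring).
#'
#' @param results Output of [test_peptides()] augmented with `q_value`.
#' @param fdr FDR threshold (default 0.10).
#' @return `results` with added columns `direction` and `neg_log10_p`.
#' @export
classify_peptides <- function(results, fdr = 0.10) {
  sig <- results$q_value <= fdr
  results$direction <- ifelse(sig & results$mean_log2 > 0, "up",
                              ifelse(sig & results$mean_log2 < 0, "down",
                                     "unchanged"))
  results$neg_log10_p <- -log10(results$p_value)
  results
}
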