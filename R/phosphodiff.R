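#' Differential analysis of a SILAC phosphoproteomics experiment
#'
#' The main fitting function of the package. Starting from an event-level
#' quantification table (one row per peptide x charge state x SCX fraction x
#' replicate, heavy and light channel intensities), it
#' \enumerate{
#'   \item sums raw intensities per unique peptide and replicate over charge
#'     states and fractions ([sum_by_peptide()]),
#'   \item forms log2 treated/control ratios under the per-replicate label
#'     orientation ([compute_ratio()]),
#'   \item normalizes each replicate by its median log2 ratio over all
#'     peptides, phospho and non-phospho ([normalize_replicates()]),
#'   \item keeps peptides quantified in at least `min_replicates` replicates
#'     ([filter_min_replicates()]),
#'   \item tests each peptide's mean log2 ratio against zero
#'     ([test_peptides()]) and controls the FDR by Benjamini-Hochberg
#'     step-up ([bh_fdr()]),
#'   \item classifies peptides as up / down / unchanged at the FDR threshold
#'     ([classify_peptides()]).
#' }
#'
#' @param quant Event-level quantification data.frame (see [validate_quant()]
#'   for the column contract), e.g. from [simulate_silac()] or
#'   [read_quant_table()].
#' @param orientation Named character vector mapping replicate ids to the
#'   treated channel (`"heavy"`/`"light"`); `NULL` = treated is heavy
#'   everywhere.
#' @param min_replicates Minimum replicates per testable peptide (default 3).
#' @param fdr BH-FDR threshold (default 0.10).
#' @param method `"t"` (unmoderated one-sample Student t, default) or
#'   `"moderated"` (limma empirical-Bayes).
#' @param normalize_on Normalization population: `"all"` peptides (default),
#'   `"phospho"` or `"nonphospho"`.
#' @param phospho_only Test only phosphopeptides (default `TRUE`);
#'   non-phosphopeptides always participate in normalization.
#'
#' @return Object of class `"phosphodiff"`: a list with components
#'   `results` (per-peptide data.frame: effect, p, q, direction), `mat`
#'   (tested peptides x replicates matrix of normalized ratios), `offsets`
#'   (per-replicate normalization offsets), `ratios` (the full per-peptide
#'   per-replicate ratio table with exclusion reason codes), `n_excluded`
#'   (peptides failing the replicate filter), `fdr`, `method`, `call`.
#'   Methods: [print.phosphodiff()], [summary.phosphodiff()],
#'   [coef.phosphodiff()], [plot.phosphodiff()] (volcano),
#'   [residuals.phosphodiff()], [fitted.phosphodiff()].
#'
#' @examples
#' sim <- simulate_silac(synthetic_config(n_proteins = 60,
#'   n_phosphopeptides = 150, n_nonphospho_peptides = 150, seed = 7))
#' fit <- phosphodiff(sim$quant)
#' fit
#' head(coef(fit))
#' @export
phosphodiff <- function(quant, orientation = NULL, min_replicates = 3,
                        fdr = 0.10, method = c("t", "moderated"),
                        normalize_on = "all", phospho_only = TRUE) {
  method <- match.arg(method)
  cl <- match.call()
  validate_quant(quant)
  summed <- sum_by_peptide(quant, validate = FALSE)
  ratios <- compute_ratio(summed, orientation)
  norm <- normalize_replicates(ratios, population = normalize_on)

  tab <- norm$ratios
  if (phospho_only) tab <- tab[grepl("[a-z]", tab$peptide_key), , drop = FALSE]
  tab <- tab[tab$quantified, , drop = FALSE]
  mat <- ratio_matrix(tab)
  flt <- filter_min_replicates(mat, min_replicates)
  if (nrow(flt$mat) == 0) stop("no peptides pass the replicate filter")

  res <- test_peptides(flt$mat, method = method)
  bh <- bh_fdr(res$p_value, fdr = fdr)
  res$q_value <- bh$q_value
  res <- classify_peptides(res, fdr = fdr)

  structure(list(results = res, mat = flt$mat, offsets = norm$offsets,
                 ratios = norm$ratios, n_excluded = flt$n_excluded,
                 fdr = fdr, min_replicates = min_replicates,
                 method = method, call = cl),
            class = "phosphodiff")
}

#' @export
print.phosphodiff <- function(x, ...) {
  d <- table(factor(x$results$direction, levels = c("up", "down", "unchanged")))
  cat("SILAC phosphoproteomics differential analysis\n")
  cat(sprintf("  %d peptides tested (%s test, >= %d replicates; %d excluded)\n",
              nrow(x$results),
              if (x$method == "t") "Student t" else "moderated t",
              x$min_replicates, x$n_excluded))
  cat(sprintf("  BH-FDR %.0f%%: %d up, %d down, %d unchanged\n",
              100 * x$fdr, d[["up"]], d[["down"]], d[["unchanged"]]))
  invisible(x)
}

#' Summary of a phosphodiff fit
#'
#' @param object A [phosphodiff()] fit.
#' @param ... Unused.
#' @return Object of class `"summary.phosphodiff"` with direction counts,
#'   per-replicate normalization offsets and the top regulated peptides.
#' @export
summary.phosphodiff <- function(object, ...) {
  res <- object$results
  reg <- res[res$direction != "unchanged", , drop = FALSE]
  reg <- reg[order(reg$q_value, -abs(reg$mean_log2)), , drop = FALSE]
  structure(list(
    n_tested = nrow(res),
    n_excluded = object$n_excluded,
    counts = table(factor(res$direction, levels = c("up", "down", "unchanged"))),
    offsets = object$offsets,
    fdr = object$fdr,
    method = object$method,
    top = utils::head(reg[, c("peptide_key", "mean_log2", "p_value",
                              "q_value", "direction")], 10)
  ), class = "summary.phosphodiff")
}

#' @export
print.summary.phosphodiff <- function(x, ...) {
  cat(sprintf("Tested peptides: %d (excluded by replicate filter: %d)\n",
              x$n_tested, x$n_excluded))
  cat(sprintf("Test: %s; BH-FDR threshold: %.2f\n",
              if (x$method == "t") "two-sided one-sample t" else "limma moderated t",
              x$fdr))
  cat("Direction counts:\n")
  print(x$counts)
  cat("Per-replicate normalization offsets (median log2 ratio):\n")
  print(round(x$offsets, 4))
  if (nrow(x$top)) {
    cat("Top regulated peptides:\n")
    print(x$top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Effect estimates of a phosphodiff fit
#'
#' @param object A [phosphodiff()] fit.
#' @param ... Unused.
#' @return Named vector of mean normalized log2 treated/control ratios, one
#'   per tested peptide.
#' @export
coef.phosphodiff <- function(object, ...) {
  stats::setNames(object$results$mean_log2, object$results$peptide_key)
}

#' @export
fitted.phosphodiff <- function(object, ...) coef(object)

#' Residual normalized ratios around the peptide means
#'
#' @param object A [phosphodiff()] fit.
#' @param ... Unused.
#' @return Peptides x replicates matrix of `normalized ratio - peptide mean`.
#' @export
residuals.phosphodiff <- function(object, ...) {
  object$mat - object$results$mean_log2
}

#' Volcano plot of a phosphodiff fit
#'
#' Mean log2 treated/control ratio against -log10 p, with peptides passing
#' the FDR threshold coloured red (up) and green (down), the conventional
#' display for SILAC phosphoproteome regulation.
#'
#' @param x A [phosphodiff()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.phosphodiff <- function(x, ...) {
  res <- x$results
  col <- ifelse(res$direction == "up", "red2",
                ifelse(res$direction == "down", "green4", "grey60"))
  graphics::plot(res$mean_log2, res$neg_log10_p, col = col, pch = 16,
                 cex = 0.6, xlab = expression(log[2] ~ "(treated / control)"),
                 ylab = expression(-log[10] ~ "(p value)"), ...)
  graphics::abline(v = 0, lty = 3, col = "grey40")
  invisible(x)
}

#' Volcano-plot table
#'
#' @param fit A [phosphodiff()] fit.
#' @return data.frame with `peptide_key`, `mean_log2`, `neg_log10_p`, `class`.
#' @export
volcano_table <- function(fit) {
  stopifnot(inherits(fit, "phosphodiff"))
  data.frame(peptide_key = fit$results$peptide_key,
             mean_log2 = fit$results$mean_log2,
             neg_log10_p = fit$results$neg_log10_p,
             class = fit$results$direction, stringsAsFactors = FALSE)
}
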