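#' Classify a phosphosite window into a kinase substrate motif class
#'
#' Applies the standard rules in fixed priority order, so every window
#' receives exactly one class:
#' \enumerate{
#'   \item proline-directed: proline at +1 (with `strict_proline = TRUE`,
#'     proline required at both +1 and -2);
#'   \item basophilic: arginine or lysine at -3 or -2, or histidine at -3
#'     (basic residues upstream of the site, the AGC/CAMK signature);
#'   \item acidophilic: at least two of \{D, E\} within +1 ... +3;
#'   \item other: none of the above.
#' }
#'
#' @param window 13-mer window (or vector of windows), site centred,
#'   `'_'` padding allowed.
#' @param half_width Flank width (default 6).
#' @param strict_proline Require proline at both +1 and -2 for the
#'   proline-directed class (default `FALSE`: +1 alone defines it).
#' @return Character vector of classes.
#' @export
classify_window <- function(window, half_width = 6, strict_proline = FALSE) {
  w <- 2L * half_width + 1L
  if (any(nchar(window) != w))
    stop("windows must have length ", w)
  at <- function(off) {
    j <- off + half_width + 1L
    substr(window, j, j)
  }
  pro <- at(1) == "P"
  if (strict_proline) pro <- pro & at(-2) == "P"
  baso <- at(-3) %in% c("R", "K", "H") | at(-2) %in% c("R", "K")
  acid_n <- (at(1) %in% c("D", "E")) + (at(2) %in% c("D", "E")) +
    (at(3) %in% c("D", "E"))
  ifelse(pro, "proline-directed",
         ifelse(baso, "basophilic",
                ifelse(acid_n >= 2, "acidophilic", "other")))
}

#' Summarize motif classes of regulated sites by direction
#'
#' Builds the contingency of kinase substrate motif class against regulation
#' direction, with per-direction proportions, ordered by total count — the
#' tabular form of a "which kinase families respond" summary.
#'
#' @param up_windows,down_windows Window vectors of up- and down-regulated
#'   sites.
#' @param ... Passed to [classify_window()].
#' @return data.frame with `class`, `up`, `down`, `up_prop`, `down_prop`.
#' @export
summarize_classes <- function(up_windows, down_windows, ...) {
  lev <- c("basophilic", "proline-directed", "acidophilic", "other")
  cu <- table(factor(classify_window(up_windows, ...), levels = lev))
  cd <- table(factor(classify_window(down_windows, ...), levels = lev))
  out <- data.frame(class = lev, up = as.integer(cu), down = as.integer(cd),
                    stringsAsFactors = FALSE)
  out$up_prop <- if (sum(out$up)) out$up / sum(out$up) else 0
  out$down_prop <- if (sum(out$down)) out$down / sum(out$down) else 0
  out[order(-(out$up + out$down)), , drop = FALSE]
}

#' Score a window against a kinase position-specific scoring matrix
#'
#' Adds up the matrix weights of the window's residues over all non-padding
#' offsets; padding contributes zero. Higher scores mean a better match of
#' the site to the kinase's substrate preference.
#'
#' @param window 13-mer window.
#' @param pssm Numeric matrix, rows = residues, columns = offsets named
#'   `"-6" ... "6"` (see [read_pssm()]).
#' @param half_width Flank width (default 6).
#' @return Additive log-odds score.
#' @export
pssm_score <- function(window, pssm, half_width = 6) {
  w <- 2L * half_width + 1L
  if (nchar(window) != w) stop("window must have length ", w)
  offs <- as.character(seq(-half_width, half_width))
  missing_off <- setdiff(offs, colnames(pssm))
  chars <- strsplit(window, "")[[1]]
  score <- 0
  for (i in seq_len(w)) {
    r <- chars[i]
    if (r == "_") next
    if (offs[i] %in% missing_off) next
    if (!r %in% rownames(pssm))
      stop("residue '", r, "' absent from PSSM alphabet")
    score <- score + pssm[r, offs[i]]
  }
  score
}

#' Score sites against a collection of kinase PSSMs
#'
#' @param sites Site table with a `window` column (from [map_sites()]).
#' @param pssms Named list of PSSM matrices.
#' @param half_width Flank width (default 6).
#' @return data.frame: one row per site x kinase with the additive score.
#' @export
score_kinases <- function(sites, pssms, half_width = 6) {
  if (!length(pssms)) stop("no PSSMs supplied")
  out <- expand.grid(site = seq_len(nrow(sites)), kinase = names(pssms),
                     stringsAsFactors = FALSE)
  out$score <- mapply(function(i, k)
    pssm_score(sites$window[i], pssms[[k]], half_width),
    out$site, out$kinase)
  data.frame(protein_id = sites$protein_id[out$site],
             position = sites$position[out$site],
             window = sites$window[out$site],
             kinase = out$kinase, score = out$score,
             stringsAsFactors = FALSE)
}
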