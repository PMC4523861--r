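#' Position-specific residue counts over phosphosite windows
#'
#' Counts, for every offset relative to the central residue and every amino
#' acid, how many windows carry that residue at that offset. Padding
#' characters (`'_'`) are ignored, so per-offset counts sum to the number of
#' windows with a real residue at that offset.
#'
#' @param windows Character vector of equal-length windows (default width 13,
#'   site at the centre).
#' @param half_width Flank width implied by the window length.
#' @return 20 x (2*half_width+1) integer matrix; rows are amino acids,
#'   columns are offsets `-half_width ... +half_width`.
#' @export
position_residue_counts <- function(windows, half_width = 6) {
  w <- 2L * half_width + 1L
  if (length(windows) && any(nchar(windows) != w))
    stop("all windows must have length ", w)
  offs <- as.character(seq(-half_width, half_width))
  m <- matrix(0L, nrow = length(AA20), ncol = w,
              dimnames = list(AA20, offs))
  if (!length(windows)) return(m)
  chars <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                  nrow = w)
  for (j in seq_len(w)) {
    tb <- table(factor(chars[j, ], levels = AA20))
    m[, j] <- as.integer(tb)
  }
  m
}

#' Upper-tail binomial enrichment p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`: the probability of observing at
#' least `k` windows carrying a residue at an offset when the background
#' frequency of that residue there is `p0`.
#'
#' @param k Observed count, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Background success probability in (0, 1).
#' @return Upper-tail p-value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n")
  if (any(p0 <= 0) || any(p0 >= 1)) stop("p0 must lie strictly in (0, 1)")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

match_pairs <- function(windows, pairs, half_width = 6) {
  if (nrow(pairs) == 0) return(rep(TRUE, length(windows)))
  ok <- rep(TRUE, length(windows))
  for (i in seq_len(nrow(pairs))) {
    j <- pairs$offset[i] + half_width + 1L
    ok <- ok & substr(windows, j, j) == pairs$residue[i]
  }
  ok
}

#' Iterative binomial motif extraction (Motif-X-style)
#'
#' Greedy extraction of over-represented fixed (offset, residue) pairs from a
#' foreground set of phosphosite windows against a background set. Each
#' iteration computes position-specific counts in the surviving foreground
#' and background, evaluates the binomial upper-tail p-value of every
#' candidate pair with at least `min_occurrences` foreground occurrences
#' against the current background frequency, and fixes the most significant
#' pair if it beats `p_threshold`; both sets are then reduced to windows
#' matching all fixed pairs. When no pair qualifies the motif is emitted with
#' \itemize{
#'   \item `score` = sum of the stage-wise `-log10 p` values,
#'   \item `fold_change` = `(fg_matches/fg_size0) / (bg_matches/bg_size0)`
#'     with sizes taken at the start of this motif's extraction.
#' }
#' Matched foreground windows are removed and extraction restarts for the
#' next motif until the foreground is exhausted or no motif is found. Ties on
#' minimal p are broken by larger foreground count, then lexicographically on
#' (offset, residue), so output is deterministic.
#'
#' A background count of zero at a candidate pair receives a pseudo-count of
#' 0.5 occurrences to keep the background frequency in (0, 1).
#'
#' @param foreground,background Character vectors of 13-mer windows (e.g.
#'   regulated-site windows vs all identified sites). The central position is
#'   never a candidate.
#' @param p_threshold Significance threshold per fixed pair (default 1e-6,
#'   the Motif-X convention).
#' @param min_occurrences Minimum foreground support per pair (default 20).
#' @param half_width Window flank width (default 6).
#' @return Object of class `"motif_set"`: list of motifs, each with `fixed`
#'   (data.frame offset/residue/p_value), `pattern`, `central_residue`,
#'   `score`, `fold_change`, `fg_matches`, `fg_size0`, `bg_matches`,
#'   `bg_size0`.
#' @export
extract_motifs <- function(foreground, background, p_threshold = 1e-6,
                           min_occurrences = 20, half_width = 6) {
  if (!length(foreground) || !length(background))
    stop("foreground and background must be nonempty")
  if (min_occurrences > length(foreground))
    warning("min_occurrences exceeds foreground size; no motifs can be found")
  motifs <- list()
  fg <- foreground
  repeat {
    m <- extract_one_motif(fg, background, p_threshold, min_occurrences,
                           half_width)
    if (is.null(m)) break
    motifs[[length(motifs) + 1L]] <- m
    matched <- match_pairs(fg, m$fixed, half_width)
    fg <- fg[!matched]
    if (!length(fg)) break
  }
  structure(motifs, class = "motif_set",
            fg_size = length(foreground), bg_size = length(background))
}

extract_one_motif <- function(fg, bg, p_threshold, min_occurrences, half_width) {
  fg_size0 <- length(fg); bg_size0 <- length(bg)
  fixed <- data.frame(offset = integer(0), residue = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  center <- half_width + 1L
  repeat {
    fg_counts <- position_residue_counts(fg, half_width)
    bg_counts <- position_residue_counts(bg, half_width)
    fg_n <- colSums(fg_counts)
    bg_n <- colSums(bg_counts)

    best <- NULL
    for (j in seq_len(ncol(fg_counts))) {
      if (j == center || fg_n[j] == 0 || bg_n[j] == 0) next
      if (nrow(fixed) && (j - center) %in% fixed$offset) next
      for (r in AA20) {
        k <- fg_counts[r, j]
        if (k < min_occurrences) next
        p0 <- max(bg_counts[r, j], 0.5) / bg_n[j]
        if (p0 >= 1) next
        p <- binomial_enrichment(k, fg_n[j], p0)
        cand <- list(offset = j - center, residue = r, p = p, k = k)
        if (is.null(best) || better_pair(cand, best)) best <- cand
      }
    }
    if (is.null(best) || best$p >= p_threshold) break
    fixed <- rbind(fixed, data.frame(offset = best$offset,
                                     residue = best$residue,
                                     p_value = best$p,
                                     stringsAsFactors = FALSE))
    fg <- fg[match_pairs(fg, fixed, half_width)]
    bg <- bg[match_pairs(bg, fixed, half_width)]
    if (!length(fg) || !length(bg)) break
  }
  if (nrow(fixed) == 0) return(NULL)
  fg_matches <- length(fg); bg_matches <- length(bg)
  central <- central_residue_of(fg, half_width)
  list(fixed = fixed,
       pattern = motif_pattern(fixed, central, half_width),
       central_residue = central,
       score = sum(-log10(pmax(fixed$p_value, .Machine$double.xmin))),
       fold_change = (fg_matches / fg_size0) / (bg_matches / bg_size0),
       fg_matches = fg_matches, fg_size0 = fg_size0,
       bg_matches = bg_matches, bg_size0 = bg_size0)
}

# smaller p wins; ties by larger fg count, then (offset, residue) order
better_pair <- function(a, b) {
  if (a$p != b$p) return(a$p < b$p)
  if (a$k != b$k) return(a$k > b$k)
  if (a$offset != b$offset) return(a$offset < b$offset)
  a$residue < b$residue
}

central_residue_of <- function(fg, half_width) {
  center <- half_width + 1L
  cr <- unique(substr(fg, center, center))
  if (length(cr) == 1) cr else "S/T"
}

motif_pattern <- function(fixed, central, half_width) {
  span <- sort(c(fixed$offset, 0L))
  lo <- min(span, -1L); hi <- max(span, 1L)
  out <- character(0)
  for (o in lo:hi) {
    if (o == 0) out <- c(out, paste0("p", central))
    else {
      hit <- fixed$residue[fixed$offset == o]
      out <- c(out, if (length(hit)) hit else "X")
    }
  }
  paste(out, collapse = "")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("Motif extraction: %d motif(s) from %d foreground vs %d background windows\n",
              length(x), attr(x, "fg_size"), attr(x, "bg_size")))
  for (m in x) {
    cat(sprintf("  %-12s score %.2f, fold change %.2f (%d/%d fg, %d/%d bg)\n",
                m$pattern, m$score, m$fold_change,
                m$fg_matches, m$fg_size0, m$bg_matches, m$bg_size0))
  }
  invisible(x)
}

#' Tabulate an extracted motif set
#'
#' @param x A `motif_set` from [extract_motifs()].
#' @param ... Unused.
#' @return data.frame with one row per motif.
#' @export
as.data.frame.motif_set <- function(x, ...) {
  if (!length(x))
    return(data.frame(pattern = character(0), central_residue = character(0),
                      score = numeric(0), fold_change = numeric(0),
                      fg_matches = integer(0), fg_size0 = integer(0),
                      bg_matches = integer(0), bg_size0 = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(x, function(m)
    data.frame(pattern = m$pattern, central_residue = m$central_residue,
               score = m$score, fold_change = m$fold_change,
               fg_matches = m$fg_matches, fg_size0 = m$fg_size0,
               bg_matches = m$bg_matches, bg_size0 = m$bg_size0,
               stringsAsFactors = FALSE)))
}

#' Signed binomial enrichment logo matrix
#'
#' For every (offset, residue) cell, compares the foreground count against
#' the background frequency under a binomial model and reports a signed
#' log-significance: `-log10 P(X >= k)` when the residue is over-represented
#' (positive = enriched) and `+log10 P(X <= k)` when under-represented
#' (negative = depleted). Magnitudes are capped. The central cell is
#' computed and reported but carries no motif information (every window has
#' the phosphorylated residue there).
#'
#' @param foreground,background Window sets as in [extract_motifs()].
#' @param cap Magnitude cap (default 10).
#' @param half_width Window flank width (default 6).
#' @return Object of class `"logo_matrix"`: 20 x 13 signed value matrix with
#'   attributes `fg_size` and `bg_size`.
#' @export
logo_matrix <- function(foreground, background, cap = 10, half_width = 6) {
  if (!length(foreground) || !length(background))
    stop("foreground and background must be nonempty")
  fg_counts <- position_residue_counts(foreground, half_width)
  bg_counts <- position_residue_counts(background, half_width)
  fg_n <- colSums(fg_counts)
  bg_n <- colSums(bg_counts)
  vals <- matrix(0, nrow = nrow(fg_counts), ncol = ncol(fg_counts),
                 dimnames = dimnames(fg_counts))
  for (j in seq_len(ncol(vals))) {
    if (fg_n[j] == 0 || bg_n[j] == 0) next
    for (r in AA20) {
      k <- fg_counts[r, j]
      p0 <- max(bg_counts[r, j], 0.5) / bg_n[j]
      if (p0 >= 1) p0 <- 1 - 0.5 / bg_n[j]
      over <- k / fg_n[j] > p0
      if (over) {
        p <- stats::pbinom(k - 1, fg_n[j], p0, lower.tail = FALSE)
        vals[r, j] <- -log10(max(p, .Machine$double.xmin))
      } else {
        p <- stats::pbinom(k, fg_n[j], p0)
        vals[r, j] <- log10(max(p, .Machine$double.xmin))
      }
    }
  }
  vals <- pmin(pmax(vals, -cap), cap)
  structure(vals, class = c("logo_matrix", "matrix"),
            fg_size = length(foreground), bg_size = length(background))
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("Signed enrichment logo matrix (%d fg, %d bg windows)\n",
              attr(x, "fg_size"), attr(x, "bg_size")))
  print(round(unclass(x), 2))
  invisible(x)
}
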