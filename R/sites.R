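#' Map a phosphopeptide onto its protein
#'
#' Locates the plain peptide sequence (modification markers stripped) as a
#' substring of the assigned protein and converts the peptide-relative
#' phosphosite positions to 1-based protein coordinates:
#' `protein position = peptide offset + peptide-relative position - 1`.
#' Peptides occurring more than once in the protein are resolved to the first
#' occurrence with a warning.
#'
#' @param peptide_key Modified peptide sequence; phosphorylated residues are
#'   lowercase.
#' @param protein Protein sequence string.
#' @param site_positions Integer vector of peptide-relative site positions;
#'   defaults to the lowercase positions in `peptide_key`.
#' @return data.frame with `position` (protein coordinate) and `residue`.
#' @export
map_peptide_to_protein <- function(peptide_key, protein,
                                   site_positions = NULL) {
  plain <- toupper(peptide_key)
  if (is.null(site_positions)) {
    site_positions <- which(strsplit(peptide_key, "")[[1]] %in% letters)
  }
  hits <- gregexpr(plain, protein, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop(sprintf("peptide '%s' is not a substring of its assigned protein",
                 peptide_key))
  if (length(hits) > 1)
    warning(sprintf("peptide '%s' occurs %d times in protein; using first occurrence",
                    peptide_key, length(hits)))
  off <- hits[1]
  pos <- off + site_positions - 1L
  data.frame(position = as.integer(pos),
             residue = substring(protein, pos, pos),
             stringsAsFactors = FALSE)
}

#' Extract a fixed-width sequence window around a phosphosite
#'
#' Returns the residues `position - half_width` to `position + half_width`,
#' padding positions beyond the protein termini with `'_'`. With the default
#' half-width 6 this is the 13-mer conventionally used for phospho-motif
#' analysis; the phosphorylated residue sits at the centre
#' (`substr(window, half_width + 1, half_width + 1)`).
#'
#' @param protein Protein sequence string.
#' @param position 1-based residue index of the site.
#' @param half_width Flank width (default 6).
#' @return Character window of length `2 * half_width + 1`.
#' @export
extract_window <- function(protein, position, half_width = 6) {
  n <- nchar(protein)
  if (position < 1 || position > n)
    stop("position out of range: ", position)
  lo <- position - half_width; hi <- position + half_width
  core <- substring(protein, max(1L, lo), min(n, hi))
  paste0(strrep("_", max(0L, 1L - lo)), core, strrep("_", max(0L, hi - n)))
}

#' Map all phosphopeptides of a quantification table to protein sites
#'
#' Builds a site-level table from event-level evidence: each phosphosite is
#' anchored to protein coordinates, its best localization score is the
#' maximum over all supporting events (one confident observation suffices to
#' localize a site), and a centred sequence window is extracted.
#'
#' @param quant Event-level quantification table (see [validate_quant()]).
#' @param proteome Named character vector of protein sequences (or an
#'   `AAStringSet`).
#' @param half_width Window flank width (default 6).
#' @return data.frame with one row per (protein, position): `protein_id`,
#'   `position`, `residue`, `best_localization_score`, `window`,
#'   `peptide_keys` (supporting peptides, comma-separated).
#' @export
map_sites <- function(quant, proteome, half_width = 6) {
  proteome <- as_protein_vector(proteome)
  validate_quant(quant)
  ph <- quant[nzchar(quant$site_positions), , drop = FALSE]
  if (nrow(ph) == 0)
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0),
                      best_localization_score = numeric(0),
                      window = character(0), peptide_keys = character(0),
                      stringsAsFactors = FALSE))
  # resolve at the unique-peptide level, then roll event scores up per site
  upep <- unique(ph[, c("peptide_key", "protein_id", "site_positions")])
  site_rows <- vector("list", nrow(upep))
  for (i in seq_len(nrow(upep))) {
    prot <- unname(proteome[upep$protein_id[i]])
    if (is.na(prot))
      stop("no protein sequence for id ", upep$protein_id[i])
    sp <- parse_int_list(upep$site_positions[i])[[1]]
    mp <- map_peptide_to_protein(upep$peptide_key[i], prot, sp)
    site_rows[[i]] <- data.frame(peptide_key = upep$peptide_key[i],
                                 protein_id = upep$protein_id[i],
                                 site_index = seq_along(sp),
                                 position = mp$position, residue = mp$residue,
                                 stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)

  # per-event localization scores, aligned to site index within the peptide
  ev_scores <- parse_num_list(ph$localization_scores)
  ev_pos <- parse_int_list(ph$site_positions)
  ev <- data.frame(
    peptide_key = rep(ph$peptide_key, lengths(ev_pos)),
    site_index = unlist(lapply(ev_pos, seq_along), use.names = FALSE),
    score = unlist(ev_scores, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  skey <- paste(ev$peptide_key, ev$site_index, sep = "\r")
  best <- tapply(ev$score, skey, max)
  sites$best_localization_score <-
    as.numeric(best[paste(sites$peptide_key, sites$site_index, sep = "\r")])

  # collapse to unique (protein, position) records
  gkey <- paste(sites$protein_id, sites$position, sep = "\r")
  agg <- split(seq_len(nrow(sites)), gkey)
  out <- do.call(rbind, lapply(agg, function(idx) {
    s <- sites[idx, , drop = FALSE]
    data.frame(protein_id = s$protein_id[1], position = s$position[1],
               residue = s$residue[1],
               best_localization_score = max(s$best_localization_score),
               window = extract_window(unname(proteome[s$protein_id[1]]),
                                       s$position[1], half_width),
               peptide_keys = paste(unique(s$peptide_key), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$protein_id, out$position), , drop = FALSE]
}

as_protein_vector <- function(proteome) {
  if (inherits(proteome, "XStringSet")) {
    stats::setNames(as.character(proteome), names(proteome))
  } else {
    proteome
  }
}

#' Filter sites by localization confidence
#'
#' Retains sites whose best localization score is strictly above the
#' threshold (a phosphoRS-style "score above 80" rule).
#'
#' @param sites Site table from [map_sites()].
#' @param threshold Score threshold (default 80); strict inequality.
#' @return Filtered site table.
#' @export
filter_localization <- function(sites, threshold = 80) {
  sc <- sites$best_localization_score
  if (any(is.na(sc)) || any(sc < 0) || any(sc > 100))
    stop("localization scores must lie in [0, 100]")
  sites[sc > threshold, , drop = FALSE]
}

#' Roll peptide-level classifications up to sites
#'
#' A site inherits the direction of its supporting peptide(s). Sites whose
#' supporting peptides disagree in direction (up vs down) are flagged
#' `"conflict"` and should be excluded from motif foregrounds; duplicate
#' peptide evidence (e.g. missed-cleavage variants) collapses to one site
#' record.
#'
#' @param results Per-peptide results with `peptide_key` and `direction`
#'   (e.g. `fit$results` from [phosphodiff()]).
#' @param site_map Site table from [map_sites()] (optionally
#'   localization-filtered).
#' @return `site_map` with added columns `direction` (`up`, `down`,
#'   `unchanged`, or `conflict`) and `n_peptides`.
#' @export
aggregate_peptides_to_sites <- function(results, site_map) {
  dir_of <- stats::setNames(results$direction, results$peptide_key)
  peps <- strsplit(site_map$peptide_keys, ",", fixed = TRUE)
  site_map$direction <- vapply(peps, function(pk) {
    d <- unique(stats::na.omit(dir_of[pk]))
    d <- d[d != "unchanged"]
    if (length(d) == 0) "unchanged"
    else if (length(d) == 1) d
    else "conflict"
  }, character(1))
  site_map$n_peptides <- lengths(peps)
  site_map
}
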