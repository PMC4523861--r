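#' Validate an event-level quantification table
#'
#' Checks the column contract for raw SILAC quantification events: one row per
#' peptide x charge x fraction x replicate with non-negative heavy and light
#' intensities, and, for phosphopeptides, aligned peptide-relative site
#' positions and localization scores. Site positions must index S, T or Y in
#' the plain peptide sequence.
#'
#' @param quant data.frame with columns `peptide_key`, `protein_id`, `charge`,
#'   `fraction_id`, `replicate_id`, `heavy`, `light`, `site_positions`,
#'   `localization_scores` (the latter two as comma-separated strings, empty
#'   for non-phosphopeptides).
#' @return The validated data.frame, invisibly.
#' @export
validate_quant <- function(quant) {
  need <- c("peptide_key", "protein_id", "charge", "fraction_id",
            "replicate_id", "heavy", "light", "site_positions",
            "localization_scores")
  miss <- setdiff(need, names(quant))
  if (length(miss))
    stop("quant table is missing columns: ", paste(miss, collapse = ", "))
  if (any(quant$heavy < 0, na.rm = TRUE) || any(quant$light < 0, na.rm = TRUE))
    stop("channel intensities must be >= 0")
  pos_l <- parse_int_list(quant$site_positions)
  sc_l <- parse_num_list(quant$localization_scores)
  n_pos <- lengths(pos_l); n_sc <- lengths(sc_l)
  if (any(n_pos != n_sc))
    stop("site_positions and localization_scores must have equal lengths per row")
  bad_sc <- unlist(sc_l, use.names = FALSE)
  if (length(bad_sc) && (any(bad_sc < 0) || any(bad_sc > 100)))
    stop("localization scores must lie in [0, 100]")
  has <- which(n_pos > 0)
  if (length(has)) {
    plain <- toupper(quant$peptide_key[has])
    for (k in seq_along(has)) {
      i <- has[k]
      res <- substring(plain[k], pos_l[[i]], pos_l[[i]])
      if (any(!res %in% c("S", "T", "Y")))
        stop(sprintf("row %d: site position does not point at S/T/Y in '%s'",
                     i, quant$peptide_key[i]))
    }
  }
  invisible(quant)
}

parse_int_list <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE),
         function(v) as.integer(v[nzchar(v)]))
}
parse_num_list <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE),
         function(v) as.numeric(v[nzchar(v)]))
}

#' Sum channel intensities per unique peptide and replicate
#'
#' Collapses quantification events over charge states and fractions: the
#' heavy and light intensities of all events sharing a (`peptide_key`,
#' `replicate_id`) pair are summed. Peptides differing only in charge or
#' fraction collapse; peptides with different modification placement (distinct
#' keys) stay distinct. Events with zero in both channels carry no
#' quantitative information and are dropped before summation; a zero in one
#' channel still contributes to the other channel's sum.
#'
#' @param quant Validated event table (see [validate_quant()]).
#' @param validate Run [validate_quant()] first (default `TRUE`).
#' @return data.frame with columns `peptide_key`, `replicate_id`,
#'   `heavy_sum`, `light_sum`, `n_events`.
#' @export
sum_by_peptide <- function(quant, validate = TRUE) {
  if (validate) validate_quant(quant)
  if (nrow(quant) == 0)
    return(data.frame(peptide_key = character(0), replicate_id = character(0),
                      heavy_sum = numeric(0), light_sum = numeric(0),
                      n_events = integer(0), stringsAsFactors = FALSE))
  keep <- !(quant$heavy == 0 & quant$light == 0)
  quant <- quant[keep, , drop = FALSE]
  key <- paste(quant$peptide_key, quant$replicate_id, sep = "\r")
  hs <- rowsum(quant$heavy, key)
  ls <- rowsum(quant$light, key)
  ne <- rowsum(rep(1L, nrow(quant)), key)
  parts <- strsplit(rownames(hs), "\r", fixed = TRUE)
  out <- data.frame(
    peptide_key = vapply(parts, `[[`, character(1), 1L),
    replicate_id = vapply(parts, `[[`, character(1), 2L),
    heavy_sum = hs[, 1], light_sum = ls[, 1], n_events = as.integer(ne[, 1]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$peptide_key, out$replicate_id), , drop = FALSE]
}

#' Compute log2 treated/control ratios from summed channel intensities
#'
#' Applies the per-replicate label orientation (which SILAC channel received
#' the treatment) and computes `log2(treated_sum / control_sum)`. Rows where
#' either channel sum is zero are flagged unquantified with a reason code
#' rather than silently dropped.
#'
#' @param summed Output of [sum_by_peptide()].
#' @param orientation Named character vector mapping `replicate_id` to
#'   `"heavy"` or `"light"` (the treated channel). `NULL` means treated =
#'   heavy in every replicate. Every replicate present in `summed` must be
#'   covered.
#' @return `summed` with added columns `treated_sum`, `control_sum`,
#'   `log2_ratio` (NA when unquantified), `quantified` (logical) and
#'   `reason` (`""`, `"zero-numerator"` or `"zero-denominator"`).
#' @export
compute_ratio <- function(summed, orientation = NULL) {
  reps <- unique(summed$replicate_id)
  if (is.null(orientation)) {
    orientation <- stats::setNames(rep("heavy", length(reps)), reps)
  }
  unknown <- setdiff(reps, names(orientation))
  if (length(unknown))
    stop("orientation map does not cover replicate(s): ",
         paste(unknown, collapse = ", "))
  if (!all(orientation %in% c("heavy", "light")))
    stop("orientation entries must be 'heavy' or 'light'")
  treated_is_heavy <- orientation[summed$replicate_id] == "heavy"
  summed$treated_sum <- ifelse(treated_is_heavy, summed$heavy_sum, summed$light_sum)
  summed$control_sum <- ifelse(treated_is_heavy, summed$light_sum, summed$heavy_sum)
  summed$reason <- ifelse(summed$control_sum == 0, "zero-denominator",
                          ifelse(summed$treated_sum == 0, "zero-numerator", ""))
  summed$quantified <- summed$reason == ""
  summed$log2_ratio <- ifelse(summed$quantified,
                              log2(summed$treated_sum / summed$control_sum), NA_real_)
  summed
}

#' Normalize log2 ratios by the per-replicate median
#'
#' Subtracts, per biological replicate, the median log2 ratio of the
#' normalization population from every ratio, removing global mixing bias.
#' Following standard SILAC practice the default population is all quantified
#' peptides, phospho and non-phospho alike; set
#' `population = "nonphospho"`/`"phospho"` to restrict it. After
#' normalization the median of the population is exactly 0 in each replicate.
#'
#' @param ratios Output of [compute_ratio()]; peptide keys with lowercase
#'   letters mark phosphopeptides.
#' @param population `"all"` (default), `"phospho"` or `"nonphospho"`.
#' @return List with `ratios` (input plus `normalized_log2_ratio`) and
#'   `offsets` (named per-replicate median offsets).
#' @export
normalize_replicates <- function(ratios, population = c("all", "phospho", "nonphospho")) {
  population <- match.arg(population)
  if (nrow(ratios) == 0) stop("no peptide ratios to normalize")
  is_ph <- grepl("[a-z]", ratios$peptide_key)
  in_pop <- switch(population, all = rep(TRUE, nrow(ratios)),
                   phospho = is_ph, nonphospho = !is_ph)
  reps <- sort(unique(ratios$replicate_id))
  offsets <- stats::setNames(numeric(length(reps)), reps)
  for (r in reps) {
    sel <- ratios$replicate_id == r & ratios$quantified
    if (!any(sel)) stop("replicate ", r, " has no quantified peptides")
    pop_sel <- sel & in_pop
    if (!any(pop_sel))
      stop("normalization population is empty in replicate ", r,
           " while quantified peptides exist")
    offsets[r] <- stats::median(ratios$log2_ratio[pop_sel])
  }
  ratios$normalized_log2_ratio <- ratios$log2_ratio - offsets[ratios$replicate_id]
  list(ratios = ratios, offsets = offsets)
}

#' Arrange normalized ratios as a peptides x replicates matrix
#'
#' @param ratios data.frame with `peptide_key`, `replicate_id` and a value
#'   column; missing (peptide, replicate) pairs become NA.
#' @param value Name of the value column (default `"normalized_log2_ratio"`).
#' @return Numeric matrix, rownames = peptide keys, colnames = replicates.
#' @export
ratio_matrix <- function(ratios, value = "normalized_log2_ratio") {
  peps <- unique(ratios$peptide_key)
  reps <- sort(unique(ratios$replicate_id))
  m <- matrix(NA_real_, length(peps), length(reps),
              dimnames = list(peps, reps))
  m[cbind(match(ratios$peptide_key, peps),
          match(ratios$replicate_id, reps))] <- ratios[[value]]
  m
}
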