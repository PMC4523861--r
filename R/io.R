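#' Read and write the package's delimited formats
#'
#' Thin wrappers around standard readers so every table the pipeline consumes
#' or emits has one documented entry point. Quantification and site tables
#' are tab-separated with a header row; proteomes are FASTA.
#'
#' @param path File path.
#' @name silacphos-io
NULL

#' @describeIn silacphos-io Read an event-level quantification table (TSV)
#'   and validate its column contract.
#' @export
read_quant_table <- function(path) {
  q <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(site_positions = "character",
                                        localization_scores = "character"))
  q$site_positions[is.na(q$site_positions)] <- ""
  q$localization_scores[is.na(q$localization_scores)] <- ""
  validate_quant(q)
  q
}

#' @describeIn silacphos-io Write a quantification (or any) table as TSV.
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn silacphos-io Read a protein FASTA into a named character
#'   vector (first whitespace-delimited token of the header is the id).
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  stats::setNames(as.character(aa), ids)
}

#' @describeIn silacphos-io Write a named character vector of protein
#'   sequences as FASTA.
#' @param proteome Named character vector of sequences.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @describeIn silacphos-io Read a kinase PSSM: TSV with residue row names in
#'   the first column and offset column headers `-6 ... 6`.
#' @export
read_pssm <- function(path) {
  m <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(m)
}

#' Write all outputs of a synthetic experiment to a directory
#'
#' Emits `proteome.fasta`, `quant.tsv` and `truth.tsv`.
#'
#' @param sim A [simulate_silac()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "silac_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_proteome(sim$proteome, file.path(dir, "proteome.fasta"))
  write_tsv(sim$quant, file.path(dir, "quant.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Run the configured analysis path on a deposited supplementary table
#'
#' Benchmark harness: reads an externally obtained quantified-peptide table
#' (TSV with the [validate_quant()] columns), runs the full
#' quantification/normalization/test/BH path at the given settings and
#' returns the fit together with the regulated-direction counts, so results
#' recomputed from deposited study data can be compared under alternative
#' test settings (e.g. unmoderated vs moderated t).
#'
#' @param path Path to the table.
#' @param ... Passed to [phosphodiff()].
#' @return List with `fit` (a [phosphodiff()] object) and `counts` (named
#'   vector: up, down, total regulated).
#' @export
benchmark_supplementary <- function(path, ...) {
  quant <- read_quant_table(path)
  fit <- phosphodiff(quant, ...)
  d <- table(factor(fit$results$direction, levels = c("up", "down", "unchanged")))
  list(fit = fit,
       counts = c(up = unname(d[["up"]]), down = unname(d[["down"]]),
                  regulated = unname(d[["up"]] + d[["down"]])))
}
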