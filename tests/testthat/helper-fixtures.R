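# Small in-code fixtures shared across test files.

# One quantification event row with sensible defaults.
quant_row <- function(key = "AAAsAAAK", protein = "P1", charge = 2L,
                      fraction = "F1", replicate = "R1",
                      heavy = 100, light = 50,
                      positions = "4", scores = "95") {
  data.frame(peptide_key = key, protein_id = protein, charge = charge,
             fraction_id = fraction, replicate_id = replicate,
             heavy = heavy, light = light,
             site_positions = positions, localization_scores = scores,
             stringsAsFactors = FALSE)
}

quant_table <- function(...) do.call(rbind, list(...))

# Random 13-mer windows with residues drawn iid from `freqs`; optionally
# force `residue` at `offset` with probability `prob`.
random_windows <- function(n, freqs = NULL, offset = NULL, residue = NULL,
                           prob = 1, central = "S") {
  if (is.null(freqs)) {
    freqs <- rep(1 / 20, 20)
    names(freqs) <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  }
  aa <- names(freqs)
  m <- matrix(sample(aa, n * 13, replace = TRUE, prob = freqs), nrow = n)
  m[, 7] <- central
  if (!is.null(offset)) {
    hit <- runif(n) < prob
    m[hit, offset + 7] <- residue
  }
  apply(m, 1, paste, collapse = "")
}

# Brute-force BH step-up by definition: q_i = min_{j >= i} p_(j) * n / j.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
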