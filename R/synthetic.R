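#' Configuration for the synthetic SILAC phosphoproteomics generator
#'
#' Builds and validates the parameter set used by [generate_proteome()] and
#' [simulate_silac()]. Defaults emulate a SILAC experiment on a kidney
#' epithelial cell line: four biological replicates, SCX-fractionated peptides
#' observed in several charge states, log-normal intensities, and a small
#' fraction of phosphopeptides carrying planted log2 effects tied to sequence
#' motifs (basophilic motifs up-regulated, proline-directed motifs
#' down-regulated).
#'
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param protein_length Named numeric vector with elements `mean`, `sd`,
#'   `min`, `max`: residue-count distribution (normal, truncated to
#'   `[min, max]`).
#' @param residue_freqs Named numeric vector of background amino-acid
#'   frequencies over the 20 standard residues; normalised internally.
#' @param n_phosphopeptides,n_nonphospho_peptides Numbers of unique phospho-
#'   and non-phosphopeptides.
#' @param n_replicates Number of biological replicates (default 4).
#' @param n_fractions Number of SCX fractions.
#' @param charge_states Integer vector of observable precursor charge states.
#' @param frac_up,frac_down Proportions of phosphopeptides with planted
#'   positive / negative log2 effects; `frac_up + frac_down <= 1`.
#' @param effect_log2 Mean planted |log2 treated/control| effect magnitude.
#' @param noise_sd Standard deviation of the log2 measurement noise added per
#'   peptide and replicate.
#' @param intensity_scale Named numeric vector `c(meanlog=, sdlog=)` of the
#'   log-normal base (light-channel) intensity.
#' @param global_bias Numeric vector, one log2 offset per replicate (recycled
#'   from length 1); non-zero values emulate incomplete mixing and are what
#'   median normalization must remove.
#' @param planted_motifs List with elements `up` and `down`, each
#'   `list(offset=, residue=)`: the sequence feature written into the protein
#'   next to every planted regulated site. Defaults: arginine at -3 for
#'   up-regulated sites (basophilic), proline at +1 for down-regulated sites
#'   (proline-directed).
#' @param localization_score_model Named numeric vector with elements
#'   `p_high`, `high_mean`, `high_sd`, `amb_mean`, `amb_sd`: scores are drawn
#'   from a two-component mixture on \[0, 100\] (a confident mode and an
#'   ambiguous mode) so localization filtering is exercised.
#' @param missing_rate Probability that a peptide is absent from a replicate.
#'   May be a single value or one per replicate.
#' @param treated_channel Character vector, `"heavy"` or `"light"` per
#'   replicate (recycled): which SILAC channel received the treatment.
#' @param prob_st Probability that a planted central residue is serine
#'   (otherwise threonine).
#' @param seed Integer seed; all generator output is deterministic given the
#'   configuration.
#'
#' @return A validated list of class `"silac_config"`.
#' @export
synthetic_config <- function(n_proteins = 300,
                             protein_length = c(mean = 350, sd = 100, min = 60, max = 1500),
                             residue_freqs = NULL,
                             n_phosphopeptides = 1000,
                             n_nonphospho_peptides = 1000,
                             n_replicates = 4,
                             n_fractions = 3,
                             charge_states = c(2L, 3L),
                             frac_up = 0.05,
                             frac_down = 0.05,
                             effect_log2 = 1,
                             noise_sd = 0.3,
                             intensity_scale = c(meanlog = 16, sdlog = 1),
                             global_bias = 0,
                             planted_motifs = list(
                               up = list(offset = -3L, residue = "R"),
                               down = list(offset = 1L, residue = "P")
                             ),
                             localization_score_model = c(p_high = 0.8, high_mean = 95,
                                                          high_sd = 3, amb_mean = 60,
                                                          amb_sd = 10),
                             missing_rate = 0.1,
                             treated_channel = "heavy",
                             prob_st = 0.8,
                             seed = 1L) {
  if (is.null(residue_freqs)) residue_freqs <- default_residue_freqs()
  cfg <- list(
    n_proteins = n_proteins, protein_length = protein_length,
    residue_freqs = residue_freqs,
    n_phosphopeptides = n_phosphopeptides,
    n_nonphospho_peptides = n_nonphospho_peptides,
    n_replicates = as.integer(n_replicates), n_fractions = as.integer(n_fractions),
    charge_states = as.integer(charge_states),
    frac_up = frac_up, frac_down = frac_down,
    effect_log2 = effect_log2, noise_sd = noise_sd,
    intensity_scale = intensity_scale,
    global_bias = rep_len(global_bias, n_replicates),
    planted_motifs = planted_motifs,
    localization_score_model = localization_score_model,
    missing_rate = rep_len(missing_rate, n_replicates),
    treated_channel = rep_len(treated_channel, n_replicates),
    prob_st = prob_st,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "silac_config"
  cfg
}

# standard vertebrate-like amino-acid background frequencies
default_residue_freqs <- function() {
  f <- c(A = 7.0, R = 5.5, N = 3.6, D = 4.8, C = 2.2, Q = 4.4, E = 7.1,
         G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.2, F = 3.6,
         P = 6.2, S = 8.5, T = 5.4, W = 1.1, Y = 2.7, V = 6.0)
  f / sum(f)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

validate_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  }
  counts <- c("n_proteins", "n_phosphopeptides", "n_nonphospho_peptides",
              "n_replicates", "n_fractions")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v != round(v))
      stop_field(f, "must be a single positive integer")
  }
  pl <- cfg$protein_length
  if (!all(c("mean", "sd", "min", "max") %in% names(pl)))
    stop_field("protein_length", "needs named elements mean, sd, min, max")
  if (pl[["min"]] < 30 || pl[["max"]] < pl[["min"]])
    stop_field("protein_length", "requires max >= min >= 30")
  rf <- cfg$residue_freqs
  if (!all(AA20 %in% names(rf)) || any(rf < 0) || sum(rf) <= 0)
    stop_field("residue_freqs", "must be non-negative over the 20 amino acids")
  if (length(cfg$charge_states) == 0 || any(cfg$charge_states < 1))
    stop_field("charge_states", "must be a nonempty set of positive integers")
  if (cfg$frac_up < 0 || cfg$frac_down < 0 || cfg$frac_up + cfg$frac_down > 1)
    stop_field("frac_up/frac_down", "must be >= 0 and sum to at most 1")
  if (cfg$noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (any(cfg$missing_rate < 0 | cfg$missing_rate > 1))
    stop_field("missing_rate", "must lie in [0, 1]")
  if (!all(cfg$treated_channel %in% c("heavy", "light")))
    stop_field("treated_channel", "entries must be 'heavy' or 'light'")
  for (side in c("up", "down")) {
    pm <- cfg$planted_motifs[[side]]
    if (is.null(pm$offset) || is.null(pm$residue) || pm$offset == 0 ||
        abs(pm$offset) > 6 || !pm$residue %in% AA20)
      stop_field("planted_motifs", sprintf("'%s' needs offset in [-6,6]\\{0} and a standard residue", side))
  }
  invisible(cfg)
}

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` random amino-acid sequences with lengths from a
#' truncated normal and residues from the configured background frequencies.
#' Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()] object.
#' @return Named character vector of protein sequences (`sp0001`, ...).
#' @export
generate_proteome <- function(config) {
  validate_config(config)
  withr_seed(config$seed, {
    pl <- config$protein_length
    lens <- round(stats::rnorm(config$n_proteins, pl[["mean"]], pl[["sd"]]))
    lens <- pmin(pmax(lens, pl[["min"]]), pl[["max"]])
    freqs <- config$residue_freqs[AA20] / sum(config$residue_freqs)
    res <- sample(AA20, sum(lens), replace = TRUE, prob = freqs)
    ends <- cumsum(lens)
    starts <- ends - lens + 1
    seqs <- vapply(seq_along(lens), function(i)
      paste(res[starts[i]:ends[i]], collapse = ""), character(1))
    names(seqs) <- sprintf("sp%04d", seq_along(seqs))
    seqs
  })
}

# Evaluate expr under a locally-set RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Simulate a SILAC quantification table with known ground truth
#'
#' Plants phosphosites into the proteome (mutating the central residue to S/T
#' and, for regulated sites, writing the configured motif residue at its
#' offset), derives tryptic-like peptides around each site, and emits one row
#' per quantification event (peptide x charge x fraction x replicate) with
#' heavy/light intensities such that, per peptide and replicate,
#' `log2(treated/control) = true_effect + global_bias + noise`. The base
#' intensity is log-normal and split multiplicatively across the events of a
#' peptide with identical weights in both channels, so the ratio-of-sums over
#' events recovers the planted ratio exactly when `noise_sd = 0`.
#'
#' @param config A [synthetic_config()] object.
#' @param proteome Optional proteome from [generate_proteome()]; generated
#'   from `config` when `NULL`. Note the returned `proteome` component carries
#'   the planted mutations and is the one downstream mapping must use.
#' @return A list of class `"silac_sim"` with components `quant` (the
#'   event-level quantification data.frame), `truth` (per-peptide ground
#'   truth: planted effect, regulation flag, motif class, protein site),
#'   `proteome` (mutated sequences), and `config`.
#' @export
simulate_silac <- function(config, proteome = NULL) {
  validate_config(config)
  if (is.null(proteome)) proteome <- generate_proteome(config)
  if (length(proteome) == 0) stop("proteome must be nonempty")

  withr_seed(config$seed + 1L, {
    sim <- build_peptides(config, proteome)
    quant <- build_events(config, sim$peptides)
    list_out <- list(quant = quant, truth = sim$truth,
                     proteome = sim$proteome, config = config)
    class(list_out) <- "silac_sim"
    list_out
  })
}

# Choose site slots, mutate the proteome, derive peptides and ground truth.
build_peptides <- function(config, proteome) {
  lens <- nchar(proteome)
  # candidate site positions spaced 20 residues apart: windows (+/-6) of
  # distinct sites never overlap, so planted motifs cannot collide
  slot_prot <- integer(0); slot_pos <- integer(0)
  for (i in seq_along(proteome)) {
    if (lens[i] < 30) next
    pos <- seq(12L, lens[i] - 12L, by = 20L)
    slot_prot <- c(slot_prot, rep(i, length(pos)))
    slot_pos <- c(slot_pos, pos)
  }
  n_ph <- config$n_phosphopeptides
  if (length(slot_pos) < n_ph)
    stop("proteome too small for requested number of phosphopeptides")
  pick <- sample(length(slot_pos), n_ph)
  sprot <- slot_prot[pick]; spos <- slot_pos[pick]

  n_up <- round(config$frac_up * n_ph)
  n_down <- round(config$frac_down * n_ph)
  reg <- c(rep("up", n_up), rep("down", n_down), rep("none", n_ph - n_up - n_down))

  central <- ifelse(stats::runif(n_ph) < config$prob_st, "S", "T")
  for (j in seq_len(n_ph)) {
    substr(proteome[sprot[j]], spos[j], spos[j]) <- central[j]
    if (reg[j] != "none") {
      pm <- config$planted_motifs[[reg[j]]]
      mp <- spos[j] + pm$offset
      substr(proteome[sprot[j]], mp, mp) <- pm$residue
    }
  }

  mag <- rtrunc_norm(n_ph, config$effect_log2, 0.2 * config$effect_log2,
                     0.2, Inf)
  true_log2 <- ifelse(reg == "up", mag, ifelse(reg == "down", -mag, 0))

  up_off <- sample(4:9, n_ph, replace = TRUE)
  dn_off <- sample(4:9, n_ph, replace = TRUE)
  start <- pmax(1L, spos - up_off)
  end <- pmin(lens[sprot], spos + dn_off)
  plain <- substr(proteome[sprot], start, end)
  rel <- spos - start + 1L
  key <- plain
  substr(key, rel, rel) <- tolower(substr(key, rel, rel))

  ph <- data.frame(
    peptide_key = key,
    protein_id = names(proteome)[sprot],
    rel_pos = rel,
    site_pos = spos,
    is_phospho = TRUE,
    true_log2 = true_log2,
    regulated = reg,
    motif_class = ifelse(reg == "up", "basophilic",
                         ifelse(reg == "down", "proline-directed", "none")),
    stringsAsFactors = FALSE
  )

  # non-phospho peptides: random substrings, no sites, never regulated
  n_np <- config$n_nonphospho_peptides
  np_prot <- sample(seq_along(proteome), n_np, replace = TRUE)
  np_len <- sample(8:22, n_np, replace = TRUE)
  np_start <- pmax(1L, floor(stats::runif(n_np) * pmax(1, lens[np_prot] - np_len)) + 1L)
  np_seq <- substr(proteome[np_prot], np_start, pmin(lens[np_prot], np_start + np_len - 1L))
  np <- data.frame(
    peptide_key = np_seq,
    protein_id = names(proteome)[np_prot],
    rel_pos = NA_integer_,
    site_pos = NA_integer_,
    is_phospho = FALSE,
    true_log2 = 0,
    regulated = "none",
    motif_class = "none",
    stringsAsFactors = FALSE
  )

  peptides <- rbind(ph, np)
  # collapse accidental duplicate keys (rare): keep first occurrence
  peptides <- peptides[!duplicated(peptides$peptide_key), , drop = FALSE]
  rownames(peptides) <- NULL

  truth <- peptides[, c("peptide_key", "protein_id", "site_pos", "is_phospho",
                        "true_log2", "regulated", "motif_class")]
  list(peptides = peptides, truth = truth, proteome = proteome)
}

# Expand peptides into quantification events across replicates, charges and
# fractions, drawing intensities under the configured noise model.
build_events <- function(config, peptides) {
  n_pep <- nrow(peptides)
  R <- config$n_replicates
  C <- length(config$charge_states)
  F_ <- config$n_fractions

  pep_idx <- rep(seq_len(n_pep), each = R)
  rep_idx <- rep(seq_len(R), times = n_pep)
  present <- stats::runif(length(pep_idx)) >= config$missing_rate[rep_idx]
  pep_idx <- pep_idx[present]; rep_idx <- rep_idx[present]
  n_ppr <- length(pep_idx)
  if (n_ppr == 0) {
    return(empty_quant())
  }

  noise <- stats::rnorm(n_ppr, 0, config$noise_sd)
  log2r <- peptides$true_log2[pep_idx] + config$global_bias[rep_idx] + noise
  light_tot <- stats::rlnorm(n_ppr, config$intensity_scale[["meanlog"]],
                             config$intensity_scale[["sdlog"]])
  heavy_tot <- light_tot * 2^log2r

  # charge states: per peptide-replicate include each charge w.p. 0.6, always
  # keeping a randomly chosen primary charge
  primary_c <- sample.int(C, n_ppr, replace = TRUE)
  inc_c <- matrix(stats::runif(n_ppr * C) < 0.6, n_ppr, C)
  inc_c[cbind(seq_len(n_ppr), primary_c)] <- TRUE
  # fractions: a primary fraction, plus the next one w.p. 0.3
  primary_f <- sample.int(F_, n_ppr, replace = TRUE)
  inc_f <- matrix(FALSE, n_ppr, F_)
  inc_f[cbind(seq_len(n_ppr), primary_f)] <- TRUE
  nxt <- primary_f + 1L
  take2 <- stats::runif(n_ppr) < 0.3 & nxt <= F_
  inc_f[cbind(which(take2), nxt[take2])] <- TRUE

  nc <- rowSums(inc_c); nf <- rowSums(inc_f)
  nev <- nc * nf
  ev_ppr <- rep(seq_len(n_ppr), nev)

  charges_list <- apply(inc_c, 1, which, simplify = FALSE)
  fracs_list <- apply(inc_f, 1, which, simplify = FALSE)
  ev_charge <- unlist(lapply(seq_len(n_ppr), function(i)
    rep(charges_list[[i]], times = nf[i])), use.names = FALSE)
  ev_frac <- unlist(lapply(seq_len(n_ppr), function(i)
    rep(fracs_list[[i]], each = nc[i])), use.names = FALSE)

  # Dirichlet(1) split of the peptide total across its events, identical in
  # both channels: preserves the ratio-of-sums identity
  g <- stats::rexp(length(ev_ppr))
  tot_g <- rowsum(g, ev_ppr)[, 1]
  w <- g / tot_g[ev_ppr]

  treated_ev <- heavy_tot[ev_ppr] * w
  control_ev <- light_tot[ev_ppr] * w
  swap <- config$treated_channel[rep_idx[ev_ppr]] == "light"
  heavy_ev <- ifelse(swap, control_ev, treated_ev)
  light_ev <- ifelse(swap, treated_ev, control_ev)

  is_ph <- peptides$is_phospho[pep_idx[ev_ppr]]
  lsm <- config$localization_score_model
  n_ev <- length(ev_ppr)
  hi <- stats::runif(n_ev) < lsm[["p_high"]]
  score <- ifelse(hi,
                  rtrunc_norm(n_ev, lsm[["high_mean"]], lsm[["high_sd"]], 0, 100),
                  rtrunc_norm(n_ev, lsm[["amb_mean"]], lsm[["amb_sd"]], 0, 100))

  data.frame(
    peptide_key = peptides$peptide_key[pep_idx[ev_ppr]],
    protein_id = peptides$protein_id[pep_idx[ev_ppr]],
    charge = config$charge_states[ev_charge],
    fraction_id = sprintf("F%d", ev_frac),
    replicate_id = sprintf("R%d", rep_idx[ev_ppr]),
    heavy = heavy_ev,
    light = light_ev,
    site_positions = ifelse(is_ph,
                            as.character(peptides$rel_pos[pep_idx[ev_ppr]]), ""),
    localization_scores = ifelse(is_ph, formatC(score, format = "f", digits = 2), ""),
    stringsAsFactors = FALSE
  )
}

empty_quant <- function() {
  data.frame(peptide_key = character(0), protein_id = character(0),
             charge = integer(0), fraction_id = character(0),
             replicate_id = character(0), heavy = numeric(0),
             light = numeric(0), site_positions = character(0),
             localization_scores = character(0), stringsAsFactors = FALSE)
}

#' @export
print.silac_sim <- function(x, ...) {
  cat("Synthetic SILAC experiment\n")
  cat(sprintf("  %d quantification events, %d unique peptides, %d replicates\n",
              nrow(x$quant), length(unique(x$quant$peptide_key)),
              x$config$n_replicates))
  tt <- table(x$truth$regulated)
  cat(sprintf("  planted regulation: %s up, %s down (of %d phosphopeptides)\n",
              if ("up" %in% names(tt)) tt[["up"]] else 0L,
              if ("down" %in% names(tt)) tt[["down"]] else 0L,
              sum(x$truth$is_phospho)))
  invisible(x)
}
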