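---
title: "Quantitative SILAC phosphoproteomics with silacphos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SILAC phosphoproteomics with silacphos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacphos)
```

## The experiment this package models

In a SILAC experiment two cell populations — one grown in "light" medium,
one in "heavy" medium with mass-shifted lysine and arginine — are pooled
after treatment and measured together. Every peptide appears in the mass
spectra twice, and the heavy-to-light intensity ratio is a direct
treated-versus-control abundance ratio, immune to run-to-run variation. For
phosphoproteomics the digest is fractionated by strong cation exchange
(SCX), phosphopeptides are enriched, and each unique peptide is typically
observed several times: in multiple charge states and in multiple fractions,
in each biological replicate.

`silacphos` implements the downstream quantitative analysis of such an
experiment: from an event-level quantification table to regulated
phosphosites and the kinase substrate motifs they carry.

## Peptide quantification: ratio of sums

The quantification of a unique peptide in a replicate is obtained from the
**sum of raw intensities** over all of its events (charge states x
fractions), separately per channel, and the ratio is formed from the summed
values:

$$ r_{p} = \log_2 \frac{\sum_{e} H_{p,e}}{\sum_{e} L_{p,e}} $$

This ratio-of-sums weights each spectrum by its intensity. It is not the
mean of per-event log-ratios: low-intensity events with noisy ratios are
naturally down-weighted. The test suite carries a regression case where the
two estimators disagree and the ratio-of-sums value is required.

Design points:

* The **peptide key is the full modified sequence** including
  phosphorylation placement (lowercase residue). Two placements of the same
  phosphate on the same backbone are different measurable species and are
  never co-summed.
* An event that is zero in **both** channels carries no information and is
  dropped before summation; a zero in one channel still contributes to the
  other channel's sum.
* A peptide whose summed ratio has a zero numerator or denominator is
  flagged (`zero-numerator` / `zero-denominator`) and excluded downstream —
  flagged, not silently removed.
* The treated condition may sit in either SILAC channel, per replicate
  (label swaps); `compute_ratio()` takes an orientation map and always
  reports log2 treated/control.

## Normalization

Small errors in 1:1 mixing shift all ratios of a replicate
multiplicatively. Each replicate is therefore centred by subtracting its
**median log2 ratio**, computed over *all* quantified peptides — including
peptides from the non-phosphorylated fractions, which are the bulk of the
population and are not expected to respond to treatment. After subtraction
the population median is zero by construction (to machine precision). The
median is taken over defined ratios only (a ratio that does not exist cannot
enter a median) with the usual midpoint rule for even counts.

## Replicate statistics and FDR

Peptides quantified in **at least three replicates** are tested
(`min_replicates = 3`, configurable). The default test is a two-sided
one-sample Student t of the normalized log2 ratios against zero; p-values
are corrected by Benjamini–Hochberg step-up and peptides with q at or below
the **10% FDR** threshold are called regulated, with the direction given by
the sign of the mean log2 ratio.

Degenerate rows are flagged rather than propagated as NaN: zero variance
with zero mean gives p = 1, zero variance with a nonzero mean gives the
smallest representable p.

**Sensitivity at n = 4.** With four replicates the t test has three degrees
of freedom, and BH-adjusted significance requires t statistics around 9.
Under our reference simulation (mean |log2| effect 1, measurement noise sd
0.3) that yields roughly one-third sensitivity at controlled FDR. The
`method = "moderated"` option (limma's empirical-Bayes moderated t, which
shrinks per-peptide variances toward a common prior) recovers ~95% of
planted effects under identical conditions while keeping the empirical FDR
under the nominal level. The unmoderated t remains the default because it
makes the fewest assumptions; the moderated variant is the practical choice
for few-replicate designs, and the acceptance report computes both.

## Site mapping and localization filtering

Peptide evidence is anchored to protein coordinates by exact substring
search (first occurrence wins, with a warning, for the rare peptide that
occurs twice). The per-site localization confidence is the **maximum** score
over supporting events — one confidently localized spectrum suffices — and
sites are kept when the score is **strictly above 80** on the 0–100
phosphoRS-style scale. Each site gets a 13-mer window (six residues each
side, `_`-padded at protein termini); 13 is the de facto standard width for
phospho-motif work and is configurable. All coordinates are 1-based,
matching site nomenclature such as "Thr-58".

When several peptides (e.g. missed-cleavage variants) support one site, the
site inherits their common direction; disagreeing peptides mark the site
`conflict`, which is excluded from motif foregrounds.

## Motif extraction

`extract_motifs()` is a greedy iterative procedure over a foreground
(regulated-site windows) and a background (all confidently localized site
windows). At each step, for every (offset, residue) pair with at least
`min_occurrences = 20` foreground occurrences, the upper-tail binomial
p-value of the foreground count against the current background frequency is
computed; the smallest p wins if it beats `p_threshold = 1e-6`, the pair is
fixed, and both sets are reduced to windows matching all fixed pairs. When
no pair qualifies the motif is emitted with

* **score** = sum of stage-wise $-\log_{10} p$ values, and
* **fold change** = foreground match rate over background match rate, both
  measured against the set sizes at the start of that motif's extraction,

after which matched windows are removed and the search restarts for the
next motif. The two thresholds follow the established Motif-X convention
and are exposed as arguments. Ties on p are broken by larger foreground
count, then lexicographic (offset, residue), making the output
deterministic. A zero background count receives a pseudo-count of 0.5
occurrences so the background frequency stays inside (0, 1). There is no
multiple-testing correction across the (offset, residue) grid — the hard
1e-6 threshold is the convention's control.

The signed logo matrix (`logo_matrix()`) reports, per cell,
$-\log_{10} P(X \ge k)$ for over-represented residues and
$+\log_{10} P(X \le k)$ for under-represented ones (so depletion is
negative), capped at ±10. This binomial-significance definition is this
package's statistic for enrichment logos; tools differ in the exact
information measure they draw, so the matrix export is the interface and
rendering is left to the user.

Central-residue handling: serine- and threonine-centred windows are pooled
by default (a motif is reported as pS/pT by its observed centres); pass
per-centre foregrounds to separate them.

## Kinase annotation

`classify_window()` applies the standard substrate-motif reading in fixed
priority order: proline-directed (P at +1; a strict mode additionally
requires P at −2, for the stricter reading of "proline at +1 and −2"),
basophilic (R/K at −3 or −2, H at −3 — basic residues upstream), acidophilic
(two or more of D/E in +1…+3), else other. Priority order means every
window gets exactly one class; the proline rule fires first because P at +1
is the defining CDK/MAPK feature even when basic residues are present.

Network-context kinase prediction is out of scope; instead `pssm_score()`
scores windows against user-supplied position-specific scoring matrices
(additive log-odds, padding contributes zero), which supports family-level
summaries when curated kinase matrices are available. This is a documented
methodological substitution, not an emulation of any specific predictor.

## The synthetic-data generator

`simulate_silac()` generates the full data structure with known ground
truth, so every stage is testable without raw mass-spectrometry data:

* a random proteome (truncated-normal lengths, configurable residue
  frequencies);
* phosphosites planted on a 20-residue grid (site windows can never
  overlap), central residue set to S (80%) or T;
* regulated sites carry a planted motif residue written into the protein —
  arginine at −3 for up-regulated (basophilic), proline at +1 for
  down-regulated (proline-directed) — so motif discovery has a recoverable
  signal that is *in the sequence*, exactly as in real data;
* per peptide and replicate, $\log_2(T/C) = \text{effect} + \text{bias}_r +
  \varepsilon$, with $\varepsilon \sim N(0, \sigma)$; the log-normal base
  intensity is split across a peptide's events by a Dirichlet(1) partition
  applied identically to both channels, which preserves the ratio-of-sums
  identity — at $\sigma = 0$ the pipeline recovers planted effects to
  machine precision, a strong end-to-end correctness check;
* planted effect magnitudes are truncated-normal around `effect_log2`
  (sd 20%, floor 0.2), so `effect_log2` is the mean planted magnitude
  rather than a single spike — closer to real regulation spectra;
* localization scores come from a two-component mixture (confident mode
  near 95, ambiguous mode near 60) so the score filter is exercised;
* per-replicate missingness, global log2 biases and label orientation are
  configurable (`missing_rate`, `global_bias`, `treated_channel`).

Defaults: 4 replicates (a ≥3-replicate testability filter implies at least
four collected), 300 proteins, 1000 phosphopeptides + 1000 non-phospho
peptides, 3 fractions, charges {2, 3}, 5% up / 5% down at mean |log2| = 1,
noise sd 0.3, 10% missingness.

What it does **not** emulate: spectrum-level noise, retention time,
missing-not-at-random intensity dependence, isotope impurity, or
identification error. Passing tests therefore demonstrate correctness of
the quantification-to-motif chain under the stated noise model, not
robustness to identification artefacts.

## Numerical and design notes

* Binomial tails use R's exact `pbinom`; the suite verifies agreement with
  term-by-term summation to 1e-12 relative error.
* BH is `p.adjust(method = "BH")` behind a validating wrapper; the suite
  checks it against a brute-force step-up oracle on exhaustive small inputs.
* The rowwise t test is vectorised (closed-form statistic), which keeps a
  200-simulation null calibration of 5000-peptide experiments in the
  two-minute range; single rows are cross-checked against `stats::t.test`.
* Localization filtering is strictly `> threshold`; ties at the threshold
  are excluded.
* Problem sizes used by the validation suite and the acceptance report —
  2000–5000 peptides, 100–200 simulation seeds, 50 motif extractions — were
  chosen as the smallest sizes at which the Monte-Carlo error of each check
  is well below its acceptance margin.

## Known limitations

* Site aggregation assumes one direction per site; genuinely bidirectional
  regulation (different peptides of one site moving oppositely) is reported
  as `conflict` rather than resolved.
* Isoform-aware mapping is out of scope: a peptide is mapped within its
  assigned protein only.
* The moderated test borrows strength across peptides and assumes
  exchangeable variances; with strongly heteroscedastic data the default t
  is the safer choice.
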