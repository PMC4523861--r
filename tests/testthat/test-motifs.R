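test_that("position-residue counts ignore padding and match a recount loop", {
  m0 <- position_residue_counts("______S______")
  expect_equal(sum(m0[, colnames(m0) != "0"]), 0)
  expect_equal(m0["S", "0"], 1L)

  w3 <- c("AAARAASAAAAAA", "CCCRCCSCCCCCC", "GGGRGGSGGGGGG")
  m3 <- position_residue_counts(w3)
  expect_equal(m3["R", "-3"], 3L)

  expect_error(position_residue_counts("SHORT"), "length 13")

  set.seed(60)
  ws <- random_windows(40)
  m <- position_residue_counts(ws)
  # brute-force recount, character by character
  for (j in 1:13) {
    for (r in rownames(m)) {
      cnt <- 0L
      for (w in ws) if (substr(w, j, j) == r) cnt <- cnt + 1L
      expect_identical(m[r, as.character(j - 7)], cnt)
    }
  }
  expect_equal(colSums(m), setNames(rep(40L, 13), colnames(m)))
})

test_that("binomial upper tails match closed forms and term-by-term summation", {
  expect_equal(binomial_enrichment(0, 10, 0.3), 1)
  expect_equal(binomial_enrichment(10, 10, 0.5), 2^-10, tolerance = 1e-12)

  brute <- function(k, n, p0) sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
  for (case in list(c(10, 20, 0.05), c(3, 8, 0.2), c(7, 7, 0.9),
                    c(1, 30, 0.01), c(25, 40, 0.5))) {
    k <- case[1]; n <- case[2]; p0 <- case[3]
    expect_equal(binomial_enrichment(k, n, p0), brute(k, n, p0),
                 tolerance = 1e-12)
  }
  expect_error(binomial_enrichment(5, 3, 0.1), "k <= n")
  expect_error(binomial_enrichment(1, 3, 0), "strictly in")
})

test_that("no motifs are extracted when foreground equals background", {
  set.seed(61)
  ws <- random_windows(300)
  ms <- extract_motifs(ws, ws, min_occurrences = 10)
  expect_length(ms, 0)
})

test_that("a planted pair is found with the binomial-oracle score", {
  set.seed(62)
  freqs <- setNames(rep(0.05, 20), rownames(position_residue_counts(character(0))))
  fg <- random_windows(200, freqs = freqs, offset = -3, residue = "R",
                       prob = 0.9)
  bg <- random_windows(3000, freqs = freqs)
  ms <- extract_motifs(fg, bg)
  expect_gte(length(ms), 1)
  first <- ms[[1]]
  expect_equal(first$fixed$offset[1], -3)
  expect_equal(first$fixed$residue[1], "R")

  # oracle: the stage-1 p-value recomputed from the raw counts
  k <- sum(substr(fg, 4, 4) == "R")
  p0 <- max(sum(substr(bg, 4, 4) == "R"), 0.5) / length(bg)
  p_oracle <- sum(dbinom(k:length(fg), length(fg), p0))
  expect_equal(first$fixed$p_value[1], p_oracle, tolerance = 1e-12)

  # fold change uses sizes at extraction start
  if (nrow(first$fixed) == 1) {
    fc_oracle <- (first$fg_matches / 200) / (first$bg_matches / 3000)
    expect_equal(first$fold_change, fc_oracle)
  }
})

test_that("extraction reduces both sets soundly and scores add stage-wise", {
  set.seed(63)
  fg <- random_windows(150, offset = -3, residue = "R", prob = 0.95)
  # add a second signal at +1 so a two-pair motif can emerge
  idx <- runif(150) < 0.9
  substr(fg[idx], 8, 8) <- "P"
  bg <- random_windows(2000)
  ms <- extract_motifs(fg, bg, min_occurrences = 10)
  expect_gte(length(ms), 1)
  m <- ms[[1]]
  expect_gte(nrow(m$fixed), 2)
  # soundness: every counted match really carries all fixed residues
  match_all <- function(w) all(substring(w, m$fixed$offset + 7,
                                         m$fixed$offset + 7) == m$fixed$residue)
  fg_m <- sum(vapply(fg, match_all, logical(1)))
  bg_m <- sum(vapply(bg, match_all, logical(1)))
  expect_equal(m$fg_matches, fg_m)
  expect_equal(m$bg_matches, bg_m)
  # additivity of the motif score over stage-wise p-values
  expect_equal(m$score, sum(-log10(m$fixed$p_value)), tolerance = 1e-12)
  # distinct fixed offsets
  expect_equal(anyDuplicated(m$fixed$offset), 0)
})

test_that("extraction is deterministic and respects min_occurrences", {
  set.seed(64)
  fg <- random_windows(100, offset = 2, residue = "K", prob = 0.8)
  bg <- random_windows(1000)
  a <- extract_motifs(fg, bg, min_occurrences = 10)
  b <- extract_motifs(fg, bg, min_occurrences = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_warning(out <- extract_motifs(fg[1:5], bg, min_occurrences = 20),
                 "min_occurrences")
  expect_length(out, 0)
  expect_error(extract_motifs(character(0), bg), "nonempty")
})

test_that("motif patterns read as centred consensus strings", {
  set.seed(65)
  freqs <- setNames(rep(0.05, 20), rownames(position_residue_counts(character(0))))
  fg <- random_windows(200, freqs = freqs, offset = -3, residue = "R",
                       prob = 0.95)
  bg <- random_windows(3000, freqs = freqs)
  ms <- extract_motifs(fg, bg)
  expect_match(ms[[1]]$pattern, "R..pS|RXXpS")
  df <- as.data.frame(ms)
  expect_true(all(c("pattern", "score", "fold_change") %in% names(df)))
  expect_output(print(ms), "score")
})

test_that("logo values are signed, capped, and near zero without enrichment", {
  set.seed(66)
  bg <- random_windows(4000)
  fg <- random_windows(400)
  lm0 <- logo_matrix(fg, bg)
  off_centre <- lm0[, colnames(lm0) != "0"]
  # fg drawn from the bg distribution: almost all cells below -log10(0.01)
  expect_gte(mean(abs(off_centre) < 2), 0.95)

  # forced depletion: fg has no P at +1 while bg is P-rich there
  fgd <- random_windows(100)
  substr(fgd, 8, 8) <- "A"
  bgd <- random_windows(1000)
  substr(bgd, 8, 8) <- ifelse(runif(1000) < 0.3, "P", substr(bgd, 8, 8))
  lmd <- logo_matrix(fgd, bgd)
  expect_lt(lmd["P", "1"], -5)

  capd <- logo_matrix(fgd, bgd, cap = 3)
  expect_true(all(abs(capd) <= 3))
})
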