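test_that("intensities sum over charge states and fractions per peptide", {
  q <- quant_table(
    quant_row(charge = 2L, heavy = 100, light = 50),
    quant_row(charge = 3L, heavy = 50, light = 25)
  )
  s <- sum_by_peptide(q)
  expect_equal(nrow(s), 1)
  expect_equal(s$heavy_sum, 150)
  expect_equal(s$light_sum, 75)

  q2 <- rbind(q, quant_row(key = "AAAtAAAK", heavy = 10, light = 10))
  s2 <- sum_by_peptide(q2)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$heavy_sum[s2$peptide_key == "AAAtAAAK"], 10)
})

test_that("summation matches a naive per-record loop on random tables", {
  set.seed(21)
  n <- 300
  q <- quant_row()[rep(1, n), ]
  q$peptide_key <- sample(c("AAsAK", "GGtGGR", "LLyLLK", "MMsMMR"), n, TRUE)
  q$site_positions <- c(AAsAK = "3", GGtGGR = "3", LLyLLK = "3",
                        MMsMMR = "3")[q$peptide_key]
  q$replicate_id <- sample(paste0("R", 1:3), n, TRUE)
  q$charge <- sample(2:4, n, TRUE)
  q$fraction_id <- sample(paste0("F", 1:3), n, TRUE)
  q$heavy <- runif(n, 0, 1e6)
  q$light <- runif(n, 0, 1e6)
  s <- sum_by_peptide(q)
  for (i in seq_len(nrow(s))) {
    sel <- q$peptide_key == s$peptide_key[i] & q$replicate_id == s$replicate_id[i]
    hs <- 0; ls <- 0
    for (j in which(sel)) { hs <- hs + q$heavy[j]; ls <- ls + q$light[j] }
    expect_equal(s$heavy_sum[i], hs)
    expect_equal(s$light_sum[i], ls)
  }
})

test_that("validation rejects malformed quantification tables", {
  expect_error(validate_quant(quant_row(heavy = -1)), ">= 0")
  expect_error(validate_quant(quant_row(positions = "1,4", scores = "90")),
               "equal lengths")
  expect_error(validate_quant(quant_row(scores = "150")), "\\[0, 100\\]")
  # position 2 is an A, not S/T/Y
  expect_error(validate_quant(quant_row(positions = "2")), "S/T/Y")
  expect_error(validate_quant(quant_row()[, -6]), "missing columns")
})

test_that("log2 ratios follow the treated/control orientation", {
  s <- sum_by_peptide(quant_table(
    quant_row(charge = 2L, heavy = 100, light = 50),
    quant_row(charge = 3L, heavy = 50, light = 25)
  ))
  r <- compute_ratio(s)
  expect_equal(r$log2_ratio, 1.0)

  r_eq <- compute_ratio(data.frame(peptide_key = "AAsA", replicate_id = "R1",
                                   heavy_sum = 100, light_sum = 100))
  expect_equal(r_eq$log2_ratio, 0)

  r_sw <- compute_ratio(s, orientation = c(R1 = "light"))
  expect_equal(r_sw$log2_ratio, -1.0)

  expect_error(compute_ratio(s, orientation = c(R9 = "heavy")),
               "does not cover")
})

test_that("zero channel sums are flagged with reason codes, not dropped", {
  s <- data.frame(peptide_key = c("a", "b", "c"),
                  replicate_id = "R1",
                  heavy_sum = c(10, 0, 10), light_sum = c(0, 10, 10))
  r <- compute_ratio(s)
  expect_equal(r$reason, c("zero-denominator", "zero-numerator", ""))
  expect_equal(r$quantified, c(FALSE, FALSE, TRUE))
  expect_equal(sum(is.na(r$log2_ratio)), 2)
  expect_equal(nrow(r), 3)
})

test_that("per-replicate median normalization matches hand-worked offsets", {
  mk <- function(lr) data.frame(peptide_key = paste0("p", seq_along(lr), "s"),
                                replicate_id = "R1",
                                log2_ratio = lr, quantified = TRUE,
                                stringsAsFactors = FALSE)
  n0 <- normalize_replicates(mk(c(-1, 0, 3)))
  expect_equal(unname(n0$offsets), 0)
  expect_equal(n0$ratios$normalized_log2_ratio, c(-1, 0, 3))

  n1 <- normalize_replicates(mk(c(1, 2, 4)))
  expect_equal(unname(n1$offsets), 2)
  expect_equal(n1$ratios$normalized_log2_ratio, c(-1, 0, 2))

  expect_error(normalize_replicates(mk(0)[0, ]), "no peptide ratios")
})

test_that("normalization population can be restricted and errors when empty", {
  tab <- data.frame(peptide_key = c("AAsAA", "GGGGG"), replicate_id = "R1",
                    log2_ratio = c(2, 0), quantified = TRUE,
                    stringsAsFactors = FALSE)
  n_np <- normalize_replicates(tab, population = "nonphospho")
  expect_equal(unname(n_np$offsets), 0)
  tab_ph_only <- tab[1, ]
  expect_error(normalize_replicates(tab_ph_only, population = "nonphospho"),
               "population is empty")
})

test_that("after normalization the population median is exactly zero", {
  sim <- simulate_silac(synthetic_config(n_proteins = 80,
                                         n_phosphopeptides = 200,
                                         n_nonphospho_peptides = 200,
                                         global_bias = c(0.3, -0.2, 0.7, 0),
                                         seed = 30))
  norm <- normalize_replicates(compute_ratio(sum_by_peptide(sim$quant)))
  meds <- tapply(norm$ratios$normalized_log2_ratio[norm$ratios$quantified],
                 norm$ratios$replicate_id[norm$ratios$quantified], median)
  expect_equal(as.numeric(meds), rep(0, 4))
})

test_that("log2 ratios are invariant to rescaling a replicate's intensities", {
  sim <- simulate_silac(synthetic_config(n_proteins = 40,
                                         n_phosphopeptides = 60,
                                         n_nonphospho_peptides = 60, seed = 31))
  q <- sim$quant
  r0 <- compute_ratio(sum_by_peptide(q))
  sel <- q$replicate_id == "R1"
  q$heavy[sel] <- q$heavy[sel] * 37.5
  q$light[sel] <- q$light[sel] * 37.5
  r1 <- compute_ratio(sum_by_peptide(q))
  m <- merge(r0, r1, by = c("peptide_key", "replicate_id"))
  expect_equal(m$log2_ratio.x, m$log2_ratio.y, tolerance = 1e-12)
})

test_that("ratio-of-sums is used, not mean-of-ratios", {
  # two charge states with discordant per-event ratios: 100/10 and 10/100
  q <- quant_table(
    quant_row(charge = 2L, heavy = 100, light = 10),
    quant_row(charge = 3L, heavy = 10, light = 100)
  )
  r <- compute_ratio(sum_by_peptide(q))
  ratio_of_sums <- log2(110 / 110)
  mean_of_ratios <- mean(c(log2(100 / 10), log2(10 / 100)))
  expect_equal(r$log2_ratio, ratio_of_sums)
  # here the two coincide numerically (0); distinguish with an asymmetric case
  q2 <- quant_table(
    quant_row(charge = 2L, heavy = 100, light = 10),
    quant_row(charge = 3L, heavy = 20, light = 80)
  )
  r2 <- compute_ratio(sum_by_peptide(q2))
  expect_equal(r2$log2_ratio, log2(120 / 90))
  expect_false(isTRUE(all.equal(r2$log2_ratio,
                                mean(c(log2(10), log2(0.25))))))
})

test_that("events that are zero in both channels do not inflate event counts", {
  q <- quant_table(
    quant_row(charge = 2L, heavy = 100, light = 50),
    quant_row(charge = 3L, heavy = 0, light = 0),
    quant_row(charge = 4L, heavy = 0, light = 25)
  )
  s <- sum_by_peptide(q)
  expect_equal(s$n_events, 2L)
  expect_equal(s$heavy_sum, 100)
  expect_equal(s$light_sum, 75)
})
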