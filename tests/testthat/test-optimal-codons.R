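test_that("extreme-CAI partition uses the ceiling rule and gene-id ties", {
  vals <- setNames(seq(0.3, 0.9, length.out = 40), sprintf("g%02d", 1:40))
  p <- partition_by_cai(vals, fraction = 0.10)
  expect_equal(length(p$high), 4)
  expect_equal(length(p$low), 4)
  expect_equal(p$high, names(sort(vals, decreasing = TRUE))[1:4])
  expect_length(intersect(p$high, p$low), 0)

  # ceiling: 25 genes at 10% -> 3 per side
  vals25 <- setNames(seq_len(25) / 25, sprintf("g%02d", 1:25))
  expect_equal(length(partition_by_cai(vals25)$high), 3)

  # ties at the cutoff resolved by ascending gene id
  tied <- setNames(c(1, 1, rep(0.5, 20), 0.1, 0.1),
                   c("zz", "aa", sprintf("m%02d", 1:20), "yy", "ab"))
  p <- partition_by_cai(tied, fraction = 0.05)
  expect_equal(p$high, c("aa", "zz"))
  expect_equal(p$low, c("ab", "yy"))

  expect_error(partition_by_cai(vals, fraction = 0.6), "fraction")
  expect_error(partition_by_cai(vals[1:10]), "at least 20")
})

test_that("delta RSCU is the high-minus-low RSCU difference with NA propagation", {
  hi <- as_codon_count(c(AAA = 30, AAG = 10))
  lo <- as_codon_count(c(AAA = 10, AAG = 30))
  d <- delta_rscu(hi, lo)
  expect_equal(d$delta_rscu[d$codon == "AAA"], 1.0)
  expect_equal(d$delta_rscu[d$codon == "AAG"], -1.0)
  # identical usage: zero everywhere it is defined
  d0 <- delta_rscu(hi, hi)
  expect_true(all(d0$delta_rscu[!is.na(d0$delta_rscu)] == 0))
  # family absent from the low set: NA delta
  hi2 <- as_codon_count(c(AAA = 5, GGA = 5))
  d2 <- delta_rscu(hi2, hi)
  expect_true(is.na(d2$delta_rscu[d2$codon == "GGA"]))
})

test_that("optimal calls apply both inclusive thresholds and never pick ATG/TGG", {
  d <- data.frame(codon = c("AAA", "AAG", "GGA", "GGC"),
                  amino_acid = c("K", "K", "G", "G"),
                  rscu_high = c(1.3, 0.9, 1.1, 1.0),
                  rscu_low = c(1.2, 1.1, 1.02, 1.0),
                  delta_rscu = c(0.10, 0.20, 0.08, 0.079))
  calls <- call_optimal(d)
  expect_equal(calls$is_optimal, c(TRUE, FALSE, TRUE, FALSE))
  # threshold variants
  expect_true(call_optimal(d, delta_min = 0.05)$is_optimal[4])
  expect_false(call_optimal(d, rscu_min = 1.2)$is_optimal[3])
})

test_that("universal optimal codons are the cross-species intersection", {
  sets <- list(s1 = c("AGA"), s2 = c("AGA", "CCA"))
  expect_equal(universal_optimal(sets), "AGA")
  expect_equal(universal_optimal(sets, min_species = 1), c("AGA", "CCA"))
  expect_length(universal_optimal(list(a = "AAA", b = "GGG")), 0)
  expect_error(universal_optimal(list(a = "AAA")), "2 species")
  expect_error(universal_optimal(sets, min_species = 5), "min_species")
})

test_that("the per-species procedure is deterministic on identical input", {
  g <- gen_biased_corpus(n_genes = 60, seed = 17)
  kept <- filter_cds(g$records)$kept
  o1 <- find_optimal_codons(kept)
  o2 <- find_optimal_codons(kept)
  expect_identical(o1$calls, o2$calls)
  f1 <- tempfile(); f2 <- tempfile()
  write.table(o1$calls, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(o2$calls, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("optimal codons always have high-set RSCU of at least 1", {
  for (s in 1:5) {
    g <- gen_biased_corpus(n_genes = 80, bias_strength = 0.8, seed = 300 + s)
    oc <- find_optimal_codons(filter_cds(g$records)$kept)
    if (length(oc$optimal)) {
      expect_true(all(oc$calls$rscu_high[oc$calls$is_optimal] >= 1))
      expect_true(all(oc$calls$delta_rscu[oc$calls$is_optimal] >= 0.08))
    }
  }
})
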