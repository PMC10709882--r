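test_that("codon counting is in-frame, drops the terminal stop, and adds", {
  tb <- count_codons("ATGAAAAAATAA")
  expect_equal(unname(tb["ATG"]), 1L)
  expect_equal(unname(tb["AAA"]), 2L)
  expect_equal(attr(tb, "n_codons"), 3L)
  expect_equal(attr(count_codons("ATGTAA"), "n_codons"), 1L)
  # additivity
  tb2 <- count_codons("ATGCCCTAA")
  agg <- pool_codon_counts(list(tb, tb2))
  expect_equal(as.integer(agg), as.integer(tb) + as.integer(tb2))
  expect_error(count_codons("ATGAA"), "multiple of 3")
})

test_that("RSCU follows the family-degeneracy formula", {
  counts <- as_codon_count(c(AAA = 3, AAG = 1))
  r <- rscu(counts)
  expect_equal(unname(r["AAA"]), 1.5)
  expect_equal(unname(r["AAG"]), 0.5)
  # uniform usage in a family gives RSCU 1 everywhere
  g4 <- as_codon_count(c(GGA = 2, GGC = 2, GGG = 2, GGT = 2))
  expect_equal(unname(rscu(g4)[c("GGA", "GGC", "GGG", "GGT")]), rep(1, 4))
  # unobserved families are NA
  expect_true(all(is.na(r[c("GGA", "GGC", "GGG", "GGT")])))
  # normalisation: family sums equal degeneracy; scale invariance
  set.seed(3)
  for (s in 1:10) {
    counts <- random_count_table(seed = s)
    r1 <- rscu(as_codon_count(counts))
    leu <- c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG")
    if (sum(counts[leu]) > 0) {
      expect_equal(sum(r1[leu]), 6, tolerance = 1e-9)
    }
    r2 <- rscu(as_codon_count(counts * 2L))
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("positional composition separates overall and synonymous sets", {
  g <- as_codon_count(c(GGG = 2))
  comp <- positional_composition(g)
  expect_equal(unname(comp["gc"]), 1)
  expect_equal(unname(comp["gc3s"]), 1)
  lys <- as_codon_count(c(AAA = 3, AAG = 1))
  comp <- positional_composition(lys)
  expect_equal(unname(comp[c("a3s", "g3s", "gc3s", "c3s", "u3s")]),
               c(0.75, 0.25, 0.25, 0, 0))
  expect_equal(unname(comp[c("gc1", "gc2")]), c(0, 0))
  # only ATG/TGG: no synonymously variable codons
  mono <- as_codon_count(c(ATG = 2, TGG = 1))
  comp <- positional_composition(mono)
  expect_true(all(is.na(comp[c("a3s", "u3s", "c3s", "g3s", "gc3s")])))
  expect_error(positional_composition(as_codon_count(c())), "empty")
})

test_that("ENC spans its theoretical range", {
  # one codon per amino acid, every degenerate family observed twice: Nc = 20
  one_each <- vapply(orc_fams[lengths(orc_fams) >= 2], `[[`, character(1), 1)
  counts <- setNames(rep(2L, length(one_each)), one_each)
  expect_equal(enc(as_codon_count(counts)), 20)
  # long uniform-usage gene approaches the 61 cap
  set.seed(1)
  unif <- table(sample(orc_sense, 50000, replace = TRUE))
  val <- enc(as_codon_count(setNames(as.integer(unif), names(unif))))
  expect_gt(val, 59)
  expect_lte(val, 61)
})

test_that("ENC decreases with planted bias strength", {
  pref <- vapply(orc_fams[lengths(orc_fams) >= 2], `[[`, character(1), 1)
  encs <- vapply(c(0, 0.5, 0.9), function(b) {
    g <- gen_biased_corpus(n_genes = 120, preferred_codons = unname(pref),
                           bias_strength = b, high_fraction = 1, seed = 7)
    mean(vapply(g$records$seq, function(s) enc(count_codons(s)), numeric(1)),
         na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(encs) < 0))
})

test_that("CAI is the geometric mean of relative-adaptiveness weights", {
  ref <- as_codon_count(c(AAA = 3, AAG = 1))
  w <- build_w_table(ref)
  expect_equal(unname(w$w["AAA"]), 1)
  expect_equal(unname(w$w["AAG"]), 1 / 3)
  # floor for unobserved codons of observed families
  w2 <- build_w_table(as_codon_count(c(AAA = 5)))
  expect_equal(unname(w2$w["AAG"]), 0.01)
  # neutral for wholly unobserved families
  expect_equal(unname(w2$w["GGG"]), 1)
  # gene of two codons with weights 1 and 0.25 has CAI 0.5
  w3 <- structure(list(w = setNames(rep(1, length(orc_sense)), orc_sense),
                       source_label = "manual"), class = "w_table")
  w3$w["AAG"] <- 0.25
  expect_equal(cai(as_codon_count(c(AAA = 1, AAG = 1)), w3), 0.5)
  # maximal-w gene: CAI 1; ATG/TGG-only gene: NA
  expect_equal(cai(as_codon_count(c(AAA = 10)), w), 1)
  expect_true(is.na(cai(as_codon_count(c(ATG = 1, TGG = 2)), w)))
  # the consensus-optimal gene of a reference scores exactly 1
  pooled <- as_codon_count(random_count_table(99) + 1L)
  wt <- build_w_table(pooled)
  best <- vapply(orc_fams[lengths(orc_fams) >= 2], function(fam) {
    fam[which.max(wt$w[fam])]
  }, character(1))
  expect_equal(cai(as_codon_count(setNames(rep(3L, length(best)), unname(best))), wt), 1)
})

test_that("CBI measures optimal-codon excess over random expectation", {
  opt <- c("AAA", "GGA")
  expect_equal(cbi(as_codon_count(c(AAA = 4, GGA = 2)), opt), 1)
  # one 2-fold family, counts (3 optimal, 1 other): (3-2)/(4-2)
  expect_equal(cbi(as_codon_count(c(AAA = 3, AAG = 1)), "AAA"), 0.5)
  # usage at exactly the random expectation: CBI 0
  expect_equal(cbi(as_codon_count(c(AAA = 2, AAG = 2)), "AAA"), 0)
  # undefined when only fully-optimal families with all mass optimal... skip:
  expect_true(is.na(cbi(as_codon_count(c(CCC = 2)), "AAA")))
})

test_that("PR2 coordinates sit at (0.5, 0.5) for parity and shift with skew", {
  bal <- as_codon_count(c(GCA = 1, GCT = 1, GCG = 1, GCC = 1))
  expect_equal(unname(pr2_point(bal)), c(0.5, 0.5))
  skew <- as_codon_count(c(GCA = 2, GCT = 6, GCG = 6, GCC = 2))
  expect_equal(unname(pr2_point(skew)), c(0.75, 0.25))
  # no fourfold-family codons at all
  expect_true(all(is.na(pr2_point(as_codon_count(c(AAA = 5))))))
})

test_that("mean PR2 of uniform-usage corpora approaches the parity centre", {
  g <- gen_biased_corpus(n_genes = 150, bias_strength = 0, seed = 21)
  pts <- t(vapply(g$records$seq, function(s) pr2_point(count_codons(s)),
                  numeric(2)))
  for (k in 1:2) {
    se <- stats::sd(pts[, k]) / sqrt(nrow(pts))
    expect_lt(abs(mean(pts[, k]) - 0.5), 3 * se)
  }
})

test_that("per-gene profile table has the documented schema", {
  g <- gen_biased_corpus(n_genes = 25, seed = 5)
  prof <- codon_usage(g$records)
  expect_equal(names(prof),
               c("gene_id", "species", "n_codons", "gc", "gc1", "gc2", "gc3",
                 "gc3s", "a3s", "u3s", "c3s", "g3s", "enc", "cai", "cbi",
                 "pr2_x", "pr2_y"))
  expect_equal(nrow(prof), 25)
  expect_true(all(prof$enc >= 20 & prof$enc <= 61, na.rm = TRUE))
  m <- rscu_matrix(g$records)
  expect_equal(dim(m), c(61L, 1L))
})
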