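test_that("NG86 site counts follow per-position enumeration", {
  expect_equal(unname(count_sites_ng86("AAA")), c(1 / 3, 8 / 3))
  expect_equal(unname(count_sites_ng86("TGG")[1]), 0)
  # complementarity over every sense codon
  for (cod in orc_sense) {
    s <- count_sites_ng86(cod)
    expect_equal(unname(sum(s)), 3, tolerance = 1e-12)
  }
  expect_error(count_sites_ng86("TAA"), "stop")
})

test_that("NG86 difference counts average over minimal pathways", {
  expect_equal(unname(count_differences_ng86("AAA", "AAA")), c(0, 0))
  expect_equal(unname(count_differences_ng86("AAA", "AAG")), c(1, 0))
  expect_equal(unname(count_differences_ng86("TTT", "GTA")),
               orc_diffs("TTT", "GTA"))
  # sd + nd equals the Hamming distance on a codon-pair sample
  set.seed(8)
  for (k in 1:60) {
    a <- sample(orc_sense, 1); b <- sample(orc_sense, 1)
    d <- count_differences_ng86(a, b)
    hamming <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(sum(d)), hamming, tolerance = 1e-12)
  }
})

test_that("NG86 handles identity, saturation and site bookkeeping", {
  seqs <- evolve_pair(len_codons = 100, t = 0, seed = 2)
  r0 <- ng86(seqs$seq_a, seqs$seq_b)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))                 # Ks = 0
  expect_equal(r0$S + r0$N, 3 * r0$n_codons, tolerance = 1e-6)
  # symmetry
  p <- evolve_pair(len_codons = 80, omega = 0.5, t = 0.3, seed = 4)
  ra <- ng86(p$seq_a, p$seq_b); rb <- ng86(p$seq_b, p$seq_a)
  expect_identical(ra$Ka, rb$Ka)
  expect_identical(ra$Ks, rb$Ks)
  # saturated synonymous proportion -> NA via the JC domain bound
  sat <- ng86(strrep("TTA", 40), strrep("CTG", 40))
  expect_true(is.na(sat$Ks))
  expect_true(is.na(sat$ratio))
})

test_that("YN00 estimates kappa and matches its zero-divergence limit", {
  seqs <- evolve_pair(len_codons = 100, t = 0, seed = 12)
  r <- yn00(seqs$seq_a, seqs$seq_b)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(r$converged)
  # symmetry
  p <- evolve_pair(len_codons = 150, omega = 1, kappa = 3, t = 0.25, seed = 13)
  ra <- yn00(p$seq_a, p$seq_b); rb <- yn00(p$seq_b, p$seq_a)
  expect_equal(ra$Ka, rb$Ka, tolerance = 1e-9)
  expect_equal(ra$Ks, rb$Ks, tolerance = 1e-9)
  # kappa responds to the simulated transition bias
  hi <- mean(vapply(1:5, function(s) {
    e <- evolve_pair(400, omega = 1, kappa = 8, t = 0.3, seed = s)
    yn00(e$seq_a, e$seq_b)$kappa
  }, numeric(1)))
  lo <- mean(vapply(1:5, function(s) {
    e <- evolve_pair(400, omega = 1, kappa = 1, t = 0.3, seed = s + 50)
    yn00(e$seq_a, e$seq_b)$kappa
  }, numeric(1)))
  expect_gt(hi, lo + 1)
})

test_that("selection classes follow the stated Ka/Ks thresholds", {
  ratios <- c(0.3, 0.5, 0.7, 1.0, 1.2, NA)
  ks <- rep(0.5, 6)
  expect_equal(classify_selection(ratios, ks),
               c("PURIFYING", "PURIFYING", "WEAK_POSITIVE", "WEAK_POSITIVE",
                 "STRONG_POSITIVE", "UNDEFINED"))
  # Ks admission window
  expect_equal(classify_selection(0.3, ks = 1e-9), "UNDEFINED")
  expect_equal(classify_selection(0.3, ks = 5), "UNDEFINED")
  expect_equal(classify_selection(0.3, ks = 5, ks_max = 10), "PURIFYING")
})

test_that("kaks_pairs produces the per-pair table with classes", {
  tw <- gen_two_species(n_orthologs = 4, n_decoys = 0, len_codons = 120,
                        omega = 0.2, t = 0.2, seed = 77)
  pr <- rbh_pairs(filter_cds(tw$species_a)$kept, filter_cds(tw$species_b)$kept)
  for (m in c("NG86", "YN00")) {
    kk <- kaks_pairs(pr, method = m)
    expect_equal(nrow(kk), 4)
    expect_equal(unique(kk$method), m)
    expect_true(all(c("species_pair", "gene_a", "gene_b", "S", "N", "Sd",
                      "Nd", "Ka", "Ks", "ratio", "kappa", "class") %in% names(kk)))
  }
})

test_that("positive-selection commonality builds Venn cells over pairings", {
  mk <- function(genes, ratios) {
    data.frame(gene_a = genes, ratio = ratios, stringsAsFactors = FALSE)
  }
  res <- list(p1 = mk(c("g1", "g2"), c(1.5, 2.0)),
              p2 = mk(c("g2", "g3"), c(3.0, 0.4)))
  cm <- positive_commonality(res)
  expect_equal(cm$membership$pairings[cm$membership$gene_a == "g2"], "p1&p2")
  expect_equal(cm$membership$pairings[cm$membership$gene_a == "g1"], "p1")
  expect_false("g3" %in% cm$membership$gene_a)
  expect_equal(unname(cm$cells[["p1&p2"]]), 1L)
  expect_equal(unname(cm$cells[["p1"]]), 1L)
  # gene above 1 in all pairings lands in the all-pairings cell
  res5 <- setNames(lapply(1:5, function(i) mk("g9", 1.2)), paste0("q", 1:5))
  cm5 <- positive_commonality(res5)
  expect_equal(cm5$membership$n_pairings, 5L)
  # empty input
  cm0 <- positive_commonality(list(p1 = mk(character(0), numeric(0))))
  expect_equal(nrow(cm0$membership), 0)
})
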