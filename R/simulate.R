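# Seeded synthetic-data generators: biased codon-usage corpora with known
# expression classes and planted preferred codons, and ortholog pairs
# diverged under a codon model with controllable omega and kappa.

#' Generate a codon-usage-biased CDS corpus
#'
#' Each gene receives a latent expression class (high with probability
#' `high_fraction`). Amino acids are drawn uniformly over the 18
#' degenerate families; in high-expression genes the synonymous codon is
#' drawn with probability mass `bias_strength` concentrated on the
#' planted preferred codon(s) of its family (split equally when a family
#' has several) plus a uniform remainder, while low-expression genes use
#' synonymous codons uniformly. An ATG start and a random stop codon are
#' appended, so every generated gene passes [filter_cds()] when
#' `len_codons_range[1] >= 101`.
#'
#' @param n_genes number of genes.
#' @param len_codons_range integer range (min, max) of body length in
#'   codons (start/stop excluded).
#' @param preferred_codons character vector of planted preferred codons.
#' @param bias_strength b in `[0, 1]`: probability mass shifted toward the
#'   preferred codon(s) in high-expression genes.
#' @param high_fraction probability that a gene is high-expression.
#' @param species species label.
#' @param seed integer seed; the output is fully deterministic given it.
#' @return A list: `records` (a `cds_set`), `truth` (data.frame gene_id,
#'   expression_class) and `planted` (the preferred codons).
#' @export
gen_biased_corpus <- function(n_genes = 200L, len_codons_range = c(101L, 300L),
                              preferred_codons = c("AGA", "AGG", "CCA"),
                              bias_strength = 0.9, high_fraction = 0.5,
                              species = "sim", seed = 1L) {
  stopifnot(bias_strength >= 0, bias_strength <= 1,
            len_codons_range[1] >= 1, len_codons_range[2] >= len_codons_range[1],
            all(preferred_codons %in% .SYN_VARIABLE))
  set.seed(seed)
  fams <- names(.DEG_FAMILIES)
  pref_by_fam <- split(preferred_codons, .AA[preferred_codons])

  lens <- sample(seq(len_codons_range[1], len_codons_range[2]), n_genes,
                 replace = TRUE)
  is_high <- stats::runif(n_genes) < high_fraction
  gene_of_pos <- rep.int(seq_len(n_genes), lens)
  aa_all <- sample(fams, sum(lens), replace = TRUE)
  high_pos <- is_high[gene_of_pos]

  codon_all <- character(length(aa_all))
  for (fam in fams) {
    codons <- .DEG_FAMILIES[[fam]]
    k <- length(codons)
    # low-expression (and unbiased families): uniform synonymous usage
    sel_low <- aa_all == fam & (!high_pos | !(fam %in% names(pref_by_fam)))
    if (any(sel_low)) {
      codon_all[sel_low] <- sample(codons, sum(sel_low), replace = TRUE)
    }
    sel_high <- aa_all == fam & high_pos & fam %in% names(pref_by_fam)
    if (any(sel_high)) {
      pref <- pref_by_fam[[fam]]
      p <- rep((1 - bias_strength) / k, k)
      names(p) <- codons
      p[pref] <- p[pref] + bias_strength / length(pref)
      codon_all[sel_high] <- sample(codons, sum(sel_high), replace = TRUE,
                                    prob = p)
    }
  }
  bodies <- vapply(split(codon_all, gene_of_pos), paste, character(1),
                   collapse = "")
  stops <- sample(.STOP_CODONS, n_genes, replace = TRUE)
  ids <- sprintf("g%04d", seq_len(n_genes))
  records <- cds_set(ids, paste0("ATG", bodies, stops), species = species)
  list(records = records,
       truth = data.frame(gene_id = ids,
                          expression_class = ifelse(is_high, "high", "low"),
                          stringsAsFactors = FALSE),
       planted = preferred_codons)
}

# ---- codon substitution simulator ----------------------------------------

# per-codon mutation structure at given omega/kappa: target index and
# per-mutation weight (kappa for transitions, omega for nonsynonymous,
# stops forbidden)
.codon_model <- function(omega, kappa) {
  mut <- .mutation_table()
  targets <- lapply(mut, function(m) {
    m <- m[!m$stop, , drop = FALSE]
    list(to = match(m$target, .SENSE_CODONS),
         w = ifelse(m$ts, kappa, 1) * ifelse(m$syn, 1, omega),
         ts = m$ts, syn = m$syn)
  })
  totw <- vapply(targets, function(t) sum(t$w), numeric(1))
  norm <- mean(totw)           # expected rate 1 per codon for a uniform state
  list(targets = targets, rate = totw / norm, norm = norm)
}

# exact event-based (Gillespie) evolution of a codon-index vector for
# time t; returns the final state plus substitution event counts
.evolve_codons <- function(state, model, t) {
  rates <- model$rate[state]
  total <- sum(rates)
  now <- 0
  events <- c(n_sub = 0, n_ts = 0, n_tv = 0, n_syn = 0, n_nonsyn = 0)
  repeat {
    now <- now + stats::rexp(1, total)
    if (now > t) break
    pos <- sample.int(length(state), 1L, prob = rates)
    tg <- model$targets[[state[pos]]]
    k <- if (length(tg$w) == 1L) 1L else
      sample.int(length(tg$w), 1L, prob = tg$w)
    events["n_sub"] <- events["n_sub"] + 1
    events["n_ts"] <- events["n_ts"] + tg$ts[k]
    events["n_tv"] <- events["n_tv"] + !tg$ts[k]
    events["n_syn"] <- events["n_syn"] + tg$syn[k]
    events["n_nonsyn"] <- events["n_nonsyn"] + !tg$syn[k]
    state[pos] <- tg$to[k]
    rates[pos] <- model$rate[state[pos]]
    total <- sum(rates)
  }
  list(state = state, events = events)
}

#' Evolve a diverged codon-sequence pair
#'
#' An ancestor of `len_codons` sense codons is drawn uniformly; each of
#' the two lineages then evolves for time `t` (expected substitutions per
#' codon) under an exact event-based codon model with rate proportional
#' to kappa for transitions and 1 for transversions, multiplied by omega
#' for nonsynonymous changes; mutations to stop codons are forbidden.
#'
#' @param len_codons alignment length in codons.
#' @param omega true nonsynonymous/synonymous rate ratio.
#' @param kappa transition/transversion rate ratio.
#' @param t expected substitutions per codon, per lineage.
#' @param seed integer seed.
#' @return A list: `seq_a`, `seq_b` (gap-free in-frame coding strings,
#'   without start/stop), `omega`, `kappa`, `t` and `events` (summed
#'   substitution counts of both lineages).
#' @export
evolve_pair <- function(len_codons = 500L, omega = 1, kappa = 2, t = 0.2,
                        seed = 1L) {
  stopifnot(omega > 0, kappa > 0, t >= 0, len_codons >= 1)
  set.seed(seed)
  model <- .codon_model(omega, kappa)
  anc <- sample.int(length(.SENSE_CODONS), len_codons, replace = TRUE)
  la <- .evolve_codons(anc, model, t)
  lb <- .evolve_codons(anc, model, t)
  list(seq_a = paste(.SENSE_CODONS[la$state], collapse = ""),
       seq_b = paste(.SENSE_CODONS[lb$state], collapse = ""),
       omega = omega, kappa = kappa, t = t,
       events = la$events + lb$events)
}

#' Generate a two-species corpus with planted orthologs and decoys
#'
#' `n_orthologs` ancestral genes are diverged into both species under the
#' codon model of [evolve_pair()]; `n_decoys` unrelated random genes are
#' added per species. Every gene is emitted as an admissible CDS (ATG +
#' body + stop).
#'
#' @param n_orthologs number of true ortholog pairs.
#' @param n_decoys number of unrelated genes per species.
#' @param len_codons body length in codons of every gene.
#' @param omega true omega, a scalar or vector recycled over ortholog
#'   pairs.
#' @param kappa transition/transversion rate ratio.
#' @param t expected substitutions per codon per lineage.
#' @param species two species labels.
#' @param seed integer seed.
#' @return A list: `species_a`, `species_b` (each a `cds_set`) and
#'   `truth` (data.frame gene_a, gene_b, omega).
#' @export
gen_two_species <- function(n_orthologs = 50L, n_decoys = 10L,
                            len_codons = 500L, omega = 0.2, kappa = 2,
                            t = 0.2, species = c("A", "B"), seed = 1L) {
  set.seed(seed)
  omega <- rep_len(omega, n_orthologs)
  models <- lapply(unique(omega), .codon_model, kappa = kappa)
  names(models) <- as.character(unique(omega))

  finish <- function(body) paste0("ATG", body, sample(.STOP_CODONS, 1L))
  seq_a <- character(0); seq_b <- character(0)
  for (i in seq_len(n_orthologs)) {
    anc <- sample.int(length(.SENSE_CODONS), len_codons, replace = TRUE)
    model <- models[[as.character(omega[i])]]
    la <- .evolve_codons(anc, model, t)
    lb <- .evolve_codons(anc, model, t)
    seq_a[i] <- finish(paste(.SENSE_CODONS[la$state], collapse = ""))
    seq_b[i] <- finish(paste(.SENSE_CODONS[lb$state], collapse = ""))
  }
  dec <- function() {
    finish(paste(.SENSE_CODONS[sample.int(length(.SENSE_CODONS), len_codons,
                                          replace = TRUE)], collapse = ""))
  }
  dec_a <- vapply(seq_len(n_decoys), function(i) dec(), character(1))
  dec_b <- vapply(seq_len(n_decoys), function(i) dec(), character(1))

  ids_a <- c(sprintf("%s_orth%03d", species[1], seq_len(n_orthologs)),
             sprintf("%s_dec%03d", species[1], seq_len(n_decoys)))
  ids_b <- c(sprintf("%s_orth%03d", species[2], seq_len(n_orthologs)),
             sprintf("%s_dec%03d", species[2], seq_len(n_decoys)))
  list(species_a = cds_set(ids_a, c(seq_a, dec_a), species = species[1]),
       species_b = cds_set(ids_b, c(seq_b, dec_b), species = species[2]),
       truth = data.frame(gene_a = ids_a[seq_len(n_orthologs)],
                          gene_b = ids_b[seq_len(n_orthologs)],
                          omega = omega, stringsAsFactors = FALSE))
}
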