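---
title: "Codon usage bias and selection pressure: methods and design notes"
author: "codonselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and selection pressure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonselect)
```

# Scope

`codonselect` implements a desk-scale comparative analysis of codon usage
bias and selection pressure for per-species collections of coding
sequences (CDS), of the kind produced by transcriptome assembly of
non-model plants. The pipeline is: CDS admission, per-gene and pooled
codon-usage statistics (RSCU, ENC, CAI, CBI, positional GC, PR2),
optimal-codon determination from extreme-CAI gene partitions with a
cross-species universal intersection, reciprocal-best-hit (RBH) one-to-one
orthology with protein-guided codon alignments, and Ka/Ks estimation
(NG86 and YN00) with selection-class assignment and cross-pairing
commonality of positively selected genes. A seeded synthetic-data module
generates corpora with known structure so that every stage can be
validated without any sequencing data.

# CDS admission

A sequence is admitted when it exceeds 300 bp (strict inequality), starts
with ATG, ends with TAA/TAG/TGA, has length divisible by 3, contains no
in-frame internal stop, and no ambiguous base. The first two and the stop
rule are the admission conditions commonly applied to assembled
full-length CDS; divisibility, internal stops and ambiguity codes are
additional requirements of unambiguous codon counting — without them
in-frame counts are undefined — so rejected records carry the first
failing rule as a machine-readable reason code. Admission is idempotent
and every admitted sequence translates under the standard genetic code.

# Codon-usage statistics

All statistics are computed from in-frame codon counts with the terminal
stop excluded. Leu, Ser and Arg are treated as 6-fold families for RSCU
and ENC; ATG and TGG carry no synonymous choice and are excluded from
RSCU-based screening, CAI, CBI and the third-position "3s" denominators.

* **RSCU**: count divided by the uniform-usage expectation within the
  family; family sums equal the degeneracy; unobserved families are NA.
* **ENC** (Wright's Nc): per-family homozygosity
  $\hat F = (n\sum p_i^2 - 1)/(n-1)$ for families with $n \ge 2$,
  averaged within degeneracy classes, then
  $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$, capped
  at 61. The 3-fold class (Ile alone) is frequently unobserved in short
  genes; its reciprocal term is imputed as the mean of the 2- and 4-fold
  terms. If any other class is missing the statistic is NA — a
  deliberate refusal to extrapolate, since those classes carry 9, 5 and 3
  families' worth of weight.
* **CAI**: geometric mean of relative-adaptiveness weights
  $w_{ij} = \mathrm{RSCU}_{ij} / \max_k \mathrm{RSCU}_{ik}$ built from a
  highly-expressed reference. Unobserved codons of observed families get
  a floor of 0.01 (avoids $\log 0$; the conventional choice), wholly
  unobserved families are neutral ($w = 1$).
* **CBI**: $(N_{opt} - N_{ran}) / (N_{tot} - N_{ran})$ over families that
  contain at least one optimal codon.
* **PR2**: $x = G_3/(G_3{+}C_3)$, $y = A_3/(A_3{+}T_3)$ restricted to the
  eight fourfold-degenerate codon boxes (Ala, Gly, Pro, Thr, Val and the
  fourfold halves of Leu CTN, Ser TCN, Arg CGN); the split treatment of
  the 6-fold families follows standard parity-rule practice, which
  requires sites where all four bases are synonymous.

# The CAI reference and optimal codons

CAI needs a highly expressed reference set, which is unknown for a de
novo corpus. `cai_two_pass()` bootstraps it deterministically: pass 1
builds $w$ from the whole corpus and ranks genes; $w$ is rebuilt from the
provisional top 10%; pass 2 re-ranks all genes against that reference.
The final ranking feeds `partition_by_cai()`: top and bottom
$\lceil 0.10\,N \rceil$ genes (ties broken by gene id, for determinism on
small corpora) form the high/low expression sets. Optimal codons are
those with pooled RSCU $\ge 1.0$ in the high set and
$\Delta\mathrm{RSCU} = \mathrm{RSCU}_{high} - \mathrm{RSCU}_{low} \ge
0.08$, both inclusive; the universal set is by default the strict
intersection across species, with `min_species` exposed for the looser
"optimal in most species" reading.

**A known limitation of the bootstrap.** Because the reference is the
corpus's own provisional top decile, the high/low partition necessarily
correlates with whichever codon happens to be most common in each family
of that corpus — even when the corpus carries no expression-linked bias
at all. In a null corpus (uniform synonymous usage) this feedback pushes
each family's randomly modal codon toward both thresholds, so individual
species produce noise calls at rates comparable to genuine small biases,
and the strict cross-species intersection of six independent null corpora
is empty only about 85–90% of the time rather than always. The
alternative — a fixed external reference — would be worse for
specificity, since it would prefer the *same* codons in every species and
make spurious intersections near-certain. Users should therefore treat
the universal intersection as the bias-robust output and per-species
call lists as threshold-sensitive.

# Orthology

One-to-one orthologs are found by reciprocal best hit over global
(Needleman–Wunsch, affine-gap) protein alignments, BLOSUM62 with gap
open 10 and extension 0.5 — conventional protein-alignment defaults.
Pairs must be mutually best by score (ties by identity, then gene id),
pass identity $\ge 0.3$ and coverage $\ge 0.5$ on both proteins, and
retain $\ge 30$ gap-free codon columns after protein-guided threading
(gap and ambiguous columns removed). The 30-codon floor controls the
variance of downstream Ka/Ks on short alignments. RBH is a deliberate
desk-scale stand-in for graph-based orthogroup inference: only the
one-to-one pairs are consumed downstream, and RBH is the standard
equivalent for that output.

# Ka/Ks

**NG86.** Synonymous site counts per codon enumerate the nine
single-nucleotide mutations, excluding mutations to stop codons from the
per-position denominator; differences average synonymous/nonsynonymous
step counts over all minimal mutational pathways, excluding pathways
through stop codons (if no stop-free pathway exists, all pathways are
used). Sites are averaged over the two sequences, proportions are
Jukes–Cantor corrected, and $p \ge 0.75$ (outside the correction's
domain) yields NA. For every pair $S + N = 3 \cdot n_{codons}$.

**YN00.** The transition/transversion ratio $\kappa$ is estimated first,
from K80 distances at positions that are fourfold-degenerate in both
codons and at nondegenerate positions (weighted by site counts). Codon
frequencies are F3x4 (an equal-frequency mode exists for cross-checks).
Site counts weight each mutation by $\kappa$ (transitions) and the
target-codon frequency; pathway steps are additionally weighted by
$\omega$ for nonsynonymous changes. Differences are split into
transitional and transversional parts, synonymous and nonsynonymous
distances are K80-corrected, and $\omega = d_N/d_S$ is iterated to
convergence ($|\Delta\omega| < 10^{-6}$, at most 100 iterations;
non-convergence is flagged).

**Classification.** Ka/Ks below 0.5 is purifying, between 0.5 and 1 weak
positive, above 1 strong positive; the boundary values 0.5 and 1 — not
covered by the strict inequalities of the defining rule — map
conservatively to the lower class. Pairs with Ks $\le 10^{-6}$ (ratio
unstable) or Ks $> 3$ (saturation) are excluded from classification;
both bounds are exposed as configuration, since the corresponding
filtering step of desk analyses is rarely reported precisely.

# Synthetic data

`gen_biased_corpus()` draws amino acids uniformly over the 18 degenerate
families and chooses synonymous codons uniformly in low-expression genes;
in high-expression genes a probability mass $b$ is concentrated on the
planted preferred codon(s) of a family. Expression is a latent binary
class — the analysis only needs a CAI-correlated usage gradient, not
FPKM values. `evolve_pair()` evolves both lineages from a uniform
ancestor by an exact event-based (Gillespie) codon substitution model
with rates $\propto \kappa$ for transitions and $\omega$ for
nonsynonymous changes, stops forbidden; rates are normalised so that one
time unit is one expected substitution per codon at the ancestral
composition. Event-based simulation is exact at any divergence and needs
no matrix exponentials. `gen_two_species()` combines the two with decoy
genes to exercise orthology end to end.

What the generator does *not* emulate: realistic gene-length and GC
distributions, expression-correlated gene length, indels (alignments are
generated gap-free; gap handling is exercised on constructed cases), and
genome-scale corpus sizes. Passing recovery tests therefore demonstrate
correctness of the estimators and thresholds under the stated model, not
performance on real transcriptomes.

# Study sizes used in validation

The validation studies run at sizes where each statistic operates in its
intended regime while remaining quick on one CPU: optimal-codon recovery
uses six pseudo-species of 1,000 genes (extreme-decile pools of 100
genes, whose RSCU sampling noise of roughly 0.04–0.06 lies below the
0.08 screening threshold — with much smaller corpora the threshold would
sit below its own noise floor, which is not the regime the rule was
designed for); Ka/Ks recovery uses 50 replicate pairs of 500 codons per
$(\omega, \kappa)$ setting at divergence $t = 0.2$ per lineage; the
end-to-end study uses 50 ortholog pairs (half $\omega = 0.2$, half
$\omega = 1.5$) plus 10 decoys per species.

# Numerical and degenerate-input conventions

* Fractions are kept at full precision internally; percentages are
  rounded half-up to two decimals only at the reporting surface.
* RSCU/ENC/CAI return NA (never 0 or an extrapolation) when their
  defining denominators are empty; NA propagates through
  $\Delta$RSCU and disqualifies a codon from optimal calls.
* All rankings and set outputs use explicit deterministic tie-breaks
  (gene id, codon alphabetical order), so identical inputs give
  byte-identical reports; `run_pipeline()` writes a log of every
  threshold so any report is reproducible from the log alone.
* The pipeline driver is a plain R function; a thin command-line wrapper
  (`exec/codonselect`) exposes the same entry point for shell use.
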