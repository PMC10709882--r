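Package: codonselect
Title: Codon Usage Bias and Selection Pressure Analysis for Coding Sequence Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of codon usage bias and selection pressure
    across per-species coding-sequence (CDS) collections. Implements CDS
    admission rules, codon-usage statistics (RSCU, ENC, CAI, CBI, positional
    GC composition, PR2 plot coordinates), optimal-codon determination from
    extreme-CAI gene partitions with cross-species universal codons,
    reciprocal-best-hit ortholog pairing with protein-guided codon alignments,
    Ka/Ks estimation by the Nei-Gojobori (1986) and Yang-Nielsen (2000)
    counting methods with selection-class assignment, and a seeded synthetic
    CDS/ortholog generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
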