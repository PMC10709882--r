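# Genetic-code tables shared by all modules. Standard code (translation
# table 1) only; built once at install time from Biostrings.

.BASES <- c("A", "C", "G", "T")

.GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  gc[order(names(gc))]
})

.CODONS <- names(.GENCODE)                       # 64 codons, alphabetical
.STOP_CODONS <- .CODONS[.GENCODE == "*"]         # TAA TAG TGA
.SENSE_CODONS <- .CODONS[.GENCODE != "*"]        # 61

# amino-acid family per sense codon (Leu/Ser/Arg are 6-fold families)
.AA <- .GENCODE[.SENSE_CODONS]
.FAMILIES <- split(.SENSE_CODONS, .AA)           # 21 families incl. M, W
.DEGENERACY <- lengths(.FAMILIES)[.AA]
names(.DEGENERACY) <- .SENSE_CODONS

# codons with a synonymous alternative (excludes ATG, TGG)
.SYN_VARIABLE <- .SENSE_CODONS[.DEGENERACY >= 2]
.DEG_FAMILIES <- .FAMILIES[lengths(.FAMILIES) >= 2]   # 18 degenerate families

# ENC degeneracy classes: family sizes -> number of families
.ENC_CLASS_SIZE <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)

# the eight fourfold-degenerate codon families used for PR2 plots:
# Ala GCN, Gly GGN, Pro CCN, Thr ACN, Val GTN plus the fourfold halves
# of Leu (CTN), Ser (TCN) and Arg (CGN)
.PR2_PREFIXES <- c("GC", "GG", "CC", "AC", "GT", "CT", "TC", "CG")
.PR2_CODONS <- as.vector(outer(.PR2_PREFIXES, .BASES, paste0))

.is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

# split a single in-frame sequence into codons
.codon_split <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

.check_codon <- function(codon) {
  if (!codon %in% .CODONS) {
    stop("not a DNA codon: ", codon, call. = FALSE)
  }
  if (codon %in% .STOP_CODONS) {
    stop("stop codon not allowed here: ", codon, call. = FALSE)
  }
  invisible(codon)
}

# mutable cache for lazily built lookup structures (NG86/YN00 tables)
.cache <- new.env(parent = emptyenv())
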