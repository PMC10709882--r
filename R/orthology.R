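# One-to-one ortholog identification by reciprocal best hit (RBH) over
# global protein alignments, and protein-guided codon alignment threading.

.blosum62 <- function() {
  if (is.null(.cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .cache$BLOSUM62 <- e$BLOSUM62
  }
  .cache$BLOSUM62
}

.aln_identity <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  sum(a == b & a != "-") / length(a)
}

#' Global protein alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (BLOSUM62 by default) via
#' Biostrings. Identity is the fraction of alignment columns (gaps
#' included) with identical residues.
#'
#' @param a,b protein sequences (single strings).
#' @param id_a,id_b identifiers carried into the result.
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @param substitution_matrix a scoring matrix, default BLOSUM62.
#' @return A list of class `protein_alignment`: id_a, id_b, aligned_a,
#'   aligned_b, score, identity.
#' @export
align_proteins <- function(a, b, id_a = "a", id_b = "b",
                           gap_open = 10, gap_extend = 0.5,
                           substitution_matrix = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence", call. = FALSE)
  if (is.null(substitution_matrix)) substitution_matrix <- .blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  structure(list(id_a = id_a, id_b = id_b,
                 aligned_a = aligned_a, aligned_b = aligned_b,
                 score = Biostrings::score(aln),
                 identity = .aln_identity(aligned_a, aligned_b)),
            class = "protein_alignment")
}

#' Thread a codon alignment through a protein alignment
#'
#' Each aligned amino-acid column is expanded to its source codon; columns
#' where either side is a gap or contains an ambiguous base are dropped, so
#' the result is an equal-length, gap-free, in-frame codon alignment.
#'
#' @param pa a `protein_alignment`.
#' @param cds_a,cds_b the source CDS sequences (single strings, admitted by
#'   [filter_cds()]); their translations must equal the ungapped aligned
#'   proteins.
#' @param species_a,species_b species labels.
#' @param min_codons minimum number of retained codon columns (default
#'   30); shorter alignments raise a TOO_SHORT_ALIGNMENT error.
#' @return A list of class `ortholog_pair`: species_a, species_b, gene_a,
#'   gene_b, codon_aln_a, codon_aln_b, n_codons.
#' @export
thread_codon_alignment <- function(pa, cds_a, cds_b,
                                   species_a = "A", species_b = "B",
                                   min_codons = 30L) {
  cod_a <- .codon_split(cds_a)
  cod_b <- .codon_split(cds_b)
  if (cod_a[length(cod_a)] %in% .STOP_CODONS) cod_a <- cod_a[-length(cod_a)]
  if (cod_b[length(cod_b)] %in% .STOP_CODONS) cod_b <- cod_b[-length(cod_b)]
  ga <- strsplit(pa$aligned_a, "")[[1]]
  gb <- strsplit(pa$aligned_b, "")[[1]]
  if (paste(.GENCODE[cod_a], collapse = "") != paste(ga[ga != "-"], collapse = "") ||
      paste(.GENCODE[cod_b], collapse = "") != paste(gb[gb != "-"], collapse = "")) {
    stop("TRANSLATION_MISMATCH: CDS translation does not match aligned protein",
         call. = FALSE)
  }
  ia <- cumsum(ga != "-")        # codon index on side a for each column
  ib <- cumsum(gb != "-")
  keep <- ga != "-" & gb != "-"
  ka <- cod_a[ia[keep]]
  kb <- cod_b[ib[keep]]
  clean <- !grepl("[^ACGT]", ka) & !grepl("[^ACGT]", kb)
  ka <- ka[clean]; kb <- kb[clean]
  if (length(ka) < min_codons) {
    stop("TOO_SHORT_ALIGNMENT: only ", length(ka),
         " gap-free codon columns (need ", min_codons, ")", call. = FALSE)
  }
  structure(list(species_a = species_a, species_b = species_b,
                 gene_a = pa$id_a, gene_b = pa$id_b,
                 codon_aln_a = paste(ka, collapse = ""),
                 codon_aln_b = paste(kb, collapse = ""),
                 n_codons = length(ka)),
            class = "ortholog_pair")
}

#' Reciprocal-best-hit ortholog pairs between two species
#'
#' Every gene is globally aligned (as protein) against all genes of the
#' other species; a pair is kept when the two genes are mutually best by
#' alignment score (ties broken by higher identity, then lexicographic
#' gene id) and passes the identity and coverage floors. Kept pairs get a
#' protein-guided gap-free codon alignment. Each gene appears in at most
#' one pair.
#'
#' @param cds_a,cds_b `cds_set` data.frames (admitted CDS) for the two
#'   species.
#' @param min_identity minimum alignment identity (default 0.3).
#' @param min_coverage minimum fraction of each protein covered by
#'   gap-free alignment columns (default 0.5).
#' @param min_codons minimum gap-free codon columns per pair (default 30).
#' @param gap_open,gap_extend affine gap penalties.
#' @return A list of class `ortholog_pairs`: `pairs` (data.frame
#'   species_a, gene_a, species_b, gene_b, score, identity, n_codons) and
#'   `alignments` (list of `ortholog_pair`).
#' @export
rbh_pairs <- function(cds_a, cds_b, min_identity = 0.3, min_coverage = 0.5,
                      min_codons = 30L, gap_open = 10, gap_extend = 0.5) {
  if (nrow(cds_a) == 0 || nrow(cds_b) == 0) {
    stop("empty species set", call. = FALSE)
  }
  prot_a <- vapply(cds_a$seq, translate_cds, character(1), USE.NAMES = FALSE)
  prot_b <- vapply(cds_b$seq, translate_cds, character(1), USE.NAMES = FALSE)
  aa_a <- Biostrings::AAStringSet(prot_a)
  names(aa_a) <- cds_a$gene_id
  mat <- .blosum62()

  # score matrix: rows = genes of a, columns = genes of b
  scores <- vapply(seq_along(prot_b), function(j) {
    Biostrings::pairwiseAlignment(
      aa_a, Biostrings::AAString(prot_b[j]), type = "global",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, scoreOnly = TRUE)
  }, numeric(nrow(cds_a)))
  scores <- matrix(scores, nrow = nrow(cds_a),
                   dimnames = list(cds_a$gene_id, cds_b$gene_id))

  aln_cache <- new.env(parent = emptyenv())
  get_aln <- function(i, j) {
    key <- paste0(i, "|", j)
    if (is.null(aln_cache[[key]])) {
      aln_cache[[key]] <- align_proteins(
        prot_a[i], prot_b[j], id_a = cds_a$gene_id[i], id_b = cds_b$gene_id[j],
        gap_open = gap_open, gap_extend = gap_extend,
        substitution_matrix = mat)
    }
    aln_cache[[key]]
  }
  best_of <- function(svec, ids, get_identity) {
    cand <- which(svec == max(svec))
    if (length(cand) > 1) {
      idn <- vapply(cand, get_identity, numeric(1))
      cand <- cand[idn == max(idn)]
      if (length(cand) > 1) cand <- cand[order(ids[cand])][1]
    }
    cand[1]
  }
  best_a <- vapply(seq_len(nrow(scores)), function(i) {
    best_of(scores[i, ], cds_b$gene_id, function(j) get_aln(i, j)$identity)
  }, integer(1))
  best_b <- vapply(seq_len(ncol(scores)), function(j) {
    best_of(scores[, j], cds_a$gene_id, function(i) get_aln(i, j)$identity)
  }, integer(1))

  rows <- list(); alns <- list()
  for (i in seq_len(nrow(scores))) {
    j <- best_a[i]
    if (best_b[j] != i) next                       # not reciprocal
    pa <- get_aln(i, j)
    both <- strsplit(pa$aligned_a, "")[[1]] != "-" &
            strsplit(pa$aligned_b, "")[[1]] != "-"
    cov <- min(sum(both) / nchar(prot_a[i]), sum(both) / nchar(prot_b[j]))
    if (pa$identity < min_identity || cov < min_coverage) next
    op <- tryCatch(
      thread_codon_alignment(pa, cds_a$seq[i], cds_b$seq[j],
                             species_a = cds_a$species[1],
                             species_b = cds_b$species[1],
                             min_codons = min_codons),
      error = function(e) {
        if (grepl("TOO_SHORT_ALIGNMENT", conditionMessage(e))) NULL
        else stop(e)
      })
    if (is.null(op)) next
    rows[[length(rows) + 1L]] <- data.frame(
      species_a = op$species_a, gene_a = op$gene_a,
      species_b = op$species_b, gene_b = op$gene_b,
      score = pa$score, identity = pa$identity, n_codons = op$n_codons,
      stringsAsFactors = FALSE)
    alns[[length(alns) + 1L]] <- op
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_a = character(0), gene_a = character(0),
               species_b = character(0), gene_b = character(0),
               score = numeric(0), identity = numeric(0),
               n_codons = integer(0), stringsAsFactors = FALSE)
  structure(list(pairs = pairs, alignments = alns), class = "ortholog_pairs")
}

#' @export
print.ortholog_pairs <- function(x, ...) {
  cat("Reciprocal-best-hit ortholog pairs:", nrow(x$pairs), "\n")
  if (nrow(x$pairs)) {
    cat("  median identity:", stats::median(x$pairs$identity),
        " median codons:", stats::median(x$pairs$n_codons), "\n")
  }
  invisible(x)
}
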