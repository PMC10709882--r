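# CDS input/output and admission rules.
#
# A CDS set is a plain data.frame with columns gene_id, species, seq
# (uppercase DNA). Sequences are normalised on input: uppercased, U -> T.

#' Construct a CDS set
#'
#' @param gene_id character vector of gene identifiers, unique within a
#'   species.
#' @param seq character vector of DNA sequences (uppercase; U is mapped to T).
#' @param species single species label, or a vector parallel to `gene_id`.
#' @return A data.frame of class `cds_set` with columns `gene_id`, `species`,
#'   `seq`.
#' @export
cds_set <- function(gene_id, seq, species = "unknown") {
  gene_id <- as.character(gene_id)
  seq <- toupper(chartr("Uu", "Tt", as.character(seq)))
  if (length(species) == 1L) species <- rep(species, length(gene_id))
  if (any(!nzchar(gene_id))) stop("empty gene_id", call. = FALSE)
  if (any(!nzchar(seq))) stop("empty sequence", call. = FALSE)
  dup <- tapply(gene_id, species, function(g) g[duplicated(g)])
  dup <- unlist(dup, use.names = FALSE)
  if (length(dup)) {
    stop("DUPLICATE_ID: duplicated gene_id within species: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(gene_id = gene_id, species = species, seq = seq,
                    stringsAsFactors = FALSE)
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Read coding sequences from a FASTA file
#'
#' The token before the first whitespace in each header becomes the gene id.
#' Sequences are uppercased and U is mapped to T.
#'
#' @param path path to a nucleotide multi-FASTA file.
#' @param species species label attached to every record.
#' @return A `cds_set` data.frame.
#' @export
read_fasta <- function(path, species = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  cds_set(ids, as.character(ss), species = species)
}

#' Write a CDS set to FASTA
#'
#' @param records a `cds_set` data.frame.
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  ss <- Biostrings::BStringSet(records$seq)
  names(ss) <- records$gene_id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Filter coding sequences by admission rules
#'
#' A sequence is kept iff it is strictly longer than `min_len_bp`, starts
#' with ATG, ends with a stop codon (TAA/TAG/TGA), has length divisible by
#' 3, contains no in-frame internal stop codon, and contains no ambiguous
#' base. Rejected records carry the first failing rule, checked in the
#' order: TOO_SHORT, NO_ATG_START, NO_VALID_STOP, LEN_NOT_MULTIPLE_OF_3,
#' INTERNAL_STOP, AMBIGUOUS_BASE.
#'
#' @param records a `cds_set` data.frame.
#' @param min_len_bp minimum length in bp, exclusive (default 300: kept
#'   sequences exceed 300 bp).
#' @return A list of class `filter_report` with elements `kept` (a
#'   `cds_set`) and `rejected` (data.frame gene_id, species, reason).
#' @export
filter_cds <- function(records, min_len_bp = 300L) {
  seqs <- records$seq
  n <- nchar(seqs)
  reason <- rep(NA_character_, length(seqs))

  fail <- function(cond, code) {
    hit <- is.na(reason) & cond
    reason[hit] <<- code
  }
  fail(n <= min_len_bp, "TOO_SHORT")
  fail(substring(seqs, 1L, 3L) != "ATG", "NO_ATG_START")
  last3 <- substring(seqs, pmax(n - 2L, 1L), n)
  fail(!(last3 %in% .STOP_CODONS), "NO_VALID_STOP")
  fail(n %% 3L != 0L, "LEN_NOT_MULTIPLE_OF_3")

  todo <- which(is.na(reason))
  if (length(todo)) {
    internal <- vapply(seqs[todo], function(s) {
      cod <- .codon_split(s)
      any(cod[-length(cod)] %in% .STOP_CODONS)
    }, logical(1), USE.NAMES = FALSE)
    reason[todo[internal]] <- "INTERNAL_STOP"
  }
  fail(grepl("[^ACGT]", seqs), "AMBIGUOUS_BASE")

  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("cds_set", "data.frame")
  rejected <- data.frame(gene_id = records$gene_id[!keep],
                         species = records$species[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  structure(list(kept = kept, rejected = rejected),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("CDS admission report:", nrow(x$kept), "kept,",
      nrow(x$rejected), "rejected\n")
  if (nrow(x$rejected)) {
    print(table(x$rejected$reason))
  }
  invisible(x)
}

#' Serialize a filter report as TSV
#'
#' Columns: gene_id, status (kept/rejected), reason (empty for kept).
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    gene_id = c(report$kept$gene_id, report$rejected$gene_id),
    status = rep(c("kept", "rejected"),
                 c(nrow(report$kept), nrow(report$rejected))),
    reason = c(rep("", nrow(report$kept)), report$rejected$reason),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Translate an in-frame CDS to protein
#'
#' Standard genetic code (table 1); a terminal stop codon is dropped. An
#' internal stop raises an error.
#'
#' @param seq a single DNA sequence (character), in frame.
#' @return The protein sequence as a single string.
#' @export
translate_cds <- function(seq) {
  cod <- .codon_split(toupper(chartr("Uu", "Tt", seq)))
  if (length(cod) && cod[length(cod)] %in% .STOP_CODONS) {
    cod <- cod[-length(cod)]
  }
  aa <- .GENCODE[cod]
  if (anyNA(aa)) {
    stop("untranslatable codon(s): ",
         paste(unique(cod[is.na(aa)]), collapse = ", "), call. = FALSE)
  }
  if (any(aa == "*")) {
    stop("INTERNAL_STOP: internal stop codon at codon position ",
         which(aa == "*")[1], call. = FALSE)
  }
  paste(aa, collapse = "")
}
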