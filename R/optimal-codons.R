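# Optimal codon determination: extreme-CAI partitions, delta-RSCU,
# threshold calls, and cross-species universal optimal codons.

#' Two-pass CAI ranking
#'
#' CAI needs a highly-expressed reference set, which is itself unknown for
#' a de novo corpus. Pass 1 builds weights from the whole corpus and ranks
#' genes; weights are then rebuilt from the provisional top fraction, and
#' pass 2 recomputes CAI against that reference. The procedure is
#' deterministic.
#'
#' @param tables named list of per-gene `codon_count` tables (names are
#'   gene ids).
#' @param fraction fraction of genes used as the provisional reference
#'   (default 0.10).
#' @param w_floor weight floor passed to [build_w_table()].
#' @return A list with `cai` (named numeric, final per-gene CAI) and `w`
#'   (the pass-2 `w_table`).
#' @export
cai_two_pass <- function(tables, fraction = 0.10, w_floor = 0.01) {
  stopifnot(length(tables) > 0, !is.null(names(tables)))
  w1 <- build_w_table(tables, w_floor = w_floor, source_label = "corpus")
  cai1 <- vapply(tables, cai, numeric(1), w = w1)
  usable <- names(cai1)[!is.na(cai1)]
  k <- ceiling(fraction * length(usable))
  ord <- usable[order(-cai1[usable], usable)]
  top <- ord[seq_len(k)]
  w2 <- build_w_table(tables[top], w_floor = w_floor,
                      source_label = "top-fraction reference")
  list(cai = vapply(tables, cai, numeric(1), w = w2), w = w2)
}

#' Partition genes by extreme CAI
#'
#' Genes are sorted by CAI (descending, ties broken by gene id ascending);
#' the top ceil(fraction * N) form the high-expression set and the bottom
#' ceil(fraction * N) the low-expression set.
#'
#' @param cai_values named numeric vector of per-gene CAI.
#' @param fraction fraction per tail, in (0, 0.5) (default 0.10).
#' @return A list of class `expression_partition` with `high`, `low`
#'   (gene-id vectors), `fraction` and `ranking_statistic`.
#' @export
partition_by_cai <- function(cai_values, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 0.5) {
    stop("fraction must lie in (0, 0.5)", call. = FALSE)
  }
  ok <- !is.na(cai_values)
  ids <- names(cai_values)[ok]
  if (length(ids) < 20) {
    stop("need at least 20 genes with defined CAI, got ", length(ids),
         call. = FALSE)
  }
  vals <- cai_values[ok]
  k <- ceiling(fraction * length(ids))
  if (2L * k > length(ids)) {
    stop("partitions would overlap: ", k, " per tail from ", length(ids),
         " genes", call. = FALSE)
  }
  desc <- ids[order(-vals, ids)]
  asc <- ids[order(vals, ids)]
  structure(list(high = desc[seq_len(k)], low = asc[seq_len(k)],
                 fraction = fraction, ranking_statistic = "CAI"),
            class = "expression_partition")
}

#' @export
print.expression_partition <- function(x, ...) {
  cat("Expression partition by", x$ranking_statistic, "- fraction",
      x$fraction, ":", length(x$high), "high /", length(x$low), "low genes\n")
  invisible(x)
}

#' RSCU difference between high- and low-expression gene sets
#'
#' @param high_counts pooled `codon_count` of the high-expression set.
#' @param low_counts pooled `codon_count` of the low-expression set.
#' @return A data.frame over the synonymously variable codons: codon,
#'   amino_acid, rscu_high, rscu_low, delta_rscu (NA propagates).
#' @export
delta_rscu <- function(high_counts, low_counts) {
  rh <- rscu(high_counts)[.SYN_VARIABLE]
  rl <- rscu(low_counts)[.SYN_VARIABLE]
  data.frame(codon = .SYN_VARIABLE,
             amino_acid = unname(.AA[.SYN_VARIABLE]),
             rscu_high = unname(rh), rscu_low = unname(rl),
             delta_rscu = unname(rh - rl),
             stringsAsFactors = FALSE)
}

#' Call optimal codons from a delta-RSCU table
#'
#' A codon is optimal when its RSCU in the high-expression set is at least
#' `rscu_min` and its delta-RSCU (high minus low) is at least `delta_min`;
#' both comparisons are inclusive. ATG, TGG and stop codons are never
#' candidates.
#'
#' @param delta_table output of [delta_rscu()].
#' @param rscu_min RSCU threshold (default 1.0).
#' @param delta_min delta-RSCU threshold (default 0.08).
#' @return The input data.frame with a logical `is_optimal` column.
#' @export
call_optimal <- function(delta_table, rscu_min = 1.0, delta_min = 0.08) {
  opt <- !is.na(delta_table$rscu_high) & !is.na(delta_table$delta_rscu) &
    delta_table$rscu_high >= rscu_min & delta_table$delta_rscu >= delta_min
  opt[!(delta_table$codon %in% .SYN_VARIABLE)] <- FALSE
  delta_table$is_optimal <- opt
  delta_table
}

#' Universal optimal codons across species
#'
#' @param per_species named list: species -> character vector of optimal
#'   codons.
#' @param min_species minimum number of species a codon must be optimal in
#'   (default: all of them, i.e. strict intersection).
#' @return Character vector of codons, sorted.
#' @export
universal_optimal <- function(per_species, min_species = length(per_species)) {
  if (length(per_species) < 2) stop("need at least 2 species", call. = FALSE)
  if (min_species > length(per_species)) {
    stop("min_species exceeds the number of species", call. = FALSE)
  }
  tab <- table(unlist(lapply(per_species, unique)))
  sort(names(tab)[tab >= min_species])
}

#' Determine optimal codons for one species
#'
#' Runs the whole per-species procedure: per-gene codon counts, two-pass
#' CAI, extreme-CAI partition, pooled high/low RSCU, delta-RSCU and the
#' threshold call.
#'
#' @param records a `cds_set` of admitted CDS for one species.
#' @param fraction extreme-CAI tail fraction (default 0.10).
#' @param rscu_min,delta_min thresholds passed to [call_optimal()].
#' @param w_floor CAI weight floor.
#' @return A list of class `optimal_codons`: `calls` (data.frame from
#'   [call_optimal()]), `optimal` (character vector), `partition`, `cai`
#'   (named numeric), `species`.
#' @export
find_optimal_codons <- function(records, fraction = 0.10, rscu_min = 1.0,
                                delta_min = 0.08, w_floor = 0.01) {
  tables <- lapply(seq_len(nrow(records)), function(i) {
    count_codons(records$seq[i], scope = records$gene_id[i])
  })
  names(tables) <- records$gene_id
  ranking <- cai_two_pass(tables, fraction = fraction, w_floor = w_floor)
  part <- partition_by_cai(ranking$cai, fraction = fraction)
  high <- pool_codon_counts(tables[part$high], scope = "high")
  low <- pool_codon_counts(tables[part$low], scope = "low")
  calls <- call_optimal(delta_rscu(high, low),
                        rscu_min = rscu_min, delta_min = delta_min)
  structure(list(calls = calls,
                 optimal = calls$codon[calls$is_optimal],
                 partition = part, cai = ranking$cai,
                 species = records$species[1]),
            class = "optimal_codons")
}

#' @export
print.optimal_codons <- function(x, ...) {
  cat("Optimal codons for", x$species, "(", length(x$optimal), "):",
      paste(x$optimal, collapse = " "), "\n")
  invisible(x)
}
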