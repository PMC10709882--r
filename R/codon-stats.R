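# Codon-usage statistics: codon counts, RSCU, positional composition,
# ENC (Wright), CAI, CBI, PR2 coordinates.

#' Count codons of an in-frame CDS
#'
#' @param seq a single in-frame DNA sequence.
#' @param drop_terminal_stop drop the 3'-terminal stop codon before
#'   counting (default TRUE).
#' @param scope label stored with the table (gene id or set label).
#' @return An integer vector of class `codon_count` over all 64 codons,
#'   with attributes `scope` and `n_codons`.
#' @export
count_codons <- function(seq, drop_terminal_stop = TRUE, scope = NA_character_) {
  cod <- .codon_split(seq)
  if (drop_terminal_stop && length(cod) &&
      cod[length(cod)] %in% .STOP_CODONS) {
    cod <- cod[-length(cod)]
  }
  counts <- table(factor(cod, levels = .CODONS))
  out <- as.integer(counts)
  names(out) <- .CODONS
  structure(out, scope = scope, n_codons = sum(out), class = "codon_count")
}

#' Pool codon count tables
#'
#' @param tables a list of `codon_count` vectors (or a `cds_set`, in which
#'   case per-gene tables are computed first).
#' @param scope label for the pooled table.
#' @return A pooled `codon_count`.
#' @export
pool_codon_counts <- function(tables, scope = "pooled") {
  if (inherits(tables, "cds_set")) {
    tables <- lapply(tables$seq, count_codons)
  }
  out <- Reduce(`+`, lapply(tables, function(x) {
    stopifnot(identical(names(x), .CODONS))
    as.integer(x)
  }))
  names(out) <- .CODONS
  structure(out, scope = scope, n_codons = sum(out), class = "codon_count")
}

#' Relative synonymous codon usage
#'
#' For codon j in an amino-acid family of degeneracy n with family total T,
#' RSCU = count_j / (T / n). Families with no observation give NA; ATG and
#' TGG are reported as 1 when observed; stop codons are excluded.
#'
#' @param table a `codon_count`.
#' @return Named numeric vector over the 61 sense codons.
#' @export
rscu <- function(table) {
  x <- as.numeric(table[.SENSE_CODONS])
  names(x) <- .SENSE_CODONS
  out <- rep(NA_real_, length(x))
  names(out) <- .SENSE_CODONS
  for (fam in .FAMILIES) {
    tot <- sum(x[fam])
    if (tot > 0) out[fam] <- x[fam] / (tot / length(fam))
  }
  # single-codon families: 1 when observed
  for (cod in c("ATG", "TGG")) {
    out[cod] <- if (x[cod] > 0) 1 else NA_real_
  }
  out
}

#' Positional nucleotide and GC composition
#'
#' gc1/gc2/gc3 are the G+C fractions at codon positions 1-3 over all
#' non-stop codons; gc is their mean. The "3s" quantities restrict to
#' synonymously variable codons (ATG, TGG and stops excluded): a3s, u3s,
#' c3s, g3s are the base frequencies at the third position in that
#' restricted set, and gc3s = c3s + g3s.
#'
#' @param table a `codon_count`.
#' @return Named numeric vector: gc, gc1, gc2, gc3, gc3s, a3s, u3s, c3s, g3s.
#' @export
positional_composition <- function(table) {
  cnt <- as.numeric(table[.SENSE_CODONS])
  names(cnt) <- .SENSE_CODONS
  if (sum(cnt) == 0) stop("empty codon table", call. = FALSE)

  base_at <- function(codons, pos) substring(codons, pos, pos)
  gc_pos <- function(pos) {
    b <- base_at(.SENSE_CODONS, pos)
    sum(cnt[b %in% c("G", "C")]) / sum(cnt)
  }
  gc1 <- gc_pos(1); gc2 <- gc_pos(2); gc3 <- gc_pos(3)

  sv <- .SYN_VARIABLE
  tot3 <- sum(cnt[sv])
  b3 <- base_at(sv, 3)
  f3 <- function(base) {
    if (tot3 == 0) return(NA_real_)
    sum(cnt[sv][b3 == base]) / tot3
  }
  a3s <- f3("A"); u3s <- f3("T"); c3s <- f3("C"); g3s <- f3("G")

  c(gc = (gc1 + gc2 + gc3) / 3, gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc3s = if (tot3 == 0) NA_real_ else c3s + g3s,
    a3s = a3s, u3s = u3s, c3s = c3s, g3s = g3s)
}

#' Effective number of codons (Wright's Nc)
#'
#' For each degenerate family with n >= 2 observations, the codon
#' homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1). F values are
#' averaged within degeneracy classes (2-, 3-, 4-, 6-fold) and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at 61. If the 3-fold class
#' (Ile) is missing, its term is imputed as the mean of 1/F2 and 1/F4; if
#' any other class is missing the result is NA.
#'
#' @param table a `codon_count`.
#' @return ENC in [20, 61], or NA.
#' @export
enc <- function(table) {
  cnt <- as.numeric(table[.SENSE_CODONS])
  names(cnt) <- .SENSE_CODONS
  fhat <- lapply(.DEG_FAMILIES, function(fam) {
    n <- sum(cnt[fam])
    if (n < 2) return(NULL)
    p <- cnt[fam] / n
    list(deg = length(fam), f = (n * sum(p^2) - 1) / (n - 1))
  })
  fhat <- Filter(Negate(is.null), fhat)
  if (!length(fhat)) return(NA_real_)
  deg <- vapply(fhat, `[[`, numeric(1), "deg")
  f <- vapply(fhat, `[[`, numeric(1), "f")
  fbar <- vapply(c(2, 3, 4, 6), function(d) {
    if (any(deg == d)) mean(f[deg == d]) else NA_real_
  }, numeric(1))
  names(fbar) <- c("2", "3", "4", "6")

  inv <- function(fb) if (is.na(fb)) NA_real_ else if (fb <= 0) Inf else 1 / fb
  t2 <- inv(fbar["2"]); t3 <- inv(fbar["3"])
  t4 <- inv(fbar["4"]); t6 <- inv(fbar["6"])
  if (is.na(t2) || is.na(t4) || is.na(t6)) return(NA_real_)
  if (is.na(t3)) t3 <- mean(c(t2, t4))
  val <- 2 + 9 * t2 + 1 * t3 + 5 * t4 + 3 * t6
  min(val, 61)
}

#' Build a relative-adaptiveness (w) table for CAI
#'
#' Counts of the reference set are pooled; within each family
#' w = RSCU / max(RSCU). Unobserved codons of observed families receive
#' `w_floor`; wholly unobserved families are neutral (w = 1).
#'
#' @param reference a list of `codon_count` tables, a single pooled
#'   `codon_count`, or a `cds_set`.
#' @param w_floor weight assigned to unobserved codons of observed
#'   families (default 0.01, avoids log(0)).
#' @param source_label provenance label.
#' @return A list of class `w_table` with elements `w` (named over sense
#'   codons) and `source_label`.
#' @export
build_w_table <- function(reference, w_floor = 0.01, source_label = "reference") {
  pooled <- if (inherits(reference, "codon_count")) reference
            else pool_codon_counts(reference)
  if (sum(pooled) == 0) stop("empty reference set", call. = FALSE)
  r <- rscu(pooled)
  w <- rep(1, length(.SENSE_CODONS))
  names(w) <- .SENSE_CODONS
  for (fam in .FAMILIES) {
    rf <- r[fam]
    if (all(is.na(rf))) next                       # unobserved family: neutral
    w[fam] <- pmax(rf / max(rf, na.rm = TRUE), 0)
    w[fam][pooled[fam] == 0] <- w_floor
  }
  structure(list(w = w, source_label = source_label), class = "w_table")
}

#' Codon adaptation index
#'
#' Geometric mean of the relative-adaptiveness weights over the gene's
#' codons, excluding ATG, TGG and stops.
#'
#' @param table a `codon_count`.
#' @param w a `w_table` from [build_w_table()].
#' @return CAI in (0, 1], or NA if the gene has no synonymously variable
#'   codons.
#' @export
cai <- function(table, w) {
  stopifnot(inherits(w, "w_table"))
  cnt <- as.numeric(table[.SYN_VARIABLE])
  L <- sum(cnt)
  if (L == 0) return(NA_real_)
  exp(sum(cnt * log(w$w[.SYN_VARIABLE])) / L)
}

#' Codon bias index
#'
#' CBI = (N_opt - N_ran) / (N_tot - N_ran) over synonymously variable
#' codons of families that contain at least one optimal codon; families
#' without an optimal codon are skipped. N_ran is the usage expected if
#' codons were chosen at random within each family.
#'
#' @param table a `codon_count`.
#' @param optimal character vector of optimal codons.
#' @return CBI in [-1, 1], or NA when undefined.
#' @export
cbi <- function(table, optimal) {
  cnt <- as.numeric(table[.SENSE_CODONS])
  names(cnt) <- .SENSE_CODONS
  n_opt <- 0; n_tot <- 0; n_ran <- 0
  for (fam in .DEG_FAMILIES) {
    k_opt <- sum(fam %in% optimal)
    if (k_opt == 0) next
    n_fam <- sum(cnt[fam])
    n_tot <- n_tot + n_fam
    n_opt <- n_opt + sum(cnt[intersect(fam, optimal)])
    n_ran <- n_ran + n_fam * k_opt / length(fam)
  }
  if (n_tot - n_ran == 0) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' PR2 plot coordinates
#'
#' Third-position base counts restricted to the eight fourfold-degenerate
#' codon families (Ala, Gly, Pro, Thr, Val and the fourfold halves of Leu,
#' Ser, Arg): x = G3/(G3+C3), y = A3/(A3+T3). (0.5, 0.5) indicates no
#' strand bias.
#'
#' @param table a `codon_count`.
#' @return Named numeric vector c(x, y); NA when a denominator is zero.
#' @export
pr2_point <- function(table) {
  cnt <- as.numeric(table[.PR2_CODONS])
  b3 <- substring(.PR2_CODONS, 3, 3)
  tot <- vapply(.BASES, function(b) sum(cnt[b3 == b]), numeric(1))
  gc_den <- tot["G"] + tot["C"]
  at_den <- tot["A"] + tot["T"]
  c(x = if (gc_den > 0) unname(tot["G"] / gc_den) else NA_real_,
    y = if (at_den > 0) unname(tot["A"] / at_den) else NA_real_)
}

#' Per-gene codon usage profiles
#'
#' Computes the full per-gene profile table: codon totals, positional GC
#' composition, ENC, CAI (when a weight table is supplied), CBI (when an
#' optimal-codon set is supplied) and PR2 coordinates.
#'
#' @param records a `cds_set` of admitted CDS.
#' @param w optional `w_table` for CAI.
#' @param optimal optional character vector of optimal codons for CBI.
#' @return A data.frame with one row per gene: gene_id, species, n_codons,
#'   gc, gc1, gc2, gc3, gc3s, a3s, u3s, c3s, g3s, enc, cai, cbi, pr2_x,
#'   pr2_y.
#' @export
codon_usage <- function(records, w = NULL, optimal = NULL) {
  tabs <- lapply(seq_len(nrow(records)), function(i) {
    count_codons(records$seq[i], scope = records$gene_id[i])
  })
  rows <- lapply(tabs, function(tb) {
    comp <- positional_composition(tb)
    p <- pr2_point(tb)
    data.frame(n_codons = attr(tb, "n_codons"),
               t(comp),
               enc = enc(tb),
               cai = if (is.null(w)) NA_real_ else cai(tb, w),
               cbi = if (is.null(optimal)) NA_real_ else cbi(tb, optimal),
               pr2_x = p[["x"]], pr2_y = p[["y"]])
  })
  out <- cbind(records[, c("gene_id", "species")], do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Per-species RSCU matrix
#'
#' @param records a `cds_set` (one or several species).
#' @return A 61 x n_species numeric matrix of pooled RSCU values.
#' @export
rscu_matrix <- function(records) {
  sp <- unique(records$species)
  m <- vapply(sp, function(s) {
    rscu(pool_codon_counts(records[records$species == s, , drop = FALSE],
                           scope = s))
  }, numeric(length(.SENSE_CODONS)))
  m <- matrix(m, nrow = length(.SENSE_CODONS),
              dimnames = list(.SENSE_CODONS, sp))
  m
}
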