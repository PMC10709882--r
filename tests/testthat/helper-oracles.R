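# Independent brute-force oracles, written directly from the defining
# formulas. They share nothing with the package implementation beyond the
# standard genetic code.

orc_code <- Biostrings::GENETIC_CODE
orc_sense <- sort(names(orc_code)[orc_code != "*"])
orc_stops <- names(orc_code)[orc_code == "*"]
orc_fams <- split(orc_sense, orc_code[orc_sense])
orc_single <- c("ATG", "TGG")

orc_rscu <- function(counts) {
  out <- setNames(rep(NA_real_, length(orc_sense)), orc_sense)
  for (fam in orc_fams) {
    tot <- sum(counts[fam])
    if (tot > 0) {
      for (cod in fam) out[cod] <- counts[cod] / ((1 / length(fam)) * tot)
    }
  }
  out
}

orc_enc <- function(counts) {
  deg <- c(); f <- c()
  for (fam in orc_fams[lengths(orc_fams) >= 2]) {
    n <- sum(counts[fam])
    if (n < 2) next
    p <- counts[fam] / n
    deg <- c(deg, length(fam))
    f <- c(f, (n * sum(p^2) - 1) / (n - 1))
  }
  if (!length(deg)) return(NA_real_)
  fbar <- function(d) if (any(deg == d)) mean(f[deg == d]) else NA_real_
  term <- function(fb) if (is.na(fb)) NA_real_ else if (fb <= 0) Inf else 1 / fb
  t2 <- term(fbar(2)); t3 <- term(fbar(3)); t4 <- term(fbar(4)); t6 <- term(fbar(6))
  if (is.na(t2) || is.na(t4) || is.na(t6)) return(NA_real_)
  if (is.na(t3)) t3 <- (t2 + t4) / 2
  min(2 + 9 * t2 + t3 + 5 * t4 + 3 * t6, 61)
}

orc_cai <- function(counts, w) {
  use <- setdiff(orc_sense, orc_single)
  L <- sum(counts[use])
  if (L == 0) return(NA_real_)
  prod(vapply(use, function(cod) w[cod]^(counts[cod] / L), numeric(1)))
}

orc_cbi <- function(counts, optimal) {
  n_opt <- 0; n_tot <- 0; n_ran <- 0
  for (fam in orc_fams[lengths(orc_fams) >= 2]) {
    k <- sum(fam %in% optimal)
    if (k == 0) next
    n_tot <- n_tot + sum(counts[fam])
    n_opt <- n_opt + sum(counts[fam[fam %in% optimal]])
    n_ran <- n_ran + sum(counts[fam]) * k / length(fam)
  }
  if (n_tot - n_ran == 0) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

# enumerate the single-nucleotide mutants of a codon
orc_mutants <- function(codon, pos) {
  from <- substring(codon, pos, pos)
  vapply(setdiff(c("A", "C", "G", "T"), from), function(b) {
    x <- codon; substring(x, pos, pos) <- b; x
  }, character(1))
}

orc_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    tg <- orc_mutants(codon, pos)
    tg <- tg[!tg %in% orc_stops]
    if (length(tg)) s <- s + sum(orc_code[tg] == orc_code[codon]) / length(tg)
  }
  c(s, 3 - s)
}

# all orderings of up to three positions, hardcoded
orc_orderings <- function(pos) {
  n <- length(pos)
  if (n == 1) return(list(pos))
  if (n == 2) return(list(pos, pos[2:1]))
  idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
              c(3, 1, 2), c(3, 2, 1))
  lapply(idx, function(i) pos[i])
}

orc_diffs <- function(a, b) {
  if (a == b) return(c(0, 0))
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  res <- list()
  for (ord in orc_orderings(pos)) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; substring(nxt, p, p) <- substring(b, p, p)
      if (nxt %in% orc_stops) { ok <- FALSE; break }
      if (orc_code[nxt] == orc_code[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- list(ok = ok, sd = sd, nd = nd)
  }
  ok <- vapply(res, `[[`, logical(1), "ok")
  if (any(ok)) res <- res[ok]
  c(mean(vapply(res, `[[`, numeric(1), "sd")),
    mean(vapply(res, `[[`, numeric(1), "nd")))
}

# exhaustive global-alignment score under affine gaps: every monotone
# path is enumerated and scored (gap of length L costs open + L * ext)
orc_align_score <- function(a, b, mat, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  score_ops <- function(ops) {
    ia <- 0; ib <- 0; sc <- 0; run <- ""
    for (op in ops) {
      if (op == "M") {
        ia <- ia + 1; ib <- ib + 1
        sc <- sc + mat[A[ia], B[ib]]
        run <- ""
      } else {
        if (op != run) sc <- sc - open
        sc <- sc - ext
        run <- op
        if (op == "A") ia <- ia + 1 else ib <- ib + 1
      }
    }
    sc
  }
  rec <- function(ia, ib, ops) {
    if (ia == length(A) && ib == length(B)) {
      best <<- max(best, score_ops(ops)); return(invisible())
    }
    if (ia < length(A) && ib < length(B)) rec(ia + 1, ib + 1, c(ops, "M"))
    if (ia < length(A)) rec(ia + 1, ib, c(ops, "A"))
    if (ib < length(B)) rec(ia, ib + 1, c(ops, "B"))
  }
  rec(0, 0, character(0))
  best
}

# random sparse codon-count table over the sense codons
random_count_table <- function(seed, lambda = 2) {
  set.seed(seed)
  counts <- stats::rpois(64, lambda)
  names(counts) <- sort(names(orc_code))
  counts[orc_stops] <- 0L
  # knock out a couple of whole families to exercise the NA paths
  for (fam in sample(orc_fams, 2)) counts[fam] <- 0L
  counts
}

as_codon_count <- function(counts) {
  full <- setNames(integer(64), sort(names(orc_code)))
  full[names(counts)] <- as.integer(counts)
  structure(unname(full), names = names(full),
            scope = "test", n_codons = sum(full),
            class = "codon_count")
}

# a valid CDS built from explicit body codons
make_cds <- function(..., stop = "TAA") paste0("ATG", paste0(...), stop)
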