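# Ka/Ks estimation per ortholog pair: Nei-Gojobori (1986) counting with
# Jukes-Cantor correction, and the Yang-Nielsen (2000) approximate method
# accounting for transition/transversion bias (kappa) and codon
# frequencies (F3x4), plus selection-class assignment and cross-pairing
# commonality of positively selected genes.

# ---- lazily built lookup tables ------------------------------------------

# all single-nucleotide mutations of each sense codon
.mutation_table <- function() {
  if (!is.null(.cache$mut)) return(.cache$mut)
  mut <- lapply(.SENSE_CODONS, function(cod) {
    from_aa <- .GENCODE[cod]
    rows <- list()
    for (pos in 1:3) {
      from_base <- substring(cod, pos, pos)
      for (to_base in setdiff(.BASES, from_base)) {
        target <- cod
        substring(target, pos, pos) <- to_base
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, target = target,
          ts = .is_transition(from_base, to_base),
          stop = target %in% .STOP_CODONS,
          syn = !(target %in% .STOP_CODONS) && .GENCODE[target] == from_aa,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  names(mut) <- .SENSE_CODONS
  .cache$mut <- mut
  mut
}

# minimal mutational pathways between two sense codons: a list of paths,
# each a data.frame of steps (from, to, syn, ts, through_stop)
.codon_paths <- function(a, b) {
  key <- paste0(a, "|", b)
  if (!is.null(.cache$paths[[key]])) return(.cache$paths[[key]])
  if (is.null(.cache$paths)) .cache$paths <- list()
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  perms <- .permutations(diff_pos)
  paths <- lapply(perms, function(ord) {
    cur <- a
    steps <- vector("list", length(ord))
    for (k in seq_along(ord)) {
      nxt <- cur
      substring(nxt, ord[k], ord[k]) <- substring(b, ord[k], ord[k])
      fb <- substring(cur, ord[k], ord[k])
      tb <- substring(nxt, ord[k], ord[k])
      is_stop <- nxt %in% .STOP_CODONS
      steps[[k]] <- data.frame(
        from = cur, to = nxt,
        syn = !is_stop && !(cur %in% .STOP_CODONS) &&
          .GENCODE[nxt] == .GENCODE[cur],
        ts = .is_transition(fb, tb), through_stop = is_stop,
        stringsAsFactors = FALSE)
      cur <- nxt
    }
    df <- do.call(rbind, steps)
    df$through_stop <- cumsum(df$through_stop) > 0 |
      df$from %in% .STOP_CODONS
    df
  })
  valid <- !vapply(paths, function(p) any(p$through_stop), logical(1))
  out <- list(paths = paths, valid = valid)
  .cache$paths[[key]] <- out
  out
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# ---- NG86 ----------------------------------------------------------------

#' NG86 synonymous/nonsynonymous site counts of a codon
#'
#' Over the single-nucleotide mutations at each position (mutations to
#' stop codons excluded from the per-position denominator), the
#' synonymous site count is the summed fraction of synonymous changes;
#' nonsynonymous sites are the complement to 3.
#'
#' @param codon a sense codon.
#' @return Named numeric c(s_sites, n_sites), summing to 3.
#' @export
count_sites_ng86 <- function(codon) {
  .check_codon(codon)
  mut <- .mutation_table()[[codon]]
  s <- 0
  for (pos in 1:3) {
    m <- mut[mut$pos == pos & !mut$stop, , drop = FALSE]
    if (nrow(m)) s <- s + sum(m$syn) / nrow(m)
  }
  c(s_sites = s, n_sites = 3 - s)
}

#' NG86 synonymous/nonsynonymous difference counts between two codons
#'
#' Averages the synonymous and nonsynonymous step counts over all minimal
#' mutational pathways between the codons; pathways passing through stop
#' codons are excluded (unless no stop-free pathway exists, in which case
#' all pathways are used with stop-crossing steps counted as
#' nonsynonymous).
#'
#' @param codon_a,codon_b sense codons.
#' @return Named numeric c(sd, nd); sd + nd equals the Hamming distance.
#' @export
count_differences_ng86 <- function(codon_a, codon_b) {
  .check_codon(codon_a); .check_codon(codon_b)
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  pw <- .codon_paths(codon_a, codon_b)
  use <- if (any(pw$valid)) pw$paths[pw$valid] else pw$paths
  sd <- mean(vapply(use, function(p) sum(p$syn), numeric(1)))
  nd <- mean(vapply(use, function(p) sum(!p$syn), numeric(1)))
  c(sd = sd, nd = nd)
}

# 61x61 lookup matrices for fast whole-alignment NG86
.ng86_tables <- function() {
  if (!is.null(.cache$ng86)) return(.cache$ng86)
  ns <- length(.SENSE_CODONS)
  ssites <- vapply(.SENSE_CODONS, function(c) count_sites_ng86(c)[["s_sites"]],
                   numeric(1))
  sd <- matrix(0, ns, ns, dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  nd <- sd
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      d <- count_differences_ng86(.SENSE_CODONS[i], .SENSE_CODONS[j])
      sd[i, j] <- d[["sd"]]; nd[i, j] <- d[["nd"]]
    }
  }
  .cache$ng86 <- list(ssites = ssites, sd = sd, nd = nd)
  .cache$ng86
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

.aligned_codons <- function(seq_a, seq_b) {
  cod_a <- .codon_split(seq_a)
  cod_b <- .codon_split(seq_b)
  if (length(cod_a) != length(cod_b)) {
    stop("aligned sequences differ in codon length", call. = FALSE)
  }
  bad <- cod_a %in% .STOP_CODONS | cod_b %in% .STOP_CODONS
  list(a = cod_a[!bad], b = cod_b[!bad])
}

.kaks_result <- function(method, n_codons, S, N, Sd, Nd, ka, ks, kappa = NA_real_,
                         converged = TRUE, gene_a = NA, gene_b = NA,
                         species_pair = NA) {
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(method = method, gene_a = gene_a, gene_b = gene_b,
                 species_pair = species_pair, n_codons = n_codons,
                 S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ka = ka, Ks = ks, ratio = ratio, kappa = kappa,
                 converged = converged),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("%s: Ka = %s  Ks = %s  Ka/Ks = %s  (%d codons%s)\n",
              x$method, format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$ratio, digits = 4), x$n_codons,
              if (x$converged) "" else ", NONCONVERGED"))
  invisible(x)
}

#' Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Site and difference counts averaged over the two sequences and all
#' minimal pathways, with Jukes-Cantor distance correction. Proportions at
#' or beyond the correction's domain bound (p >= 0.75) give NA.
#'
#' @param seq_a,seq_b equal-length, gap-free, in-frame aligned CDS (or an
#'   `ortholog_pair` as the first argument).
#' @return A `kaks_result`.
#' @export
ng86 <- function(seq_a, seq_b = NULL) {
  if (inherits(seq_a, "ortholog_pair")) {
    op <- seq_a
    res <- ng86(op$codon_aln_a, op$codon_aln_b)
    res$gene_a <- op$gene_a; res$gene_b <- op$gene_b
    res$species_pair <- paste0(op$species_a, ":", op$species_b)
    return(res)
  }
  al <- .aligned_codons(seq_a, seq_b)
  tb <- .ng86_tables()
  S <- (sum(tb$ssites[al$a]) + sum(tb$ssites[al$b])) / 2
  N <- 3 * length(al$a) - S
  idx <- cbind(match(al$a, .SENSE_CODONS), match(al$b, .SENSE_CODONS))
  Sd <- sum(tb$sd[idx]); Nd <- sum(tb$nd[idx])
  ks <- .jc_correct(if (S > 0) Sd / S else NA_real_)
  ka <- .jc_correct(if (N > 0) Nd / N else NA_real_)
  .kaks_result("NG86", length(al$a), S, N, Sd, Nd, ka, ks)
}

# ---- YN00 ----------------------------------------------------------------

# degeneracy of each codon position: 4 = all changes synonymous,
# 0 = none synonymous (used for kappa estimation)
.position_degeneracy <- function() {
  if (!is.null(.cache$posdeg)) return(.cache$posdeg)
  mut <- .mutation_table()
  deg <- vapply(.SENSE_CODONS, function(cod) {
    vapply(1:3, function(pos) {
      m <- mut[[cod]][mut[[cod]]$pos == pos, ]
      sum(m$syn)
    }, numeric(1))
  }, numeric(3))
  .cache$posdeg <- t(deg)                 # 61 x 3, values 0..3
  .cache$posdeg
}

.k80_kappa <- function(P, Q) {
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  A <- -0.5 * log(a1) + 0.25 * log(a2)
  B <- -0.5 * log(a2)
  if (B <= 0) return(if (A > 0) 99 else NA_real_)
  max(min(2 * A / B, 99), 0.01)
}

.k80_distance <- function(P, Q) {
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

.estimate_kappa <- function(cod_a, cod_b) {
  pd <- .position_degeneracy()
  ia <- match(cod_a, .SENSE_CODONS); ib <- match(cod_b, .SENSE_CODONS)
  stats <- c(n4 = 0, ts4 = 0, tv4 = 0, n0 = 0, ts0 = 0, tv0 = 0)
  for (pos in 1:3) {
    da <- pd[ia, pos]; db <- pd[ib, pos]
    ba <- substring(cod_a, pos, pos); bb <- substring(cod_b, pos, pos)
    four <- da == 3 & db == 3
    zero <- da == 0 & db == 0
    for (cls in c("4", "0")) {
      sel <- if (cls == "4") four else zero
      if (!any(sel)) next
      diffs <- ba[sel] != bb[sel]
      ts <- diffs & .is_transition(ba[sel], bb[sel])
      stats[paste0("n", cls)] <- stats[paste0("n", cls)] + sum(sel)
      stats[paste0("ts", cls)] <- stats[paste0("ts", cls)] + sum(ts)
      stats[paste0("tv", cls)] <- stats[paste0("tv", cls)] + sum(diffs & !ts)
    }
  }
  ks <- c(); wts <- c()
  for (cls in c("4", "0")) {
    n <- stats[paste0("n", cls)]
    if (n < 5) next
    k <- .k80_kappa(stats[paste0("ts", cls)] / n, stats[paste0("tv", cls)] / n)
    if (!is.na(k)) { ks <- c(ks, k); wts <- c(wts, n) }
  }
  if (!length(ks)) return(1)
  sum(ks * wts) / sum(wts)
}

.f3x4_freqs <- function(cod_a, cod_b) {
  all_cod <- c(cod_a, cod_b)
  f <- vapply(1:3, function(pos) {
    b <- substring(all_cod, pos, pos)
    tab <- table(factor(b, levels = .BASES))
    as.numeric(tab) / length(b)
  }, numeric(4))                         # 4 x 3
  rownames(f) <- .BASES
  pi <- vapply(.SENSE_CODONS, function(cod) {
    f[substring(cod, 1, 1), 1] * f[substring(cod, 2, 2), 2] *
      f[substring(cod, 3, 3), 3]
  }, numeric(1))
  pi / sum(pi)
}

# kappa/frequency-weighted site counts of one codon
.yn_sites <- function(codon, kappa, pi) {
  mut <- .mutation_table()[[codon]]
  s <- 0
  for (pos in 1:3) {
    m <- mut[mut$pos == pos & !mut$stop, , drop = FALSE]
    if (!nrow(m)) next
    w <- ifelse(m$ts, kappa, 1) * pi[m$target]
    tw <- sum(w)
    if (tw > 0) s <- s + sum(w[m$syn]) / tw
  }
  c(s = s, n = 3 - s)
}

# pathway-weighted difference counts for one codon pair, split into
# transition/transversion and synonymous/nonsynonymous categories
.yn_differences <- function(a, b, kappa, omega, pi) {
  out <- c(s_ts = 0, s_tv = 0, n_ts = 0, n_tv = 0)
  if (a == b) return(out)
  pw <- .codon_paths(a, b)
  use <- if (any(pw$valid)) pw$paths[pw$valid] else pw$paths
  wts <- vapply(use, function(p) {
    prod(ifelse(p$ts, kappa, 1) * ifelse(p$syn, 1, omega) * pi[p$to])
  }, numeric(1))
  if (sum(wts) <= 0) wts <- rep(1, length(use))
  wts <- wts / sum(wts)
  for (k in seq_along(use)) {
    p <- use[[k]]
    out["s_ts"] <- out["s_ts"] + wts[k] * sum(p$syn & p$ts)
    out["s_tv"] <- out["s_tv"] + wts[k] * sum(p$syn & !p$ts)
    out["n_ts"] <- out["n_ts"] + wts[k] * sum(!p$syn & p$ts)
    out["n_tv"] <- out["n_tv"] + wts[k] * sum(!p$syn & !p$ts)
  }
  out
}

#' Ka/Ks by the Yang-Nielsen (2000) approximate method
#'
#' kappa is estimated from fourfold-degenerate and nondegenerate site
#' comparisons (K80); codon frequencies are taken as F3x4 (or equal);
#' sites and pathway-weighted differences use kappa, frequency and omega
#' weights, and omega is iterated to convergence with K80-corrected
#' synonymous and nonsynonymous distances.
#'
#' @param seq_a,seq_b equal-length, gap-free, in-frame aligned CDS (or an
#'   `ortholog_pair` as the first argument).
#' @param codon_freqs "F3x4" (default) or "equal".
#' @param tol convergence tolerance on omega (default 1e-6).
#' @param max_iter maximum iterations (default 100); non-convergence is
#'   flagged in the result.
#' @return A `kaks_result` (with `kappa`).
#' @export
yn00 <- function(seq_a, seq_b = NULL, codon_freqs = c("F3x4", "equal"),
                 tol = 1e-6, max_iter = 100L) {
  if (inherits(seq_a, "ortholog_pair")) {
    op <- seq_a
    res <- yn00(op$codon_aln_a, op$codon_aln_b, codon_freqs = codon_freqs,
                tol = tol, max_iter = max_iter)
    res$gene_a <- op$gene_a; res$gene_b <- op$gene_b
    res$species_pair <- paste0(op$species_a, ":", op$species_b)
    return(res)
  }
  codon_freqs <- match.arg(codon_freqs)
  al <- .aligned_codons(seq_a, seq_b)
  nc <- length(al$a)
  kappa <- .estimate_kappa(al$a, al$b)
  pi <- if (codon_freqs == "F3x4") .f3x4_freqs(al$a, al$b) else {
    p <- rep(1 / length(.SENSE_CODONS), length(.SENSE_CODONS))
    names(p) <- .SENSE_CODONS
    p
  }

  site_tab <- vapply(unique(c(al$a, al$b)), .yn_sites, numeric(2),
                     kappa = kappa, pi = pi)
  S <- (sum(site_tab["s", al$a]) + sum(site_tab["s", al$b])) / 2
  N <- 3 * nc - S

  pair_key <- paste0(al$a, "|", al$b)
  pair_tab <- table(pair_key)
  uniq <- names(pair_tab)
  ua <- substring(uniq, 1, 3); ub <- substring(uniq, 5, 7)

  omega <- 1; converged <- FALSE
  dS <- NA_real_; dN <- NA_real_
  counts <- c(s_ts = 0, s_tv = 0, n_ts = 0, n_tv = 0)
  for (iter in seq_len(max_iter)) {
    counts[] <- 0
    for (k in seq_along(uniq)) {
      d <- .yn_differences(ua[k], ub[k], kappa, omega, pi)
      counts <- counts + d * as.numeric(pair_tab[k])
    }
    dS <- if (S > 0) .k80_distance(counts[["s_ts"]] / S, counts[["s_tv"]] / S)
          else NA_real_
    dN <- if (N > 0) .k80_distance(counts[["n_ts"]] / N, counts[["n_tv"]] / N)
          else NA_real_
    if (is.na(dS) || is.na(dN) || dS <= 0) break
    omega_new <- dN / dS
    if (abs(omega_new - omega) < tol) { omega <- omega_new; converged <- TRUE; break }
    omega <- omega_new
  }
  if (identical(al$a, al$b)) converged <- TRUE    # nothing to iterate
  .kaks_result("YN00", nc, S, N,
               Sd = counts[["s_ts"]] + counts[["s_tv"]],
               Nd = counts[["n_ts"]] + counts[["n_tv"]],
               ka = dN, ks = dS, kappa = kappa, converged = converged)
}

# ---- classification and commonality --------------------------------------

#' Selection class from a Ka/Ks ratio
#'
#' Ka/Ks below 0.5 indicates purifying selection, between 0.5 and 1 weak
#' positive selection, above 1 strong positive selection. Boundary values
#' (exactly 0.5 or 1) map to the lower class. Pairs with undefined ratio
#' or with Ks outside [ks_min, ks_max] are UNDEFINED.
#'
#' @param ratio Ka/Ks ratio (vectorised), or a `kaks_result`.
#' @param ks matching Ks values (used for the Ks admission window).
#' @param ks_min,ks_max Ks admission window (defaults 1e-6 and 3:
#'   near-zero Ks makes the ratio unstable, large Ks indicates
#'   saturation).
#' @return Character vector: PURIFYING, WEAK_POSITIVE, STRONG_POSITIVE or
#'   UNDEFINED.
#' @export
classify_selection <- function(ratio, ks = NULL, ks_min = 1e-6, ks_max = 3) {
  if (inherits(ratio, "kaks_result")) {
    ks <- ratio$Ks
    ratio <- ratio$ratio
  }
  out <- rep("UNDEFINED", length(ratio))
  ok <- !is.na(ratio)
  if (!is.null(ks)) ok <- ok & !is.na(ks) & ks > ks_min & ks <= ks_max
  out[ok & ratio <= 0.5] <- "PURIFYING"
  out[ok & ratio > 0.5 & ratio <= 1] <- "WEAK_POSITIVE"
  out[ok & ratio > 1] <- "STRONG_POSITIVE"
  out
}

#' Ka/Ks over a set of ortholog pairs
#'
#' @param pairs an `ortholog_pairs` object (or list of `ortholog_pair`).
#' @param method "YN00" (default, as used for the reported analyses) or
#'   "NG86".
#' @param ks_min,ks_max Ks admission window for classification.
#' @param ... passed to the estimator.
#' @return A data.frame of class `kaks_table`: species_pair, gene_a,
#'   gene_b, method, S, N, Sd, Nd, Ka, Ks, ratio, kappa, class.
#' @export
kaks_pairs <- function(pairs, method = c("YN00", "NG86"),
                       ks_min = 1e-6, ks_max = 3, ...) {
  method <- match.arg(method)
  alns <- if (inherits(pairs, "ortholog_pairs")) pairs$alignments else pairs
  est <- if (method == "YN00") yn00 else ng86
  rows <- lapply(alns, function(op) {
    r <- est(op, ...)
    data.frame(species_pair = r$species_pair, gene_a = r$gene_a,
               gene_b = r$gene_b, method = r$method,
               S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               Ka = r$Ka, Ks = r$Ks, ratio = r$ratio, kappa = r$kappa,
               class = classify_selection(r$ratio, r$Ks,
                                          ks_min = ks_min, ks_max = ks_max),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("kaks_table", "data.frame")
  out
}

#' @export
summary.kaks_table <- function(object, ...) {
  cat("Ka/Ks results (", object$method[1], "): ", nrow(object), " pairs\n",
      sep = "")
  cat("  mean Ka:", round(mean(object$Ka, na.rm = TRUE), 4),
      " mean Ks:", round(mean(object$Ks, na.rm = TRUE), 4),
      " mean Ka/Ks:", round(mean(object$ratio, na.rm = TRUE), 4), "\n")
  print(table(object$class))
  invisible(object)
}

#' Cross-pairing commonality of positively selected genes
#'
#' For each focal-species gene, lists the species pairings in which its
#' Ka/Ks exceeds 1, and counts genes per pairing combination (the cells
#' of a Venn diagram over pairings).
#'
#' @param results named list: pairing label -> `kaks_table` (focal-species
#'   gene ids in `gene_a`).
#' @return A list: `membership` (data.frame gene_a, pairings, n_pairings)
#'   and `cells` (named integer vector keyed by "&"-joined pairing
#'   combinations).
#' @export
positive_commonality <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  pos <- lapply(results, function(df) {
    unique(df$gene_a[!is.na(df$ratio) & df$ratio > 1])
  })
  genes <- sort(unique(unlist(pos)))
  if (!length(genes)) {
    return(list(membership = data.frame(gene_a = character(0),
                                        pairings = character(0),
                                        n_pairings = integer(0)),
                cells = integer(0)))
  }
  keys <- vapply(genes, function(g) {
    paste(sort(names(pos)[vapply(pos, function(s) g %in% s, logical(1))]),
          collapse = "&")
  }, character(1))
  cells <- table(keys)
  list(membership = data.frame(gene_a = genes, pairings = unname(keys),
                               n_pairings = lengths(strsplit(unname(keys), "&", fixed = TRUE)),
                               stringsAsFactors = FALSE),
       cells = stats::setNames(as.integer(cells), names(cells)))
}
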