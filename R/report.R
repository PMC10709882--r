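# Report assembly: summary percentages, CDS length histograms and the
# end-to-end pipeline driver.

#' Percentage with half-up rounding to two decimals
#'
#' @param part non-negative count.
#' @param whole positive count, at least `part`.
#' @return 100 * part / whole, rounded half-up to 2 decimals.
#' @export
percent <- function(part, whole) {
  stopifnot(length(part) == length(whole))
  if (any(whole <= 0)) stop("whole must be positive", call. = FALSE)
  if (any(part < 0) || any(part > whole)) {
    stop("part must lie in [0, whole]", call. = FALSE)
  }
  trunc(100 * part / whole * 100 + 0.5) / 100
}

#' CDS length-interval histogram
#'
#' Bins sequence lengths into half-open intervals `[k*bin, (k+1)*bin)`.
#'
#' @param records a `cds_set`, or a numeric vector of lengths in bp.
#' @param bin_bp bin width in bp (default 300).
#' @return A data.frame: interval, lower, upper, count, frequency
#'   (frequencies sum to 1).
#' @export
length_histogram <- function(records, bin_bp = 300L) {
  if (bin_bp <= 0) stop("bin_bp must be positive", call. = FALSE)
  lens <- if (is.data.frame(records)) nchar(records$seq) else as.numeric(records)
  if (!length(lens)) stop("no records", call. = FALSE)
  k <- lens %/% bin_bp
  tab <- table(k)
  lower <- as.integer(names(tab)) * bin_bp
  data.frame(interval = sprintf("[%d,%d)", lower, lower + bin_bp),
             lower = lower, upper = lower + bin_bp,
             count = as.integer(tab),
             frequency = as.integer(tab) / length(lens),
             stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative pipeline
#'
#' Executes CDS admission, per-species codon-usage profiles, optimal-codon
#' determination with the universal intersection, focal-vs-other RBH
#' orthology, Ka/Ks estimation with selection classes, and the
#' positive-selection commonality table. All stage outputs are returned;
#' when `out_dir` is given they are also written as TSV together with a
#' run log recording every threshold.
#'
#' @param species named list: species label -> `cds_set` or FASTA path.
#' @param focal label of the focal species for orthology/Ka-Ks (default:
#'   first species); set NULL to skip the orthology stages.
#' @param min_len_bp,cai_fraction,rscu_min,delta_min,w_floor codon-usage
#'   stage thresholds (see the stage functions).
#' @param min_identity,min_coverage,min_codons RBH floors.
#' @param method Ka/Ks estimator, "YN00" (default) or "NG86".
#' @param ks_min,ks_max Ks admission window for classification.
#' @param out_dir optional output directory for TSV reports.
#' @param seed seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @return A list of class `codonselect_run` with elements `filter`,
#'   `profiles`, `optimal`, `universal`, `orthologs`, `kaks`,
#'   `commonality`, `config`.
#' @export
run_pipeline <- function(species, focal = names(species)[1],
                         min_len_bp = 300L, cai_fraction = 0.10,
                         rscu_min = 1.0, delta_min = 0.08, w_floor = 0.01,
                         min_identity = 0.3, min_coverage = 0.5,
                         min_codons = 30L, method = c("YN00", "NG86"),
                         ks_min = 1e-6, ks_max = 3, out_dir = NULL,
                         seed = NA_integer_) {
  method <- match.arg(method)
  if (is.null(names(species)) || any(!nzchar(names(species)))) {
    stop("species must be a named list", call. = FALSE)
  }
  sets <- lapply(names(species), function(s) {
    x <- species[[s]]
    if (is.character(x)) {
      if (!file.exists(x)) stop("species FASTA not found: ", x, call. = FALSE)
      read_fasta(x, species = s)
    } else x
  })
  names(sets) <- names(species)

  filt <- lapply(sets, filter_cds, min_len_bp = min_len_bp)
  kept <- lapply(filt, `[[`, "kept")

  opt <- lapply(kept, find_optimal_codons, fraction = cai_fraction,
                rscu_min = rscu_min, delta_min = delta_min, w_floor = w_floor)
  univ <- if (length(opt) >= 2) {
    universal_optimal(lapply(opt, `[[`, "optimal"))
  } else character(0)

  profiles <- do.call(rbind, lapply(names(kept), function(s) {
    tabs <- lapply(kept[[s]]$seq, count_codons)
    names(tabs) <- kept[[s]]$gene_id
    w <- build_w_table(tabs[opt[[s]]$partition$high], w_floor = w_floor,
                       source_label = paste0(s, " high-CAI reference"))
    codon_usage(kept[[s]], w = w, optimal = opt[[s]]$optimal)
  }))

  orth <- list(); kk <- list(); common <- NULL
  if (!is.null(focal) && length(kept) >= 2) {
    others <- setdiff(names(kept), focal)
    for (s in others) {
      pr <- rbh_pairs(kept[[focal]], kept[[s]], min_identity = min_identity,
                      min_coverage = min_coverage, min_codons = min_codons)
      orth[[paste0(focal, ":", s)]] <- pr
      kk[[paste0(focal, ":", s)]] <- kaks_pairs(pr, method = method,
                                                ks_min = ks_min, ks_max = ks_max)
    }
    if (length(kk)) common <- positive_commonality(kk)
  }

  config <- list(min_len_bp = min_len_bp, cai_fraction = cai_fraction,
                 rscu_min = rscu_min, delta_min = delta_min,
                 w_floor = w_floor, min_identity = min_identity,
                 min_coverage = min_coverage, min_codons = min_codons,
                 method = method, ks_min = ks_min, ks_max = ks_max,
                 focal = focal, seed = seed)
  out <- structure(list(filter = filt, profiles = profiles, optimal = opt,
                        universal = univ, orthologs = orth, kaks = kk,
                        commonality = common, config = config),
                   class = "codonselect_run")
  if (!is.null(out_dir)) .write_run(out, out_dir)
  out
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(run$filter)) {
    write_filter_report(run$filter[[s]],
                        file.path(out_dir, paste0("filter_", s, ".tsv")))
    .write_tsv(run$optimal[[s]]$calls,
               file.path(out_dir, paste0("optimal_", s, ".tsv")))
  }
  .write_tsv(run$profiles, file.path(out_dir, "profiles.tsv"))
  .write_tsv(data.frame(codon = run$universal, stringsAsFactors = FALSE),
             file.path(out_dir, "universal_optimal.tsv"))
  for (p in names(run$kaks)) {
    .write_tsv(run$kaks[[p]],
               file.path(out_dir, paste0("kaks_", gsub(":", "_vs_", p), ".tsv")))
    .write_tsv(run$orthologs[[p]]$pairs,
               file.path(out_dir, paste0("orthologs_", gsub(":", "_vs_", p), ".tsv")))
  }
  if (!is.null(run$commonality)) {
    .write_tsv(run$commonality$membership,
               file.path(out_dir, "positive_commonality.tsv"))
    .write_tsv(data.frame(cell = names(run$commonality$cells),
                          count = as.integer(run$commonality$cells)),
               file.path(out_dir, "venn_cells.tsv"))
  }
  log <- c(sprintf("codonselect %s", as.character(utils::packageVersion("codonselect"))),
           vapply(names(run$config), function(k) {
             sprintf("%s = %s", k, paste(format(run$config[[k]]), collapse = ","))
           }, character(1)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.codonselect_run <- function(x, ...) {
  cat("codonselect pipeline run\n")
  for (s in names(x$filter)) {
    cat(sprintf("  %s: %d CDS kept, %d optimal codons\n", s,
                nrow(x$filter[[s]]$kept), length(x$optimal[[s]]$optimal)))
  }
  if (length(x$universal)) {
    cat("  universal optimal codons:", paste(x$universal, collapse = " "), "\n")
  }
  for (p in names(x$kaks)) {
    cat(sprintf("  %s: %d ortholog pairs, mean Ka/Ks %.3f\n", p,
                nrow(x$kaks[[p]]),
                mean(x$kaks[[p]]$ratio, na.rm = TRUE)))
  }
  invisible(x)
}
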