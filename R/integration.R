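#' Assign genes to compartment switch classes
#'
#' Each gene is assigned the switch class of the bin containing its TSS
#' (half-open bins: a TSS exactly on a bin start belongs to that bin).
#' Genes in NA bins are flagged unassigned; genes off the layout are
#' skipped and counted.
#'
#' @param genes gene table (see [read_genes()]).
#' @param switches a [classify_switches()] table.
#' @param bins the [make_bins()] table the switch table was computed on.
#' @return The gene table with added columns `bin` and `switch_class`
#'   (NA = unassigned); attribute `n_skipped` counts off-layout genes.
#' @export
assign_gene_compartments <- function(genes, switches, bins) {
  stopifnot(inherits(switches, "switch_table"))
  idx <- locate_bins(bins, genes$chrom, genes$tss)
  n_skipped <- sum(is.na(idx))
  if (n_skipped > 0) {
    warning(sprintf("%d gene(s) outside the genome layout skipped", n_skipped))
  }
  out <- genes
  out$bin <- idx
  out$switch_class <- NA_character_
  ok <- !is.na(idx)
  out$switch_class[ok] <- switches$class[idx[ok]]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Log2 fold change of expression between conditions
#'
#' log2((fpkm2 + p) / (fpkm1 + p)); condition 2 over condition 1, so a
#' positive value is upregulation in condition 2. The pseudocount keeps
#' zero-FPKM genes representable.
#'
#' @param fpkm1,fpkm2 non-negative expression vectors.
#' @param pseudocount positive offset (default 1).
#' @return Numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(fpkm1, fpkm2, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(fpkm1 < 0, na.rm = TRUE) || any(fpkm2 < 0, na.rm = TRUE)) {
    stop("FPKM values must be non-negative")
  }
  log2((fpkm2 + pseudocount) / (fpkm1 + pseudocount))
}

#' Expression summaries per switch class
#'
#' Summarises per-gene log2 fold changes within each compartment switch
#' class, and flags whether the qualitative expectation holds that genes
#' in A-to-B bins are downregulated (median < 0) and genes in B-to-A bins
#' upregulated (median > 0).
#'
#' @param genes gene table with `switch_class` (from
#'   [assign_gene_compartments()]) and `lfc` columns, or FPKM columns from
#'   which `lfc` is computed with [log2_fold_change()].
#' @param pseudocount passed to [log2_fold_change()] when `lfc` is absent.
#' @return List with `summary` (data frame `class, n, q25, median, q75`)
#'   and `direction_consistent` (logical: median(AB) < 0 < median(BA)).
#' @export
expression_by_switch_class <- function(genes, pseudocount = 1) {
  if (!"lfc" %in% names(genes)) {
    genes$lfc <- log2_fold_change(genes$fpkm_cond1, genes$fpkm_cond2,
                                  pseudocount)
  }
  classes <- c("AA", "AB", "BA", "BB")
  rows <- lapply(classes, function(k) {
    x <- genes$lfc[!is.na(genes$switch_class) & genes$switch_class == k]
    if (length(x) == 0) {
      data.frame(class = k, n = 0L, q25 = NA_real_, median = NA_real_,
                 q75 = NA_real_)
    } else {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(class = k, n = length(x), q25 = q[1], median = q[2],
                 q75 = q[3])
    }
  })
  tab <- do.call(rbind, rows)
  med <- stats::setNames(tab$median, tab$class)
  dc <- !is.na(med["AB"]) && !is.na(med["BA"]) &&
    med["AB"] < 0 && med["BA"] > 0
  list(summary = tab, direction_consistent = unname(dc))
}

#' Flag differential expression by fold-change (and optional q-value)
#'
#' Strict thresholds: `up` requires lfc > lfc_threshold, `down` requires
#' lfc < -lfc_threshold; when q-values are supplied the flag additionally
#' requires q < q_threshold. No differential test is performed here.
#'
#' @param lfc per-gene log2 fold changes.
#' @param q optional per-gene q-values in `[0, 1]`.
#' @param lfc_threshold fold-change threshold (default 1).
#' @param q_threshold significance threshold (default 0.05).
#' @return Character vector in `{"up", "down", "ns"}`.
#' @export
de_flag <- function(lfc, q = NULL, lfc_threshold = 1, q_threshold = 0.05) {
  if (lfc_threshold <= 0 || q_threshold <= 0) stop("thresholds must be positive")
  if (!is.null(q)) {
    if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q-values must lie in [0, 1]")
  }
  flag <- ifelse(lfc > lfc_threshold, "up",
                 ifelse(lfc < -lfc_threshold, "down", "ns"))
  if (!is.null(q)) flag[!(q < q_threshold)] <- "ns"
  flag
}

#' Peak coverage per bin
#'
#' Base-pair coverage of each bin by the peak set (interval intersection;
#' overlapping peaks are NOT flattened, so stacked peaks count multiply —
#' use `weight_by_signal` for signal-weighted coverage).
#'
#' @param peaks peak table (see [read_peaks()]).
#' @param bins a [make_bins()] table.
#' @param weight_by_signal multiply each peak's contribution by its
#'   signalValue column (default FALSE).
#' @return Numeric per-bin coverage vector (bp, or signal-weighted bp).
#' @export
peak_coverage <- function(peaks, bins, weight_by_signal = FALSE) {
  if (nrow(peaks) == 0) stop("empty peak set")
  gb <- GenomicRanges::GRanges(bins$chrom,
                               IRanges::IRanges(bins$start + 1, bins$end))
  gp <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  hits <- GenomicRanges::findOverlaps(gp, gb)
  ov <- IRanges::pintersect(gp[S4Vectors::queryHits(hits)],
                            gb[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  if (weight_by_signal) w <- w * peaks$signal[S4Vectors::queryHits(hits)]
  cov <- numeric(nrow(bins))
  tab <- tapply(w, S4Vectors::subjectHits(hits), sum)
  cov[as.integer(names(tab))] <- as.numeric(tab)
  cov
}

#' Association of peak coverage with A/B compartments
#'
#' Compares per-bin peak base-pair coverage between A and B bins with a
#' two-sided Mann-Whitney rank-sum test.
#'
#' @param peaks peak table (see [read_peaks()]).
#' @param profile a `compartment_profile`.
#' @param bins the [make_bins()] table the profile was computed on.
#' @param weight_by_signal see [peak_coverage()].
#' @return List with `mean_coverage_A`, `mean_coverage_B`, `rank_sum_p`,
#'   `direction` (`"A>B"`, `"B>A"` or `"equal"`), `n_A`, `n_B`. When the
#'   profile has only one label the test is skipped (`rank_sum_p = NA`)
#'   with a note.
#' @export
peak_signal_by_compartment <- function(peaks, profile, bins,
                                       weight_by_signal = FALSE) {
  stopifnot(inherits(profile, "compartment_profile"))
  cov <- peak_coverage(peaks, bins, weight_by_signal)
  a <- cov[!is.na(profile$label) & profile$label == "A"]
  b <- cov[!is.na(profile$label) & profile$label == "B"]
  mean_a <- if (length(a)) mean(a) else NA_real_
  mean_b <- if (length(b)) mean(b) else NA_real_
  if (length(a) == 0 || length(b) == 0) {
    message("only one compartment label present: rank-sum test skipped")
    p <- NA_real_
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  direction <- if (is.na(mean_a) || is.na(mean_b) || mean_a == mean_b) "equal"
               else if (mean_a > mean_b) "A>B" else "B>A"
  list(mean_coverage_A = mean_a, mean_coverage_B = mean_b,
       rank_sum_p = p, direction = direction,
       n_A = length(a), n_B = length(b))
}
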