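#' Run the two-condition differential architecture pipeline
#'
#' End-to-end comparison of two conditions: low-coverage masking, ICE
#' balancing, per-chromosome compartment calling and switch
#' classification, insulation-score boundary calling with cross-condition
#' matching and strength-change classification, TAD construction, and
#' (when genes/peaks are supplied) integration of expression fold changes
#' and peak coverage with the compartment calls.
#'
#' @param matrix1,matrix2 raw [contact_matrix()] objects for condition 1
#'   (reference) and condition 2, on identical bin tables.
#' @param genes optional gene table (see [read_genes()]); also the default
#'   PC1 orientation reference (gene density).
#' @param peaks optional peak table (see [read_peaks()]).
#' @param reference optional explicit per-bin orientation track;
#'   overrides gene density.
#' @param params list of stage parameters; see [pipeline_params()].
#' @param out_dir optional directory: all stage outputs (bedGraph/BED/TSV
#'   tracks and the JSON report) are written there.
#' @return A `run_report` list with every summary the comparison
#'   produces; regenerating with identical inputs and parameters yields
#'   identical numbers.
#' @export
run_differential_pipeline <- function(matrix1, matrix2, genes = NULL,
                                      peaks = NULL, reference = NULL,
                                      params = pipeline_params(),
                                      out_dir = NULL) {
  if (missing(matrix1) || missing(matrix2) || is.null(matrix1) ||
      is.null(matrix2)) {
    stop("two conditions required")
  }
  stopifnot(inherits(matrix1, "contact_matrix"),
            inherits(matrix2, "contact_matrix"))
  if (!identical(dim(matrix1$values), dim(matrix2$values))) {
    stop("stage compartments: condition matrices have different dimensions")
  }
  bins <- matrix1$bins
  if (is.null(reference)) {
    if (!is.null(genes)) {
      reference <- gene_density_track(genes, bins)
    } else if (!is.null(peaks)) {
      reference <- peak_coverage(peaks, bins)
    } else {
      stop("stage compartments: an orientation reference is required ",
           "(genes, peaks, or an explicit track)")
    }
  }

  prof1 <- compartment_profile(matrix1, reference, params$mask_min_fraction)
  prof2 <- compartment_profile(matrix2, reference, params$mask_min_fraction)
  switches <- classify_switches(prof1, prof2)
  fracs <- switch_fractions(switches)

  chroms <- unique(bins$chrom)
  layout <- attr(bins, "layout")
  bset1 <- bset2 <- list()
  tads1 <- tads2 <- list()
  for (cn in chroms) {
    m1 <- mask_low_coverage(chrom_slice(matrix1, cn), params$mask_min_fraction)
    m2 <- mask_low_coverage(chrom_slice(matrix2, cn), params$mask_min_fraction)
    b1 <- ice_balance(m1)$matrix
    b2 <- ice_balance(m2)$matrix
    s1 <- call_boundaries(b1, params$window_bp, params$search_range_bp,
                          params$flank_bp, params$min_strength)
    s2 <- call_boundaries(b2, params$window_bp, params$search_range_bp,
                          params$flank_bp, params$min_strength)
    bset1[[cn]] <- s1
    bset2[[cn]] <- s2
    len <- layout$length[layout$chrom == cn]
    tads1[[cn]] <- boundaries_to_tads(s1, len, params$min_tad_bp)
    tads2[[cn]] <- boundaries_to_tads(s2, len, params$min_tad_bp)
  }
  set1 <- rbind_boundary_sets(bset1)
  set2 <- rbind_boundary_sets(bset2)
  cmp <- match_boundaries(set1, set2, params$slack_bins)
  changes <- if (nrow(cmp$pairs) > 0) {
    classify_boundary_changes(cmp, params$log2_ratio_threshold)
  } else NULL
  alltads1 <- do.call(rbind, tads1)
  alltads2 <- do.call(rbind, tads2)
  class(alltads1) <- class(alltads2) <- c("tad_set", "data.frame")
  tsum <- tad_summary(alltads1, alltads2)

  expr <- NULL
  if (!is.null(genes)) {
    g <- assign_gene_compartments(genes, switches, bins)
    g$lfc <- log2_fold_change(g$fpkm_cond1, g$fpkm_cond2, params$pseudocount)
    expr <- expression_by_switch_class(g, params$pseudocount)
    expr$genes <- g
  }
  peak_assoc <- if (!is.null(peaks)) {
    peak_signal_by_compartment(peaks, prof1, bins)
  } else NULL

  report <- list(
    params = params,
    n_bins = nrow(bins),
    switch_fractions = fracs,
    switch_counts = as.list(attr(switches, "counts")),
    n_boundaries = list(cond1 = nrow(set1), cond2 = nrow(set2)),
    boundary_changes = if (is.null(changes)) NULL else
      changes[c("frac_weakened", "frac_strengthened", "frac_stable",
                "n_pairs", "n_excluded")],
    tad_summary = tsum,
    expression_by_class = if (is.null(expr)) NULL else
      expr[c("summary", "direction_consistent")],
    peak_association = peak_assoc)

  result <- list(report = report, profile1 = prof1, profile2 = prof2,
                 switches = switches, boundaries1 = set1, boundaries2 = set2,
                 comparison = cmp, changes = changes,
                 tads1 = alltads1, tads2 = alltads2,
                 expression = expr, peak_association = peak_assoc)
  class(result) <- "run_result"

  if (!is.null(out_dir)) write_pipeline_outputs(result, bins, out_dir)
  result
}

#' Default pipeline parameters
#'
#' Every default that influences a reported number, echoed verbatim into
#' the run report.
#'
#' @param mask_min_fraction low-coverage masking quantile. The pipeline
#'   default is 0 (mask only zero-marginal bins): a fixed quantile trim
#'   removes the most insulated boundary bins on clean data; raise it
#'   (e.g. 0.02) for real libraries with technical dropout.
#' @param window_bp insulation window half-width.
#' @param search_range_bp boundary candidate search range.
#' @param flank_bp delta/strength flank.
#' @param min_strength boundary retention threshold (log2 units).
#' @param min_tad_bp minimum inter-boundary distance for a TAD.
#' @param slack_bins boundary matching dilation.
#' @param log2_ratio_threshold weakened/strengthened threshold.
#' @param pseudocount FPKM fold-change pseudocount.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(mask_min_fraction = 0, window_bp = 200000,
                            search_range_bp = 200000, flank_bp = 100000,
                            min_strength = 0.1, min_tad_bp = 400000,
                            slack_bins = 1,
                            log2_ratio_threshold = log2(1.25),
                            pseudocount = 1) {
  list(mask_min_fraction = mask_min_fraction, window_bp = window_bp,
       search_range_bp = search_range_bp, flank_bp = flank_bp,
       min_strength = min_strength, min_tad_bp = min_tad_bp,
       slack_bins = slack_bins,
       log2_ratio_threshold = log2_ratio_threshold,
       pseudocount = pseudocount)
}

rbind_boundary_sets <- function(sets) {
  sets <- Filter(function(s) !is.null(s), sets)
  out <- do.call(rbind, lapply(sets, function(s) as.data.frame(s)))
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), bin = integer(0),
                      start = numeric(0), end = numeric(0),
                      score = numeric(0), mean_left = numeric(0),
                      mean_right = numeric(0), delta = numeric(0),
                      strength = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "bin_size") <- if (length(sets) > 0) attr(sets[[1]], "bin_size")
                           else NA_real_
  class(out) <- c("boundary_set", "data.frame")
  out
}

write_pipeline_outputs <- function(result, bins, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_bedgraph(bins, result$profile1$pc1, file.path(out_dir, "pc1_cond1.bedgraph"))
  write_bedgraph(bins, result$profile2$pc1, file.path(out_dir, "pc1_cond2.bedgraph"))
  sw <- result$switches
  keep <- !is.na(sw$class)
  utils::write.table(
    data.frame(sw$chrom[keep], as.integer(sw$start[keep]),
               as.integer(sw$end[keep]), sw$class[keep]),
    file.path(out_dir, "switches.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (cond in 1:2) {
    b <- result[[paste0("boundaries", cond)]]
    utils::write.table(
      data.frame(b$chrom, as.integer(b$start), as.integer(b$end),
                 sprintf("boundary%d", seq_len(nrow(b))),
                 pmin(pmax(as.integer(round(b$strength * 1000)), 0), 1000),
                 "."),
      file.path(out_dir, sprintf("boundaries_cond%d.bed", cond)),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(b, file.path(out_dir,
                                    sprintf("boundaries_cond%d.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    td <- result[[paste0("tads", cond)]]
    utils::write.table(
      data.frame(td$chrom, as.integer(td$start), as.integer(td$end)),
      file.path(out_dir, sprintf("tads_cond%d.bed", cond)),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(result$changes)) {
    utils::write.table(result$changes$pairs,
                       file.path(out_dir, "boundary_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$expression)) {
    utils::write.table(result$expression$genes,
                       file.path(out_dir, "genes_with_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_run_report(result$report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Write the machine-readable run report
#'
#' Deterministic serialization: identical inputs and parameters yield a
#' byte-identical file. Percentages are carried as proportions; the
#' human-readable summary prints them to two decimals.
#'
#' @param report the `report` field of a [run_differential_pipeline()]
#'   result.
#' @param path output JSON path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.run_result <- function(x, ...) {
  f <- x$report$switch_fractions
  cat("Differential 3D-genome comparison\n")
  cat(sprintf("  bins: %d (eligible in both conditions: %d)\n",
              x$report$n_bins, f$eligible_bins))
  cat(sprintf("  compartment switching: %.2f%% of eligible bins (A->B %.2f%%, B->A %.2f%%)\n",
              100 * f$frac_switched, 100 * f$frac_AB, 100 * f$frac_BA))
  cat(sprintf("  boundaries: %d (cond1) / %d (cond2)\n",
              x$report$n_boundaries$cond1, x$report$n_boundaries$cond2))
  if (!is.null(x$report$boundary_changes)) {
    bc <- x$report$boundary_changes
    cat(sprintf("  boundary strength: %.2f%% weakened, %.2f%% strengthened, %.2f%% stable (%d pairs)\n",
                100 * bc$frac_weakened, 100 * bc$frac_strengthened,
                100 * bc$frac_stable, bc$n_pairs))
  }
  if (!is.null(x$report$expression_by_class)) {
    s <- x$report$expression_by_class$summary
    med <- stats::setNames(s$median, s$class)
    cat(sprintf("  expression median lfc: AB %.3f, BA %.3f (direction consistent: %s)\n",
                med["AB"], med["BA"],
                x$report$expression_by_class$direction_consistent))
  }
  if (!is.null(x$report$peak_association)) {
    pa <- x$report$peak_association
    cat(sprintf("  peak coverage: A %.1f bp/bin vs B %.1f bp/bin, rank-sum p = %.3g\n",
                pa$mean_coverage_A, pa$mean_coverage_B, pa$rank_sum_p))
  }
  invisible(x)
}
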