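#' Pearson correlation matrix of an O/E contact matrix
#'
#' `corr[i, j]` is the Pearson correlation of rows i and j over columns
#' where both are defined; the diagonal of the input is already NA after
#' [observed_over_expected()], so self-contacts never enter the
#' computation. Rows with zero variance (or fewer than 3 shared columns
#' with any partner) become NA and are added to the mask.
#'
#' @param oe an `oe` [contact_matrix()].
#' @return A `correlation` [contact_matrix()] with unit diagonal on
#'   unmasked bins.
#' @export
pearson_correlation <- function(oe) {
  stopifnot(inherits(oe, "contact_matrix"))
  vals <- oe$values
  diag(vals) <- NA  # self-contacts never inform row similarity
  corr <- suppressWarnings(stats::cor(t(vals), use = "pairwise.complete.obs"))
  corr <- (corr + t(corr)) / 2
  bad <- which(apply(corr, 1, function(r) all(is.na(r))))
  mask <- sort(union(oe$mask, bad))
  good <- setdiff(seq_len(nrow(corr)), mask)
  corr[cbind(good, good)] <- 1
  corr[mask, ] <- NA
  corr[, mask] <- NA
  contact_matrix(corr, oe$bins, kind = "correlation", mask = mask)
}

#' Leading eigenvector of a correlation matrix
#'
#' Power iteration for the eigenvector of the largest-magnitude eigenvalue,
#' run on the unmasked submatrix and re-expanded with NA at masked bins.
#' The sign of the returned vector is arbitrary; anchor it with
#' [orient_pc1()] before calling compartments.
#'
#' @param corr a `correlation` [contact_matrix()] (any symmetric
#'   [contact_matrix()] is accepted).
#' @param tol convergence tolerance on the iterate (default 1e-12).
#' @param max_iter iteration cap (default 10000).
#' @return Numeric vector, unit norm over unmasked bins, NA at masked
#'   bins; attribute `eigenvalue` holds the leading eigenvalue and
#'   attribute `degenerate` flags a (near-)tied spectrum with no dominant
#'   structure.
#' @export
leading_eigenvector <- function(corr, tol = 1e-12, max_iter = 10000) {
  stopifnot(inherits(corr, "contact_matrix"))
  keep <- unmasked_idx(corr)
  if (length(keep) < 2) stop("fewer than 2 unmasked bins")
  A <- corr$values[keep, keep, drop = FALSE]
  if (any(is.na(A))) stop("unmasked submatrix contains NA")
  n <- nrow(A)
  # deterministic start vector with nonzero overlap with any eigenvector
  v <- sin(seq_len(n) * 0.7) + 0.1
  v <- v / sqrt(sum(v^2))
  lambda <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- A %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("eigensolver hit the null space: degenerate input")
    w <- w / nw
    # align to previous iterate so sign flips (negative eigenvalue) converge
    if (sum(w * v) < 0) w <- -w
    delta <- max(abs(w - v))
    v <- as.numeric(w)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  lambda <- sum(v * (A %*% v))
  # estimate the runner-up eigenvalue by deflation to flag degenerate spectra
  B <- A - lambda * outer(v, v)
  u <- cos(seq_len(n) * 0.3) + 0.1
  u <- u / sqrt(sum(u^2))
  for (it2 in seq_len(50)) {
    u2 <- B %*% u
    n2 <- sqrt(sum(u2^2))
    if (n2 == 0) break
    u <- as.numeric(u2 / n2)
  }
  lambda2 <- sum(u * (B %*% u))
  degenerate <- !converged || abs(lambda2) >= (1 - 1e-6) * abs(lambda)
  if (degenerate) {
    warning("no dominant structure: leading eigenvalue is not separated")
  }
  out <- rep(NA_real_, n_bins(corr))
  out[keep] <- v
  attr(out, "eigenvalue") <- lambda
  attr(out, "degenerate") <- degenerate
  out
}

#' Orient PC1 against a reference track
#'
#' The eigenvector sign is arbitrary; by convention compartment A (positive
#' PC1) is the gene-dense / active side. The vector is flipped when its
#' Pearson correlation with the reference is negative and left unchanged
#' otherwise, so the operation is idempotent; zero correlation leaves it
#' unchanged with a warning.
#'
#' @param pc1 per-bin score from [leading_eigenvector()].
#' @param reference per-bin scalar track on the same bins (e.g. gene
#'   density from [gene_density_track()], or active-mark peak coverage).
#' @return The oriented pc1 vector; attribute `flipped` records the
#'   decision.
#' @export
orient_pc1 <- function(pc1, reference) {
  if (length(reference) != length(pc1)) {
    stop("reference track length does not match pc1")
  }
  use <- !is.na(pc1) & !is.na(reference)
  if (!any(use)) stop("cannot orient: all-NA reference over defined pc1")
  r <- suppressWarnings(stats::cor(pc1[use], reference[use]))
  flipped <- FALSE
  if (is.na(r) || r == 0) {
    warning("orientation reference uncorrelated with pc1; sign left unchanged")
  } else if (r < 0) {
    attrs <- attributes(pc1)
    pc1 <- -pc1
    attributes(pc1) <- attrs
    flipped <- TRUE
  }
  attr(pc1, "flipped") <- flipped
  pc1
}

#' Per-bin gene density track
#'
#' Number of gene TSSs per bin; the default PC1 orientation reference.
#'
#' @param genes gene table (see [read_genes()]).
#' @param bins a [make_bins()] table.
#' @return Numeric vector of TSS counts per bin.
#' @export
gene_density_track <- function(genes, bins) {
  idx <- locate_bins(bins, genes$chrom, genes$tss)
  tabulate(idx[!is.na(idx)], nbins = nrow(bins))
}

#' Call A/B compartments from an oriented PC1 vector
#'
#' Bins with PC1 > 0 are compartment A, bins with PC1 < 0 compartment B;
#' exactly-zero or undefined PC1 gives NA (the strict inequalities leave 0
#' unassigned).
#'
#' @param pc1 oriented per-bin PC1 scores.
#' @param bins a [make_bins()] table.
#' @param orientation_reference name of the track used for sign fixing
#'   (recorded, not used).
#' @return Object of class `compartment_profile`: data frame with columns
#'   `chrom, start, end, pc1, label`.
#' @export
call_compartments <- function(pc1, bins, orientation_reference = "gene_density") {
  stopifnot(length(pc1) == nrow(bins))
  label <- rep(NA_character_, length(pc1))
  label[!is.na(pc1) & pc1 > 0] <- "A"
  label[!is.na(pc1) & pc1 < 0] <- "B"
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    pc1 = as.numeric(pc1), label = label,
                    stringsAsFactors = FALSE)
  attr(out, "bin_size") <- bin_size_of(bins)
  attr(out, "orientation_reference") <- orientation_reference
  class(out) <- c("compartment_profile", "data.frame")
  out
}

#' Full compartment call for one condition
#'
#' Fixed pipeline raw -> ICE -> O/E -> Pearson correlation -> leading
#' eigenvector -> orientation -> A/B labels, run per chromosome.
#'
#' @param matrix a raw [contact_matrix()] (single- or multi-chromosome).
#' @param reference per-bin orientation track over the full bin table.
#' @param min_fraction low-coverage masking quantile (see
#'   [mask_low_coverage()]).
#' @return A `compartment_profile` over all bins.
#' @export
compartment_profile <- function(matrix, reference, min_fraction = 0.02) {
  bins <- matrix$bins
  stopifnot(length(reference) == nrow(bins))
  pc1 <- rep(NA_real_, nrow(bins))
  for (cn in unique(bins$chrom)) {
    sel <- which(bins$chrom == cn)
    cm <- chrom_slice(matrix, cn)
    cm <- mask_low_coverage(cm, min_fraction)
    bal <- ice_balance(cm)$matrix
    oe <- observed_over_expected(bal)
    corr <- pearson_correlation(oe)
    v <- leading_eigenvector(corr)
    v <- orient_pc1(v, reference[sel])
    pc1[sel] <- v
  }
  call_compartments(pc1, bins)
}

#' Classify per-bin compartment switches between two conditions
#'
#' Class AB means compartment A in condition 1 and B in condition 2
#' (condition order matters); NA if either label is NA. Only sign changes
#' of PC1 (AB and BA) count as differential compartments.
#'
#' @param p1,p2 `compartment_profile`s over identical bins.
#' @return Object of class `switch_table`: data frame with columns
#'   `chrom, start, end, label1, label2, class`; attributes `counts`
#'   (named per-class counts) and `eligible_bins` (bins non-NA in both).
#' @export
classify_switches <- function(p1, p2) {
  stopifnot(inherits(p1, "compartment_profile"),
            inherits(p2, "compartment_profile"))
  if (!identical(p1[c("chrom", "start", "end")], p2[c("chrom", "start", "end")])) {
    stop("compartment profiles are on different bin tables")
  }
  cls <- rep(NA_character_, nrow(p1))
  ok <- !is.na(p1$label) & !is.na(p2$label)
  cls[ok] <- paste0(p1$label[ok], p2$label[ok])
  out <- data.frame(chrom = p1$chrom, start = p1$start, end = p1$end,
                    label1 = p1$label, label2 = p2$label, class = cls,
                    stringsAsFactors = FALSE)
  counts <- vapply(c("AA", "AB", "BA", "BB"),
                   function(k) sum(cls == k, na.rm = TRUE), numeric(1))
  counts <- c(counts, "NA" = sum(!ok))
  attr(out, "counts") <- counts
  attr(out, "eligible_bins") <- sum(ok)
  attr(out, "bin_size") <- attr(p1, "bin_size")
  class(out) <- c("switch_table", "data.frame")
  out
}

#' Genome fractions of compartment switching
#'
#' Fractions are over eligible bins (labelled in both conditions); the
#' fraction over all bins, with NA bins in the denominator, is reported
#' alongside since published denominators are often unstated.
#'
#' @param table a [classify_switches()] result.
#' @return List with `frac_switched`, `frac_AB`, `frac_BA` (proportions of
#'   eligible bins), `eligible_bins`, `total_bins`, and
#'   `frac_switched_total` (denominator = all bins).
#' @export
switch_fractions <- function(table) {
  stopifnot(inherits(table, "switch_table"))
  counts <- attr(table, "counts")
  elig <- attr(table, "eligible_bins")
  if (elig == 0) stop("no eligible bins: cannot compute switch fractions")
  list(frac_AB = unname(counts["AB"] / elig),
       frac_BA = unname(counts["BA"] / elig),
       frac_switched = unname((counts["AB"] + counts["BA"]) / elig),
       eligible_bins = elig,
       total_bins = nrow(table),
       frac_switched_total = unname((counts["AB"] + counts["BA"]) / nrow(table)))
}
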