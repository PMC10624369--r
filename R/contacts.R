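#' Construct a contact matrix object
#'
#' A symmetric, non-negative bin-by-bin matrix tied to a bin table, with a
#' mask of excluded bins. `kind` records the processing stage: `raw`
#' (integer counts), `balanced` (ICE-corrected), `oe` (observed/expected)
#' or `correlation`.
#'
#' @param values symmetric numeric matrix, one row/column per bin.
#' @param bins a [make_bins()] table (or a single-chromosome slice) whose
#'   row count matches `values`.
#' @param kind one of `"raw"`, `"balanced"`, `"oe"`, `"correlation"`.
#' @param mask integer vector of masked (excluded) bin indices, relative to
#'   the rows of `values`.
#' @return An object of class `contact_matrix` with fields `values`,
#'   `bins`, `kind`, `mask`.
#' @export
contact_matrix <- function(values, bins, kind = "raw", mask = integer(0)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (!inherits(bins, "bin_table")) stop("bins must be a bin_table")
  if (nrow(values) != nrow(bins)) stop("matrix dimension does not match bin table")
  kind <- match.arg(kind, c("raw", "balanced", "oe", "correlation"))
  dif <- abs(values - t(values))
  if (any(dif[!is.na(dif)] > 1e-8 * max(1, max(abs(values), na.rm = TRUE)))) {
    stop("matrix not symmetric")
  }
  keep <- values[!is.na(values)]
  if (kind %in% c("raw", "balanced") && any(keep < 0)) {
    stop("raw/balanced contact matrices must be non-negative")
  }
  if (kind == "raw" && any(abs(keep - round(keep)) > 1e-9)) {
    stop("raw contact matrices must hold integer counts")
  }
  structure(list(values = unname(values), bins = bins, kind = kind,
                 mask = sort(unique(as.integer(mask)))),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix [%s]: %d x %d bins, %d masked, total %s\n",
              x$kind, nrow(x$values), ncol(x$values), length(x$mask),
              format(sum(x$values, na.rm = TRUE), digits = 6)))
  invisible(x)
}

n_bins <- function(m) nrow(m$values)

unmasked_idx <- function(m) setdiff(seq_len(n_bins(m)), m$mask)

#' Bin a stream of contact pairs into a raw contact matrix
#'
#' Each accepted pair increments one cell and its mirror, so the sum of the
#' upper triangle plus the diagonal equals the number of accepted pairs.
#'
#' @param pairs data frame with columns `chromA`, `posA`, `chromB`, `posB`
#'   (0-based positions), e.g. from [read_pairs()].
#' @param bins a [make_bins()] table.
#' @param cis_only drop inter-chromosomal pairs (default TRUE; all
#'   compartment and TAD analyses are cis).
#' @return A raw [contact_matrix()]; attributes `n_accepted`, `n_skipped`
#'   count kept and dropped pairs.
#' @export
bin_pairs <- function(pairs, bins, cis_only = TRUE) {
  stopifnot(is.data.frame(pairs),
            all(c("chromA", "posA", "chromB", "posB") %in% names(pairs)))
  nb <- nrow(bins)
  mat <- matrix(0, nb, nb)
  skipped <- 0L
  if (nrow(pairs) > 0L) {
    i <- locate_bins(bins, pairs$chromA, pairs$posA)
    j <- locate_bins(bins, pairs$chromB, pairs$posB)
    drop <- is.na(i) | is.na(j)
    if (cis_only) drop <- drop | (pairs$chromA != pairs$chromB)
    skipped <- sum(drop)
    if (skipped > 0L) {
      warning(sprintf("%d pair(s) skipped (off-layout or trans)", skipped))
    }
    i <- i[!drop]; j <- j[!drop]
    lo <- pmin(i, j); hi <- pmax(i, j)
    if (length(lo) > 0L) {
      tab <- table(lo + (hi - 1) * nb)
      cell <- as.integer(names(tab))
      mat[cell] <- as.numeric(tab)
      mat <- mat + t(mat)
      diag(mat) <- diag(mat) / 2
    }
  }
  out <- contact_matrix(mat, bins, kind = "raw")
  attr(out, "n_accepted") <- nrow(pairs) - skipped
  attr(out, "n_skipped") <- as.integer(skipped)
  out
}

#' Mask low-coverage bins
#'
#' Bins whose marginal (row) sum is zero, or below the `min_fraction`
#' quantile of the nonzero marginals, are added to the mask. Values are not
#' modified.
#'
#' @param matrix a [contact_matrix()].
#' @param min_fraction quantile of nonzero marginals below which bins are
#'   masked; in `[0, 1)`. Default 0.02, a conventional low-coverage filter.
#' @return The matrix with an updated mask.
#' @export
mask_low_coverage <- function(matrix, min_fraction = 0.02) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (min_fraction < 0 || min_fraction >= 1) {
    stop("min_fraction must be in [0, 1)")
  }
  marg <- rowSums(matrix$values, na.rm = TRUE)
  nz <- marg[marg > 0]
  cut <- if (length(nz) > 0 && min_fraction > 0) {
    stats::quantile(nz, min_fraction, names = FALSE)
  } else {
    0
  }
  newmask <- which(marg == 0 | marg < cut)
  mask <- sort(union(matrix$mask, newmask))
  if (length(mask) >= n_bins(matrix)) stop("matrix empty after masking")
  matrix$mask <- mask
  matrix
}

#' Extract the single-chromosome slice of a contact matrix
#'
#' Compartment and TAD procedures are cis: they run per chromosome.
#'
#' @param matrix a [contact_matrix()] over a multi-chromosome bin table.
#' @param chrom chromosome name.
#' @return A [contact_matrix()] restricted to that chromosome's bins.
#' @export
chrom_slice <- function(matrix, chrom) {
  sel <- which(matrix$bins$chrom == chrom)
  if (length(sel) == 0L) stop(sprintf("chromosome '%s' not in bin table", chrom))
  bins <- matrix$bins[sel, , drop = FALSE]
  bins$index <- seq_len(nrow(bins))
  rownames(bins) <- NULL
  attr(bins, "bin_size") <- bin_size_of(matrix$bins)
  lay <- attr(matrix$bins, "layout")
  attr(bins, "layout") <- lay[lay$chrom == chrom, , drop = FALSE]
  class(bins) <- class(matrix$bins)
  mask <- match(intersect(matrix$mask, sel), sel)
  contact_matrix(matrix$values[sel, sel, drop = FALSE], bins,
                 kind = matrix$kind, mask = mask)
}
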