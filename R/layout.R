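#' Genome layout
#'
#' Ordered set of chromosomes with their lengths in bp. The order is
#' authoritative: global bin indices follow it.
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths integer-like vector of chromosome lengths in bp,
#'   same length as `chrom_names`, all positive.
#' @return An object of class `genome_layout`: a data frame with columns
#'   `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) == 0L) {
    stop("empty layout: at least one chromosome required")
  }
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have the same length")
  }
  if (anyDuplicated(chrom_names)) {
    stop("chromosome names must be unique")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  out <- data.frame(chrom = chrom_names, length = chrom_lengths,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a UCSC-style chromosome sizes file
#'
#' Two tab-separated columns, `chrom` and `length`, no header.
#'
#' @param path path to the chrom.sizes file.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"),
                           comment.char = "#")
  genome_layout(tab$chrom, tab$length)
}

#' Partition a genome into fixed-width bins
#'
#' Bins are 0-based half-open, contiguous and non-overlapping within each
#' chromosome; the last bin of a chromosome is clipped to the chromosome
#' length. Global bin indices are dense, 1-based, and follow layout order.
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp (> 0).
#' @return An object of class `bin_table`: a data frame with columns
#'   `chrom`, `start`, `end`, `index`, and attribute `bin_size`.
#' @examples
#' make_bins(genome_layout("chrA", 1.2e6), 5e5)
#' @export
make_bins <- function(layout, bin_size) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("bin_size must be a single positive number")
  }
  pieces <- lapply(seq_len(nrow(layout)), function(k) {
    len <- layout$length[k]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    end <- pmin(start + bin_size, len)
    data.frame(chrom = layout$chrom[k], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  attr(out, "layout") <- layout
  class(out) <- c("bin_table", "data.frame")
  out
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d bins of %s bp over %d chromosome(s)\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              length(unique(x$chrom))))
  NextMethod()
}

bin_size_of <- function(bins) attr(bins, "bin_size")

#' Map genomic positions to global bin indices
#'
#' Positions are 0-based; a position on a bin start belongs to that bin
#' (half-open convention).
#'
#' @param bins a [make_bins()] table.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return Integer global bin indices; NA for positions off the layout.
#' @export
locate_bins <- function(bins, chrom, pos) {
  stopifnot(inherits(bins, "bin_table"))
  bs <- bin_size_of(bins)
  layout <- attr(bins, "layout")
  offset <- c(0, cumsum(vapply(layout$chrom, function(cn) {
    sum(bins$chrom == cn)
  }, numeric(1))))[seq_len(nrow(layout))]
  names(offset) <- layout$chrom
  nb_per <- vapply(layout$chrom, function(cn) sum(bins$chrom == cn), numeric(1))
  ci <- match(chrom, layout$chrom)
  within <- floor(pos / bs) + 1
  idx <- offset[chrom] + within
  bad <- is.na(ci) | pos < 0 | pos >= layout$length[ci] | within > nb_per[ci]
  idx[bad] <- NA_integer_
  as.integer(idx)
}
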