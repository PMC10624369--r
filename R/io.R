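#' Read a contact-pairs file
#'
#' Tab-separated `chromA posA chromB posB`, no header; lines starting with
#' `#` are comments. Positions are 0-based by default; set `one_based` for
#' 1-based dialects.
#'
#' @param path path to the pairs file.
#' @param strict if TRUE, a malformed line raises an error naming the line
#'   number; if FALSE, malformed lines are skipped and counted.
#' @param one_based subtract 1 from positions on input.
#' @return Data frame `chromA, posA, chromB, posB`; attribute `n_malformed`
#'   counts skipped lines in lenient mode.
#' @export
read_pairs <- function(path, strict = TRUE, one_based = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= 4 && !is.na(suppressWarnings(as.numeric(p[2]))) &&
      !is.na(suppressWarnings(as.numeric(p[4])))
  }, logical(1))
  if (any(!ok)) {
    if (strict) {
      stop(sprintf("malformed pairs line %d: '%s'",
                   lineno[which(!ok)[1]], lines[which(!ok)[1]]))
    }
    parts <- parts[ok]
  }
  out <- data.frame(
    chromA = vapply(parts, `[`, "", 1),
    posA = as.numeric(vapply(parts, `[`, "", 2)),
    chromB = vapply(parts, `[`, "", 3),
    posB = as.numeric(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE)
  if (one_based) {
    out$posA <- out$posA - 1
    out$posB <- out$posB - 1
  }
  attr(out, "n_malformed") <- sum(!ok)
  out
}

#' Write contact pairs
#'
#' @param pairs data frame as returned by [read_pairs()].
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("chromA", "posA", "chromB", "posB")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

bin_labels <- function(bins) {
  sprintf("%s:%d-%d", bins$chrom, as.integer(bins$start), as.integer(bins$end))
}

#' Load a contact matrix from file
#'
#' Two formats: `pairs` (tab-separated contact pairs, binned on load) and
#' `dense_tsv` (full symmetric matrix with `chrom:start-end` labels in the
#' first row and column; round-trips bit-exactly with [write_contacts()]).
#'
#' @param path input path.
#' @param bins a [make_bins()] table the matrix must conform to.
#' @param format `"pairs"` or `"dense_tsv"`.
#' @param ... passed to [read_pairs()] / [bin_pairs()] for `pairs` input.
#' @return A [contact_matrix()].
#' @export
load_contacts <- function(path, bins, format = c("dense_tsv", "pairs"), ...) {
  format <- match.arg(format)
  if (format == "pairs") {
    return(bin_pairs(read_pairs(path, ...), bins))
  }
  meta <- dense_tsv_meta(path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, comment.char = "",
                           skip = meta$n_comment)
  mat <- as.matrix(tab)
  labels <- bin_labels(bins)
  if (!identical(rownames(mat), labels) || !identical(colnames(mat), labels)) {
    stop("dense_tsv header does not match the bin table")
  }
  storage <- unname(mat)
  storage.mode(storage) <- "double"
  dif <- abs(storage - t(storage))
  if (any(dif[!is.na(dif)] > 0)) stop("matrix not symmetric")
  contact_matrix(storage, bins, kind = meta$kind, mask = meta$mask)
}

dense_tsv_meta <- function(path) {
  kind <- "raw"
  mask <- integer(0)
  n <- 0L
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    n <- n + 1L
    if (startsWith(line, "#kind=")) kind <- sub("^#kind=", "", line)
    if (startsWith(line, "#mask=")) {
      body <- sub("^#mask=", "", line)
      if (nzchar(body)) mask <- as.integer(strsplit(body, ",")[[1]])
    }
  }
  list(kind = kind, mask = mask, n_comment = n)
}

#' Write a contact matrix as dense TSV
#'
#' First row and column carry `chrom:start-end` bin labels; `#kind=` and
#' `#mask=` comment lines record the processing stage and masked bin
#' indices, so the full object round-trips through [load_contacts()].
#'
#' @param matrix a [contact_matrix()].
#' @param path output path.
#' @param format only `"dense_tsv"` is supported for writing.
#' @export
write_contacts <- function(matrix, path, format = "dense_tsv") {
  if (!identical(format, "dense_tsv")) stop(sprintf("unknown format '%s'", format))
  vals <- matrix$values
  labels <- bin_labels(matrix$bins)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#kind=%s", matrix$kind), con)
  writeLines(sprintf("#mask=%s", paste(matrix$mask, collapse = ",")), con)
  writeLines(paste(c("bin", labels), collapse = "\t"), con)
  for (i in seq_len(nrow(vals))) {
    writeLines(paste(c(labels[i],
                       format(vals[i, ], digits = 17, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a per-bin track as bedGraph
#'
#' @param bins a [make_bins()] table.
#' @param values numeric vector, one value per bin; NA bins are dropped.
#' @param path output path.
#' @export
write_bedgraph <- function(bins, values, path) {
  stopifnot(nrow(bins) == length(values))
  keep <- !is.na(values)
  utils::write.table(
    data.frame(bins$chrom[keep], as.integer(bins$start[keep]),
               as.integer(bins$end[keep]), values[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED or narrowPeak intervals
#'
#' 0-based half-open intervals. For narrowPeak input the 7th column
#' (signalValue) is kept as `signal`; plain BED gets signal 1.
#'
#' @param path input path.
#' @return Data frame `chrom, start, end, signal`.
#' @export
read_peaks <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED input needs at least 3 columns")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]),
                    signal = if (ncol(tab) >= 7) as.numeric(tab[[7]]) else 1,
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("invalid interval: end <= start")
  out
}

#' Read a gene table
#'
#' Tab-separated with header: `gene_id, chrom, strand, tss, fpkm_cond1,
#' fpkm_cond2` (TSS 0-based).
#'
#' @param path input path.
#' @return Data frame of gene records.
#' @export
read_genes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "fpkm_cond1", "fpkm_cond2")
  if (!all(need %in% names(tab))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$fpkm_cond1 < 0) || any(tab$fpkm_cond2 < 0)) {
    stop("FPKM values must be non-negative")
  }
  tab[, need]
}
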