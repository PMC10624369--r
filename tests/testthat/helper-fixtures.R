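# shared fixture builders; everything is generated in code at test time

toy_bins <- function(n, bin_size = 1e5, chrom = "chrT") {
  make_bins(genome_layout(chrom, n * bin_size), bin_size)
}

# random symmetric integer count matrix with positive marginals
sym_count_matrix <- function(n, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- upper.tri(m, diag = TRUE)
  m[up] <- stats::rpois(sum(up), lambda)
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  contact_matrix(m, toy_bins(n), kind = "raw")
}

# wrap a bare score vector as an insulation track (bin size 1e5 -> the
# default 200-kb search range spans 2 bins)
make_track <- function(scores, bin_size = 1e5, chrom = "chrT") {
  bins <- toy_bins(length(scores), bin_size, chrom)
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    community_contacts = NA_real_, score = scores,
                    stringsAsFactors = FALSE)
  attr(out, "window_bp") <- 2 * bin_size
  attr(out, "bin_size") <- bin_size
  attr(out, "chrom_mean") <- NA_real_
  attr(out, "n_capped") <- 0L
  class(out) <- c("insulation_track", "data.frame")
  out
}

# compartment profile from a bare pc1 vector
make_profile <- function(pc1, bin_size = 1e5) {
  call_compartments(pc1, toy_bins(length(pc1), bin_size))
}

# boundary set from bin indices and strengths
make_bset <- function(bins_idx, strengths, bin_size = 1e5, chrom = "chrT") {
  zeros <- rep(0, length(bins_idx))
  out <- data.frame(chrom = rep(chrom, length(bins_idx)),
                    bin = as.integer(bins_idx),
                    start = (bins_idx - 1) * bin_size,
                    end = bins_idx * bin_size,
                    score = -strengths, mean_left = zeros,
                    mean_right = zeros, delta = zeros, strength = strengths,
                    stringsAsFactors = FALSE)
  attr(out, "bin_size") <- bin_size
  class(out) <- c("boundary_set", "data.frame")
  out
}

# deterministic "balanced" matrix straight from the simulator's expected
# rates: lets structural tests run without Poisson noise
rate_matrix_as_balanced <- function(truth, condition = 1) {
  lam <- expected_rate_matrix(truth, condition)
  bins <- make_bins(
    genome_layout(truth$config$chrom_name,
                  truth$config$n_bins * truth$config$bin_size),
    truth$config$bin_size)
  contact_matrix(lam, bins, kind = "balanced")
}
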