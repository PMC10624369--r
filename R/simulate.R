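#' Simulation configuration
#'
#' Defaults describe the reference synthetic study: one 80-Mb chromosome at
#' 40-kb resolution (2000 bins), power-law distance decay with exponent 1,
#' checkerboard compartment structure of strength 0.6 over ~1-Mb blocks,
#' 9% of bins switching A-to-B and 10% B-to-A between conditions, five TAD
#' boundaries of insulation strength 1.0 of which 40% are weakened to half
#' strength in condition 2, ~2 million total contacts (about 1000 per
#' bin), and 2000 genes whose condition-2 expression is shifted by -1.5 /
#' +1.5 log2 units in AB / BA bins with 0.5 log2 units of noise.
#'
#' @param n_bins number of bins on the simulated chromosome.
#' @param bin_size bin width in bp.
#' @param total_contacts expected total contact count (sets the depth
#'   scale L).
#' @param alpha power-law distance-decay exponent.
#' @param checkerboard_strength compartment contrast c in `[0, 1)`:
#'   expected counts are multiplied by (1 + c * s_i * s_j).
#' @param segmentation `"tad_aligned"` (default): compartment blocks
#'   change sign only at a subset of the planted TAD boundaries (every
#'   other one), so every extended discontinuity of the expected-count
#'   model is a planted boundary (the checkerboard factor acts at all
#'   distances, so a compartment block edge insulates exactly like a TAD
#'   boundary; see the methods vignette). `"geometric"`: classic
#'   alternating blocks with geometric lengths, independent of
#'   boundaries.
#' @param block_mean_bins mean compartment block length (geometric mode).
#' @param fine_scale_frac fraction of bins whose condition-1 sign is
#'   flipped relative to its block, as isolated bins (real fine-resolution
#'   PC1 tracks show sub-block sign variation; isolated flips also give
#'   the per-bin eigenvector signal short-range support).
#' @param flip_min_gap minimum bin distance between any two flipped bins
#'   (fine-scale or switch); isolated flips only dent the insulation
#'   track below the boundary-calling threshold, clustered ones would
#'   mimic boundaries.
#' @param boundary_buffer_bins no flipped bin is placed within this many
#'   bins of a planted boundary, so the insulation valley shape at each
#'   boundary is identical across conditions up to the planted strength
#'   change.
#' @param frac_AB,frac_BA target switch fractions.
#' @param n_boundaries number of planted TAD boundaries.
#' @param boundary_strength per-boundary insulation strength t in
#'   condition 1: same-TAD contacts are multiplied by (1 + t).
#' @param frac_weakened fraction of boundaries whose condition-2 strength
#'   is `weakened_factor` times the condition-1 strength.
#' @param weakened_factor multiplier on t for weakened boundaries.
#' @param n_genes gene count.
#' @param gene_density_ratio relative gene density of A vs B bins
#'   (condition-1 signs). Active compartments are gene-dense in real
#'   genomes, and the gene-density track doubles as the PC1 orientation
#'   anchor, which needs a genuine correlation with compartment state.
#' @param class_effect log2 expression shift magnitude for switch-class
#'   genes.
#' @param expr_sigma per-gene log2 expression noise sd.
#' @param expr_mu0,expr_sigma0 baseline log2 FPKM mean and sd. The
#'   default baseline (~32 FPKM) keeps the unit pseudocount used in
#'   fold-change computation from materially shrinking planted effects.
#' @param peaks_per_bin expected peak count per B bin.
#' @param peak_enrichment A-bin peak rate multiplier (>= 1).
#' @param chrom_name simulated chromosome name.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_bins = 2000, bin_size = 40000,
                              total_contacts = 2e6, alpha = 1,
                              checkerboard_strength = 0.6,
                              segmentation = c("tad_aligned", "geometric"),
                              block_mean_bins = 25,
                              fine_scale_frac = 0.05, flip_min_gap = 3,
                              boundary_buffer_bins = 15,
                              frac_AB = 0.09, frac_BA = 0.10,
                              n_boundaries = 5, boundary_strength = 1.0,
                              frac_weakened = 0.4, weakened_factor = 0.5,
                              n_genes = 2000, gene_density_ratio = 3,
                              class_effect = 1.5,
                              expr_sigma = 0.5, expr_mu0 = 5,
                              expr_sigma0 = 1, peaks_per_bin = 2,
                              peak_enrichment = 1,
                              chrom_name = "chrS") {
  segmentation <- match.arg(segmentation)
  cfg <- list(n_bins = n_bins, bin_size = bin_size,
              total_contacts = total_contacts, alpha = alpha,
              checkerboard_strength = checkerboard_strength,
              segmentation = segmentation,
              block_mean_bins = block_mean_bins,
              fine_scale_frac = fine_scale_frac, flip_min_gap = flip_min_gap,
              boundary_buffer_bins = boundary_buffer_bins,
              frac_AB = frac_AB, frac_BA = frac_BA,
              n_boundaries = n_boundaries,
              boundary_strength = boundary_strength,
              frac_weakened = frac_weakened,
              weakened_factor = weakened_factor,
              n_genes = n_genes, gene_density_ratio = gene_density_ratio,
              class_effect = class_effect,
              expr_sigma = expr_sigma, expr_mu0 = expr_mu0,
              expr_sigma0 = expr_sigma0, peaks_per_bin = peaks_per_bin,
              peak_enrichment = peak_enrichment, chrom_name = chrom_name)
  stopifnot(n_bins >= 10, bin_size > 0, total_contacts > 0, alpha > 0,
            checkerboard_strength >= 0, checkerboard_strength < 1,
            fine_scale_frac >= 0, fine_scale_frac < 0.5, flip_min_gap >= 1,
            boundary_buffer_bins >= 0,
            frac_AB >= 0, frac_BA >= 0, frac_AB + frac_BA < 1,
            n_boundaries >= 0, boundary_strength >= 0,
            frac_weakened >= 0, frac_weakened <= 1,
            weakened_factor > 0, gene_density_ratio >= 1,
            peak_enrichment >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Plant the ground-truth structure
#'
#' Boundaries are evenly spaced through the chromosome interior. In the
#' default `tad_aligned` segmentation the condition-1 compartment blocks
#' change sign at every other boundary (compartment blocks span about two
#' TADs), so every extended sign discontinuity of the expected-count model
#' sits at a planted boundary; in `geometric` mode the signs form
#' alternating blocks with geometric lengths independent of boundaries.
#' A fraction of bins carries isolated fine-scale sign flips, and a
#' further random subset is flipped in condition 2 to hit the target
#' switch fractions exactly (rounded to whole bins, always within half a
#' percentage point); all flipped bins keep a minimum mutual distance and
#' stay clear of the boundary neighbourhoods. A configured fraction of
#' boundaries is marked weakened in condition 2; in `tad_aligned` mode
#' weakened boundaries are drawn among boundaries that are not
#' compartment block edges, where a strength change is identifiable from
#' the insulation profile (at a block edge the condition-invariant
#' compartment contrast dominates the valley).
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed for the structure.
#' @return A list of class `synthetic_truth` with per-bin `sign1`,
#'   `sign2`, `switch_class`, boundary table (`bin`, `t1`, `t2`,
#'   `weakened`, `at_block_edge`), and the realized switch fractions.
#' @export
plant_structure <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_bins
  nbnd <- config$n_boundaries
  bpos <- if (nbnd > 0) round(seq_len(nbnd) * n / (nbnd + 1)) else integer(0)
  s <- sample(c(1L, -1L), 1)
  at_edge <- rep(FALSE, nbnd)
  if (config$segmentation == "tad_aligned" && nbnd > 0) {
    # sign changes at every other boundary (odd indices keep the A/B bin
    # totals balanced): compartment blocks span ~2 TAD segments
    at_edge <- seq_len(nbnd) %% 2 == 1
    seg_signs <- s * cumprod(c(1L, ifelse(at_edge, -1L, 1L)))
    base <- rep(seg_signs, diff(c(0, bpos, n)))
  } else {
    # alternating A/B blocks, geometric lengths
    base <- integer(0)
    while (length(base) < n) {
      len <- 1 + stats::rgeom(1, 1 / config$block_mean_bins)
      base <- c(base, rep(s, len))
      s <- -s
    }
    base <- base[seq_len(n)]
  }
  k_fine <- round(config$fine_scale_frac * n)
  k_ab <- round(config$frac_AB * n)
  k_ba <- round(config$frac_BA * n)
  buffer <- unique(unlist(lapply(bpos, function(p) {
    (p - config$boundary_buffer_bins):(p + config$boundary_buffer_bins)
  })))
  allowed <- setdiff(seq_len(n), buffer)
  flips <- sample_spaced(allowed, k_fine + k_ab + k_ba, config$flip_min_gap,
                         base, k_ab, k_ba)
  sign1 <- base
  sign1[flips$fine] <- -base[flips$fine]
  sign2 <- sign1
  sign2[flips$ab] <- -1L
  sign2[flips$ba] <- 1L
  lab <- function(x) ifelse(x > 0, "A", "B")
  switch_class <- paste0(lab(sign1), lab(sign2))
  t1 <- rep(config$boundary_strength, nbnd)
  n_weak <- round(config$frac_weakened * nbnd)
  weakened <- rep(FALSE, nbnd)
  if (n_weak > 0 && nbnd > 0) {
    pool <- which(!at_edge)
    if (length(pool) < n_weak) pool <- seq_len(nbnd)
    weakened[sample_int(pool, n_weak)] <- TRUE
  }
  t2 <- ifelse(weakened, t1 * config$weakened_factor, t1)
  structure(list(
    config = config,
    sign1 = sign1, sign2 = sign2, switch_class = switch_class,
    boundaries = data.frame(bin = bpos, t1 = t1, t2 = t2,
                            weakened = weakened, at_block_edge = at_edge),
    realized_frac_AB = k_ab / n, realized_frac_BA = k_ba / n),
    class = "synthetic_truth")
}

# sample() treats a length-1 x as 1:x; this does not
sample_int <- function(x, k) x[sample.int(length(x), k)]

# draw flip positions from `allowed` with pairwise distance >= gap.
# Switch flips are sampled first, class by class (their counts are hard
# targets: they set the realized switch fractions), then fine-scale flips
# fill in from whatever space is left — the fine count absorbs any
# shortfall when random packing jams. Retries before giving up.
sample_spaced <- function(allowed, k, gap, base, k_ab, k_ba,
                          max_tries = 50) {
  draw <- function(avail, pool, want) {
    picked <- integer(0)
    pool <- intersect(pool, avail)
    while (length(picked) < want && length(pool) > 0) {
      p <- sample_int(pool, 1)
      picked <- c(picked, p)
      pool <- pool[abs(pool - p) >= gap]
    }
    picked
  }
  a_pool <- allowed[base[allowed] > 0]
  b_pool <- allowed[base[allowed] < 0]
  k_fine <- max(0, k - k_ab - k_ba)
  for (try in seq_len(max_tries)) {
    avail <- allowed
    ab <- draw(avail, a_pool, k_ab)
    if (length(ab) < k_ab) next
    for (p in ab) avail <- avail[abs(avail - p) >= gap]
    ba <- draw(avail, b_pool, k_ba)
    if (length(ba) < k_ba) next
    for (p in ba) avail <- avail[abs(avail - p) >= gap]
    fine <- draw(avail, avail, k_fine)
    return(list(fine = fine, ab = ab, ba = ba))
  }
  stop("switch flip targets unreachable: ",
       "not enough eligible bins with the required spacing")
}

#' Expected (Poisson rate) matrix for one condition
#'
#' lambda[i, j] = L * (|i-j| + 1)^(-alpha) * (1 + c * s_i * s_j) *
#' prod_b (1 + t_b)^(i, j on the same side of boundary b), with L chosen
#' so the expected total count matches the configured depth.
#'
#' @param truth a [plant_structure()] truth.
#' @param condition 1 or 2.
#' @return Numeric n_bins x n_bins rate matrix.
#' @export
expected_rate_matrix <- function(truth, condition = 1) {
  cfg <- truth$config
  n <- cfg$n_bins
  s <- if (condition == 1) truth$sign1 else truth$sign2
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- (d + 1)^(-cfg$alpha)
  lam <- lam * (1 + cfg$checkerboard_strength * outer(s, s))
  tcol <- if (condition == 1) "t1" else "t2"
  for (k in seq_len(nrow(truth$boundaries))) {
    p <- truth$boundaries$bin[k]
    t <- truth$boundaries[[tcol]][k]
    side <- as.integer(seq_len(n) > p)
    same <- outer(side, side, "==")
    lam <- lam * (1 + t)^same
  }
  lam * cfg$total_contacts / sum(lam[upper.tri(lam, diag = TRUE)])
}

#' Simulate a raw contact map
#'
#' Counts are Poisson draws from [expected_rate_matrix()], sampled once
#' per unordered pair and mirrored, so the matrix is symmetric and
#' integer.
#'
#' @param truth a [plant_structure()] truth.
#' @param condition 1 or 2.
#' @param seed RNG seed for this matrix.
#' @return A raw [contact_matrix()] on the simulated chromosome.
#' @export
simulate_contact_map <- function(truth, condition = 1, seed = 1) {
  cfg <- truth$config
  set.seed(seed)
  lam <- expected_rate_matrix(truth, condition)
  if (any(lam > .Machine$integer.max / 4)) stop("rate overflow: lower depth")
  n <- cfg$n_bins
  up <- upper.tri(lam, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(sum(up), lam[up])
  counts <- counts + t(counts)
  diag(counts) <- diag(counts) / 2
  layout <- genome_layout(cfg$chrom_name, n * cfg$bin_size)
  bins <- make_bins(layout, cfg$bin_size)
  contact_matrix(counts, bins, kind = "raw")
}

#' Simulate a two-condition expression table
#'
#' Genes are placed over bins with density `gene_density_ratio` times
#' higher in A (condition-1) bins than B bins. Baseline log2 FPKM is
#' Normal(mu0, sigma0^2); condition-2 log2 FPKM adds +effect for genes in
#' BA bins, -effect in AB bins, 0 otherwise, plus Normal(0, sigma^2) noise
#' in each condition.
#'
#' @param truth a [plant_structure()] truth.
#' @param seed RNG seed for the expression table.
#' @return Gene table (`gene_id, chrom, strand, tss, fpkm_cond1,
#'   fpkm_cond2`) with truth columns `true_bin`, `true_class`,
#'   `true_effect`.
#' @export
simulate_expression <- function(truth, seed = 1) {
  cfg <- truth$config
  set.seed(seed)
  n <- cfg$n_genes
  w <- ifelse(truth$sign1 > 0, cfg$gene_density_ratio, 1)
  bin <- sample.int(cfg$n_bins, n, replace = TRUE, prob = w)
  offset <- floor(stats::runif(n, 0, cfg$bin_size))
  tss <- (bin - 1) * cfg$bin_size + offset
  cls <- truth$switch_class[bin]
  effect <- ifelse(cls == "BA", cfg$class_effect,
                   ifelse(cls == "AB", -cfg$class_effect, 0))
  base <- stats::rnorm(n, cfg$expr_mu0, cfg$expr_sigma0)
  l1 <- base + stats::rnorm(n, 0, cfg$expr_sigma)
  l2 <- base + effect + stats::rnorm(n, 0, cfg$expr_sigma)
  data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
             chrom = cfg$chrom_name,
             strand = sample(c("+", "-"), n, replace = TRUE),
             tss = tss,
             fpkm_cond1 = pmax(2^l1, 0),
             fpkm_cond2 = pmax(2^l2, 0),
             true_bin = bin, true_class = cls, true_effect = effect,
             stringsAsFactors = FALSE)
}

#' Simulate a histone-mark peak set
#'
#' Peak counts per bin are Poisson with rate `peaks_per_bin` in B bins and
#' `peak_enrichment` times that in A bins (condition-1 signs); peaks are
#' placed uniformly within their bin.
#'
#' @param truth a [plant_structure()] truth.
#' @param seed RNG seed for the peaks.
#' @param peak_width peak width in bp (clipped to the bin).
#' @return Peak table (`chrom, start, end, signal`).
#' @export
simulate_peaks <- function(truth, seed = 1, peak_width = 500) {
  cfg <- truth$config
  set.seed(seed)
  rate <- ifelse(truth$sign1 > 0,
                 cfg$peaks_per_bin * cfg$peak_enrichment, cfg$peaks_per_bin)
  counts <- stats::rpois(cfg$n_bins, rate)
  bin <- rep(seq_len(cfg$n_bins), counts)
  if (length(bin) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), signal = numeric(0)))
  }
  width <- pmin(peak_width, cfg$bin_size)
  start <- (bin - 1) * cfg$bin_size +
    floor(stats::runif(length(bin), 0, cfg$bin_size - width))
  data.frame(chrom = cfg$chrom_name, start = start, end = start + width,
             signal = stats::rexp(length(bin), 1) + 1,
             stringsAsFactors = FALSE)
}

#' Generate a complete two-condition synthetic dataset
#'
#' Derives independent sub-seeds for structure, the two matrices,
#' expression and peaks from one master seed, so artifacts can be
#' regenerated independently.
#'
#' @param config a [simulation_config()].
#' @param seed master seed.
#' @return List of class `synthetic_dataset` with `truth`, `matrix1`,
#'   `matrix2`, `genes`, `peaks`, `config`, `seeds`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1) {
  seeds <- derive_seeds(seed)
  truth <- plant_structure(config, seeds["structure"])
  structure(list(
    truth = truth,
    matrix1 = simulate_contact_map(truth, 1, seeds["matrix1"]),
    matrix2 = simulate_contact_map(truth, 2, seeds["matrix2"]),
    genes = simulate_expression(truth, seeds["expression"]),
    peaks = simulate_peaks(truth, seeds["peaks"]),
    config = config, seeds = seeds),
    class = "synthetic_dataset")
}

derive_seeds <- function(seed) {
  # distinct deterministic streams per artifact, kept within 32-bit range
  base <- (as.numeric(seed) * 7919) %% 2147480000
  s <- (base + c(structure = 11, matrix1 = 23, matrix2 = 37,
                 expression = 53, peaks = 71)) %% 2147480000
  stats::setNames(as.integer(s), names(s))
}

#' Write a synthetic dataset as a fixture directory
#'
#' Emits the pipeline's own input formats: dense TSV matrices per
#' condition, gene TSV, peak BED, and a truth JSON.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_contacts(dataset$matrix1, file.path(dir, "cond1.matrix.tsv"))
  write_contacts(dataset$matrix2, file.path(dir, "cond2.matrix.tsv"))
  utils::write.table(dataset$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pk <- dataset$peaks
  utils::write.table(
    data.frame(pk$chrom, as.integer(pk$start), as.integer(pk$end),
               sprintf("peak%d", seq_len(nrow(pk))), 0, ".",
               pk$signal, -1, -1, as.integer((pk$end - pk$start) / 2)),
    file.path(dir, "peaks.narrowPeak"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  truth <- dataset$truth
  jsonlite::write_json(
    list(config = unclass(truth$config), sign1 = truth$sign1,
         sign2 = truth$sign2, switch_class = truth$switch_class,
         boundaries = truth$boundaries,
         realized_frac_AB = truth$realized_frac_AB,
         realized_frac_BA = truth$realized_frac_BA,
         seeds = as.list(dataset$seeds)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  chrom <- truth$config$chrom_name
  writeLines(sprintf("%s\t%d", chrom,
                     truth$config$n_bins * truth$config$bin_size),
             file.path(dir, "chrom.sizes"))
  invisible(dir)
}
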