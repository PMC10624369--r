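small_cfg <- function(...) {
  simulation_config(n_bins = 300, total_contacts = 3e5, n_boundaries = 2,
                    boundary_buffer_bins = 8, flip_min_gap = 2, ...)
}

test_that("planted structure is deterministic and hits switch targets exactly", {
  cfg <- small_cfg()
  t1 <- plant_structure(cfg, seed = 42)
  t2 <- plant_structure(cfg, seed = 42)
  expect_identical(t1, t2)

  n <- cfg$n_bins
  expect_equal(sum(t1$sign1 > 0 & t1$sign2 < 0) / n, t1$realized_frac_AB)
  expect_equal(sum(t1$sign1 < 0 & t1$sign2 > 0) / n, t1$realized_frac_BA)
  expect_lt(abs(t1$realized_frac_AB - cfg$frac_AB), 0.005)
  expect_lt(abs(t1$realized_frac_BA - cfg$frac_BA), 0.005)

  # switch classes consistent with the two sign vectors
  lab <- function(s) ifelse(s > 0, "A", "B")
  expect_equal(t1$switch_class, paste0(lab(t1$sign1), lab(t1$sign2)))

  # no switches requested: identical sign vectors
  t0 <- plant_structure(small_cfg(frac_AB = 0, frac_BA = 0,
                                  fine_scale_frac = 0), seed = 7)
  expect_identical(t0$sign1, t0$sign2)
})

test_that("flip placement respects spacing and boundary buffers", {
  cfg <- small_cfg()
  tr <- plant_structure(cfg, seed = 9)
  flipped <- sort(unique(c(which(tr$sign1 != tr$sign2),
                           which(tr$sign1 != rep(tr$sign1[1], cfg$n_bins)) )))
  switched <- which(tr$sign1 != tr$sign2)
  expect_true(all(diff(sort(switched)) >= cfg$flip_min_gap))
  for (b in tr$boundaries$bin) {
    expect_false(any(abs(switched - b) <= cfg$boundary_buffer_bins))
  }
})

test_that("larger structures hit 9%/10% targets within half a point", {
  truth <- plant_structure(simulation_config(), seed = 11)
  expect_lt(abs(truth$realized_frac_AB - 0.09), 0.005)
  expect_lt(abs(truth$realized_frac_BA - 0.10), 0.005)
})

test_that("contact maps are symmetric integer Poisson draws around the rate model", {
  cfg <- small_cfg()
  truth <- plant_structure(cfg, seed = 1)
  m1 <- simulate_contact_map(truth, 1, seed = 5)
  m2 <- simulate_contact_map(truth, 1, seed = 5)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$values, t(m1$values))
  expect_true(all(m1$values == round(m1$values)))
  expect_true(all(m1$values >= 0))

  # totals concentrate near the configured depth
  expect_lt(abs(sum(m1$values[upper.tri(m1$values, diag = TRUE)]) -
                  cfg$total_contacts) / cfg$total_contacts, 0.05)

  # with no structure the expected matrix is Toeplitz: per-diagonal O/E of
  # the rate matrix is exactly 1
  flat <- plant_structure(small_cfg(checkerboard_strength = 0,
                                    boundary_strength = 0,
                                    fine_scale_frac = 0), seed = 2)
  lam <- expected_rate_matrix(flat, 1)
  for (d in c(1, 5, 20)) {
    vals <- lam[cbind(1:(300 - d), (1 + d):300)]
    expect_lt(stats::sd(vals) / mean(vals), 1e-12)
  }
})

test_that("the checkerboard factor shows up in O/E sign structure of sampled maps", {
  cfg <- small_cfg(checkerboard_strength = 0.6)
  truth <- plant_structure(cfg, seed = 3)
  m <- simulate_contact_map(truth, 1, seed = 4)
  oe <- observed_over_expected(m)
  s <- truth$sign1
  same <- outer(s, s) > 0
  off <- !is.na(oe$values)
  expect_gt(mean(oe$values[same & off]), 1)
  expect_lt(mean(oe$values[!same & off]), 1)
})

test_that("expression tables couple fold changes to planted switch classes", {
  cfg <- simulation_config(n_bins = 500, n_genes = 2000, total_contacts = 5e5)
  truth <- plant_structure(cfg, seed = 21)
  g1 <- simulate_expression(truth, seed = 8)
  expect_identical(g1, simulate_expression(truth, seed = 8))
  expect_true(all(g1$fpkm_cond1 >= 0))
  lfc <- log2_fold_change(g1$fpkm_cond1, g1$fpkm_cond2)
  med <- tapply(lfc, g1$true_class, median)
  expect_lt(abs(med["BA"] - cfg$class_effect), 0.15)
  expect_lt(abs(med["AB"] + cfg$class_effect), 0.15)

  # zero effect: class medians shrink toward zero
  cfg0 <- simulation_config(n_bins = 500, n_genes = 2000,
                            total_contacts = 5e5, class_effect = 0)
  t0 <- plant_structure(cfg0, seed = 21)
  g0 <- simulate_expression(t0, seed = 8)
  lfc0 <- log2_fold_change(g0$fpkm_cond1, g0$fpkm_cond2)
  med0 <- tapply(lfc0, g0$true_class, median)
  bound <- 3 * cfg0$expr_sigma / sqrt(min(table(g0$true_class)))
  expect_lt(abs(med0["AB"]), bound)
  expect_lt(abs(med0["BA"]), bound)

  # gene density follows the planted compartments
  dens <- gene_density_track(g1, toy_bins(500, 40000, "chrS"))
  expect_gt(mean(dens[truth$sign1 > 0]), mean(dens[truth$sign1 < 0]))
})

test_that("peak simulation reflects the enrichment ratio", {
  cfg <- simulation_config(n_bins = 500, total_contacts = 5e5,
                           peak_enrichment = 5)
  truth <- plant_structure(cfg, seed = 2)
  pk <- simulate_peaks(truth, seed = 3)
  expect_identical(pk, simulate_peaks(truth, seed = 3))
  bins <- toy_bins(500, 40000, "chrS")
  cov <- peak_coverage(pk, bins)
  a <- cov[truth$sign1 > 0]; b <- cov[truth$sign1 < 0]
  expect_lt(stats::wilcox.test(a, b)$p.value, 0.01)

  cfg1 <- simulation_config(n_bins = 500, total_contacts = 5e5,
                            peak_enrichment = 1)
  t1 <- plant_structure(cfg1, seed = 2)
  pk1 <- simulate_peaks(t1, seed = 3)
  cov1 <- peak_coverage(pk1, bins)
  m_a <- mean(cov1[t1$sign1 > 0]); m_b <- mean(cov1[t1$sign1 < 0])
  expect_lt(abs(m_a - m_b) / m_b, 0.2)
})

test_that("datasets regenerate bit-identically from the master seed and round-trip to disk", {
  cfg <- small_cfg(n_genes = 100)
  d1 <- simulate_dataset(cfg, seed = 77)
  d2 <- simulate_dataset(cfg, seed = 77)
  expect_identical(d1$matrix1$values, d2$matrix1$values)
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$peaks, d2$peaks)

  dir <- withr::local_tempdir()
  write_dataset(d1, dir)
  bins <- d1$matrix1$bins
  back <- load_contacts(file.path(dir, "cond1.matrix.tsv"), bins)
  expect_identical(back$values, d1$matrix1$values)
  genes <- read_genes(file.path(dir, "genes.tsv"))
  expect_equal(nrow(genes), 100)
  peaks <- read_peaks(file.path(dir, "peaks.narrowPeak"))
  expect_equal(nrow(peaks), nrow(d1$peaks))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$sign1, d1$truth$sign1)
  layout <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(layout$length, cfg$n_bins * cfg$bin_size)
})
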