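# independent brute-force ICE used as the oracle: plain alternating row
# normalisation run to machine precision
brute_ice <- function(M, iters = 5000) {
  M0 <- M
  b <- rep(1, nrow(M))
  for (i in seq_len(iters)) {
    s <- rowSums(M)
    s <- s / mean(s)
    M <- M / outer(s, s)
    b <- b * s
    if (max(abs(s - 1)) < 1e-14) break
  }
  b <- b / exp(mean(log(b)))   # geometric-mean-1 convention
  list(balanced = M0 / outer(b, b), bias = b)
}

test_that("ice_balance fixes already-balanced matrices and equalises marginals", {
  m <- contact_matrix(matrix(c(2, 1, 1, 2), 2), toy_bins(2))
  out <- ice_balance(m)
  expect_true(out$converged)
  expect_equal(out$bias, c(1, 1), tolerance = 1e-6)
  expect_equal(out$matrix$values / m$values, matrix(1, 2, 2), tolerance = 1e-6)

  m3 <- sym_count_matrix(30, seed = 5)
  out3 <- ice_balance(m3, tol = 1e-10)
  marg <- rowSums(out3$matrix$values)
  expect_lt(stats::sd(marg) / mean(marg), 1e-9)
  expect_equal(exp(mean(log(out3$bias))), 1, tolerance = 1e-12)
})

test_that("ice_balance recovers planted biases against the brute-force oracle", {
  # balanced core with equal marginals, then one bin scaled by 2 (cell x4)
  A <- matrix(c(0, 2, 2,
                2, 0, 2,
                2, 2, 0), 3)
  D <- diag(c(2, 1, 1))
  M <- D %*% A %*% D
  oracle <- brute_ice(M)
  out <- ice_balance(contact_matrix(M, toy_bins(3)), tol = 1e-12)
  expect_equal(out$bias, oracle$bias, tolerance = 1e-8)
  expect_equal(out$bias / out$bias[2], c(2, 1, 1), tolerance = 1e-6)
  expect_equal(out$matrix$values, oracle$balanced, tolerance = 1e-8)

  # random case, bias vector recovered up to normalisation
  set.seed(11)
  n <- 20
  base <- sym_count_matrix(n, seed = 12, lambda = 50)$values + 1
  bias <- exp(stats::rnorm(n, 0, 0.4))
  M <- base * outer(bias, bias)
  oracle <- brute_ice(M)
  out <- ice_balance(contact_matrix(round(M), toy_bins(n)), tol = 1e-12,
                     max_iter = 2000)
  expect_equal(out$bias, brute_ice(round(M))$bias, tolerance = 1e-8)
})

test_that("masked and zero rows stay zero and outside the marginal contract", {
  m <- sym_count_matrix(6, seed = 2)
  v <- m$values
  v[3, ] <- v[, 3] <- 0
  out <- ice_balance(contact_matrix(v, m$bins))
  expect_true(all(out$matrix$values[3, ] == 0))
  expect_true(is.na(out$bias[3]))
  marg <- rowSums(out$matrix$values)[-3]
  expect_lt(stats::sd(marg) / mean(marg), 1e-5)

  expect_error(ice_balance(contact_matrix(matrix(c(0, 0, 0, 5), 2),
                                          toy_bins(2))), "fewer than 2")
})

test_that("balancing is idempotent and scale-equivariant", {
  m <- sym_count_matrix(25, seed = 8)
  b1 <- ice_balance(m, tol = 1e-10)
  again <- b1$matrix
  again$kind <- "raw"  # re-enter the balancer
  again$values <- again$values
  b2 <- ice_balance(contact_matrix(round(again$values * 1e6), m$bins),
                    tol = 1e-10)
  expect_equal(b2$bias, rep(1, 25), tolerance = 1e-4)

  scaled <- contact_matrix(m$values * 7, m$bins)
  bs <- ice_balance(scaled, tol = 1e-10)
  ratio <- bs$matrix$values / b1$matrix$values
  expect_equal(max(ratio, na.rm = TRUE), min(ratio, na.rm = TRUE),
               tolerance = 1e-6)
})

test_that("expected_by_distance averages unmasked cells per diagonal", {
  m <- contact_matrix(matrix(7, 5, 5), toy_bins(5))
  d <- expected_by_distance(m)
  expect_equal(d$expected, rep(7, 5))

  # banded Toeplitz: values forced by construction
  v <- matrix(0, 4, 4)
  v[abs(row(v) - col(v)) == 0] <- 5
  v[abs(row(v) - col(v)) == 1] <- 3
  v[abs(row(v) - col(v)) == 2] <- 1
  d <- expected_by_distance(contact_matrix(v, toy_bins(4)))
  expect_equal(d$expected, c(5, 3, 1, 0))

  # hand-enumerated masked average: with bin 2 masked, distance-1 pairs
  # (1,2) and (2,3) drop out, leaving cells (3,4)
  v2 <- matrix(c(10, 1, 2, 3,
                 1, 20, 4, 5,
                 2, 4, 30, 6,
                 3, 5, 6, 40), 4)
  dm <- expected_by_distance(contact_matrix(v2, toy_bins(4), mask = 2L))
  expect_equal(dm$expected[2], 6)       # only cell (3,4)
  expect_equal(dm$n_cells[2], 1)
  expect_equal(dm$expected[3], 2)       # only cell (1,3)
})

test_that("observed/expected is unity on Toeplitz input and per-diagonal mean 1", {
  v <- matrix(0, 6, 6)
  for (d in 0:5) v[abs(row(v) - col(v)) == d] <- 10 - d
  oe <- observed_over_expected(contact_matrix(v, toy_bins(6)))
  off <- oe$values[abs(row(oe$values) - col(oe$values)) > 0]
  expect_true(all(abs(off - 1) < 1e-12))
  expect_true(all(is.na(diag(oe$values))))  # diagonal excluded

  m <- sym_count_matrix(15, seed = 21)
  oe <- observed_over_expected(m)
  for (d in 1:10) {
    diag_vals <- oe$values[cbind(1:(15 - d), (1 + d):15)]
    expect_equal(mean(diag_vals), 1, tolerance = 1e-12)
  }
})

test_that("O/E preserves the planted checkerboard sign structure", {
  cfg <- simulation_config(n_bins = 120, total_contacts = 5e5,
                           checkerboard_strength = 0.6, n_boundaries = 0,
                           segmentation = "geometric", block_mean_bins = 15,
                           fine_scale_frac = 0, frac_AB = 0, frac_BA = 0)
  truth <- plant_structure(cfg, seed = 4)
  lam <- expected_rate_matrix(truth, 1)
  oe <- observed_over_expected(contact_matrix(round(lam * 1e4),
                                              toy_bins(120, 40000)))
  s <- truth$sign1
  same <- outer(s, s) > 0
  off <- abs(row(lam) - col(lam)) > 0
  expect_gt(mean(oe$values[same & off]), 1)
  expect_lt(mean(oe$values[!same & off]), 1)
})

test_that("dimension mismatches and multi-chromosome input are rejected", {
  m <- sym_count_matrix(5)
  d <- expected_by_distance(m)
  expect_error(observed_over_expected(sym_count_matrix(6), d), "match")
  layout <- genome_layout(c("a", "b"), c(2e5, 2e5))
  mm <- contact_matrix(matrix(1, 4, 4), make_bins(layout, 1e5))
  expect_error(expected_by_distance(mm), "single-chromosome")
})
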