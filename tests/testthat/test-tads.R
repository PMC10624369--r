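# brute-force community contacts: literal double loop over the square
# cross-boundary window
brute_community <- function(vals, w) {
  nb <- nrow(vals)
  C <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    if (i - w < 1 || i + w > nb) next
    acc <- 0
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) acc <- acc + vals[a, b]
    C[i] <- acc
  }
  C
}

test_that("insulation window sums equal the brute-force double loop exactly", {
  for (seed in 1:3) {
    n <- sample(20:50, 1)
    m <- sym_count_matrix(n, seed = seed)
    m$kind <- "balanced"
    for (w in c(1, 3, 5)) {
      tr <- insulation_score(m, w * 1e5)
      expect_identical(tr$community_contacts, brute_community(m$values, w))
    }
  }
})

test_that("uniform matrices give an identically-zero interior insulation score", {
  m <- contact_matrix(matrix(4, 20, 20), toy_bins(20), kind = "balanced")
  tr <- insulation_score(m, 3e5)
  interior <- tr$score[4:17]
  expect_true(all(abs(interior) < 1e-12))
  expect_true(all(is.na(tr$score[c(1:3, 18:20)])))
})

test_that("perfectly insulated blocks produce a capped valley at the junction", {
  v <- matrix(0, 12, 12)
  v[1:6, 1:6] <- 5
  v[7:12, 7:12] <- 5
  m <- contact_matrix(v, toy_bins(12), kind = "balanced")
  expect_warning(tr <- insulation_score(m, 2e5), "capped")
  # junction bins have zero cross-block contacts in their window
  finite_min <- min(tr$score[!is.na(tr$score) & tr$community_contacts > 0])
  capped <- which(!is.na(tr$score) & tr$community_contacts == 0)
  expect_true(length(capped) > 0)
  expect_equal(unique(tr$score[capped]), finite_min - 1)
  expect_equal(attr(tr, "n_capped"), length(capped))
})

test_that("insulation score is invariant to global matrix scaling", {
  m <- sym_count_matrix(30, seed = 6)
  m$kind <- "balanced"
  m2 <- m
  m2$values <- m$values * 137
  t1 <- insulation_score(m, 3e5)
  t2 <- insulation_score(m2, 3e5)
  expect_equal(t1$score, t2$score, tolerance = 1e-12)
})

test_that("candidate detection finds V valleys and rejects monotone tracks", {
  tr <- make_track(c(3, 2, 1, 2, 3))
  expect_equal(find_candidate_boundaries(tr, 2e5), 3L)
  expect_length(find_candidate_boundaries(make_track(1:8), 2e5), 0)
  # two valleys separated by more than the range
  w <- make_track(c(5, 4, 3, 4, 5, 6, 5, 4, 3.5, 4.5, 5.5))
  expect_equal(find_candidate_boundaries(w, 2e5), c(3L, 9L))
  # plateau minimum resolves to its leftmost bin
  p <- make_track(c(5, 4, 3, 3, 4, 5))
  expect_equal(find_candidate_boundaries(p, 2e5), 3L)
})

test_that("boundary delta and strength follow the flank-mean formulas", {
  tr <- make_track(c(2, 1, 0, 1, 2))
  d <- boundary_delta(tr, 3, 2e5)
  expect_equal(d$mean_left, 1.5)
  expect_equal(d$mean_right, 1.5)
  expect_equal(d$delta, 0)
  expect_equal(d$strength, 1.5)

  flat <- boundary_delta(make_track(rep(2, 5)), 3, 2e5)
  expect_equal(flat$delta, 0)
  expect_equal(flat$strength, 0)

  asym <- boundary_delta(make_track(c(3, 2, 0, 1, 1)), 3, 2e5)
  expect_equal(asym$mean_left, 2.5)
  expect_equal(asym$mean_right, 1.0)
  expect_equal(asym$delta, 1.5)
  expect_equal(asym$strength, 1.75)

  expect_error(boundary_delta(tr, 1, 2e5), "does not fit")
  expect_error(boundary_delta(make_track(c(NA, NA, 0, 1, 2)), 3, 2e5),
               "all-NA flank")
})

test_that("call_boundaries returns nothing on structureless input and filters monotonically", {
  u <- contact_matrix(matrix(3, 40, 40), toy_bins(40, 4e4), kind = "balanced")
  expect_equal(nrow(call_boundaries(u)), 0)
  m <- rate_matrix_as_balanced(
    plant_structure(simulation_config(n_bins = 200, n_boundaries = 2,
                                      fine_scale_frac = 0, flip_min_gap = 2,
                                      boundary_buffer_bins = 5), seed = 2))
  some <- call_boundaries(m)
  expect_gt(nrow(some), 0)
  none <- call_boundaries(m, min_strength = Inf)
  expect_equal(nrow(none), 0)
})

test_that("planted boundaries sit at the insulation minima of the rate model", {
  # no checkerboard: the planted boundary is the only structure, so the
  # global minimum must track it
  cfg <- simulation_config(n_bins = 300, n_boundaries = 1,
                           checkerboard_strength = 0,
                           fine_scale_frac = 0, frac_AB = 0, frac_BA = 0)
  truth <- plant_structure(cfg, seed = 3)
  m <- rate_matrix_as_balanced(truth)
  tr <- insulation_score(m, 2e5)
  expect_lte(abs(which.min(tr$score) - truth$boundaries$bin[1]), 1)

  # translation invariance: moving the boundary moves the minimum with it
  for (shift in c(-30, 40)) {
    truth2 <- truth
    truth2$boundaries$bin <- truth$boundaries$bin + shift
    m2 <- rate_matrix_as_balanced(truth2)
    tr2 <- insulation_score(m2, 2e5)
    expect_lte(abs(which.min(tr2$score) - truth2$boundaries$bin[1]), 1)
  }
})

test_that("directionality index matches its closed form and antisymmetry", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 10
  m <- contact_matrix(v, toy_bins(3))
  di <- directional_index(m, 3e5)
  expect_equal(di, c(10, -10, 0))

  # reflection of the bin order negates the reflected DI track
  r <- sym_count_matrix(25, seed = 14)
  di1 <- directional_index(r, 5e5)
  rev_vals <- r$values[25:1, 25:1]
  di2 <- directional_index(contact_matrix(rev_vals, r$bins), 5e5)
  expect_equal(di1, -rev(di2), tolerance = 1e-12)

  # A == B gives exactly zero
  u <- contact_matrix(matrix(2, 9, 9), toy_bins(9))
  expect_equal(directional_index(u, 2e5)[5], 0)
})

test_that("insulation boundaries lie near DI sign flips on strong-boundary data", {
  cfg <- simulation_config(n_bins = 400, total_contacts = 8e5,
                           n_boundaries = 3, fine_scale_frac = 0)
  ds_truth <- plant_structure(cfg, seed = 5)
  m <- simulate_contact_map(ds_truth, 1, seed = 6)
  bal <- ice_balance(mask_low_coverage(m, 0))$matrix
  bset <- call_boundaries(bal)
  di <- directional_index(bal)
  flips <- di_sign_flips(di)
  near <- vapply(bset$bin, function(b) any(abs(flips - b) <= 2), logical(1))
  expect_gte(mean(near), 0.8)
})

test_that("TAD construction applies the point-split and merge rules", {
  bs <- make_bset(c(11, 21), c(1, 1))   # starts at 1.0 and 2.0 Mb
  tads <- boundaries_to_tads(bs, 3e6)
  expect_equal(tads$start, c(0, 1e6, 2e6))
  expect_equal(tads$end, c(1e6, 2e6, 3e6))
  expect_equal(tads$size, rep(1e6, 3))

  # 200-kb gap < 400 kb: merged into a boundary region, two TADs
  bs2 <- make_bset(c(11, 13), c(1, 1))  # 1.0 and 1.2 Mb
  tads2 <- boundaries_to_tads(bs2, 3e6)
  expect_equal(nrow(tads2), 2)
  expect_equal(tads2$start, c(0, 1.2e6))
  expect_equal(tads2$end, c(1e6, 3e6))
  expect_length(attr(tads2, "boundary_regions"), 1)

  # no boundaries: the whole chromosome is one TAD
  empty <- make_bset(integer(0), numeric(0))
  whole <- boundaries_to_tads(empty, 3e6)
  expect_equal(nrow(whole), 1)
  expect_equal(whole$size, 3e6)
})

test_that("boundary matching is one-to-one with slack dilation", {
  a <- make_bset(c(10, 30, 50), c(1, 1, 1))
  expect_equal(nrow(match_boundaries(a, a)$pairs), 3)
  expect_length(match_boundaries(a, a)$unmatched1, 0)

  b <- make_bset(c(100, 130), c(1, 1))
  far <- match_boundaries(a, b)
  expect_equal(nrow(far$pairs), 0)
  expect_length(far$unmatched1, 3)

  offset <- make_bset(c(11, 31, 51), c(1, 1, 1))
  expect_equal(nrow(match_boundaries(a, offset, slack_bins = 1)$pairs), 3)
  expect_equal(nrow(match_boundaries(a, offset, slack_bins = 0)$pairs), 0)

  wrong <- make_bset(5, 1, bin_size = 5e4)
  expect_error(match_boundaries(a, wrong), "bin-size mismatch")
})

test_that("strength-change classification thresholds and excludes correctly", {
  s1 <- make_bset(c(10, 30, 50, 70), c(1, 1, 1, 0))
  s2 <- make_bset(c(10, 30, 50, 70), c(1, 0.4, 2.0, 1))
  cmp <- match_boundaries(s1, s2)
  out <- classify_boundary_changes(cmp)
  expect_equal(out$n_excluded, 1)        # zero strength1 pair dropped
  expect_equal(out$n_pairs, 3)
  cls <- out$pairs$class[order(out$pairs$bin1)]
  expect_equal(cls, c("stable", "weakened", "strengthened"))
  expect_equal(out$frac_weakened, 1 / 3)

  ident <- classify_boundary_changes(match_boundaries(s1[1:3, ], s1[1:3, ]))
  expect_equal(ident$frac_stable, 1)

  # antisymmetry: swapping conditions exchanges weakened and strengthened
  rev <- classify_boundary_changes(match_boundaries(s2, s1))
  expect_equal(rev$frac_weakened, out$frac_strengthened)
  expect_equal(rev$frac_strengthened, out$frac_weakened)
})

test_that("tad_summary reports counts and quartiles", {
  t1 <- boundaries_to_tads(make_bset(c(11, 21), c(1, 1)), 3e6)
  s <- tad_summary(t1, boundaries_to_tads(make_bset(integer(0), numeric(0)), 3e6))
  expect_equal(s$n_tads, c(3, 1))
  expect_equal(s$median[1], 1e6)
})
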