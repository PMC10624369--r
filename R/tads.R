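#' Insulation score track
#'
#' For each bin i, the community contacts C_i sum the balanced signal in
#' the square window [i-w, i) x (i, i+w] — every contact that crosses bin
#' i within `window_bp`. The insulation score is log2(C_i / mean(C)),
#' where the mean runs over bins with a complete window (truncated-window
#' edge bins and masked bins are NA). A zero C_i (perfect insulation)
#' would give -Inf; it is capped at the finite track minimum minus 1 and
#' flagged.
#'
#' @param matrix a balanced cis [contact_matrix()] at TAD resolution
#'   (40 kb by default elsewhere).
#' @param window_bp window half-width in bp; must be a positive multiple
#'   of the bin size.
#' @return Object of class `insulation_track`: data frame with columns
#'   `chrom, start, end, community_contacts, score`; attributes
#'   `window_bp`, `chrom_mean`, `n_capped`.
#' @export
insulation_score <- function(matrix, window_bp) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (length(unique(matrix$bins$chrom)) > 1) {
    stop("insulation_score requires a single-chromosome (cis) matrix")
  }
  bs <- bin_size_of(matrix$bins)
  w <- window_bp / bs
  if (w <= 0 || abs(w - round(w)) > 1e-9) {
    stop("window_bp must be a positive multiple of the bin size")
  }
  w <- as.integer(round(w))
  nb <- n_bins(matrix)
  C <- rep(NA_real_, nb)
  if (nb <= 2 * w) {
    warning("window larger than chromosome: all-NA insulation track")
  } else {
    vals <- matrix$values
    if (length(matrix$mask) > 0) {
      vals[matrix$mask, ] <- 0
      vals[, matrix$mask] <- 0
    }
    for (i in (w + 1):(nb - w)) {
      C[i] <- sum(vals[(i - w):(i - 1), (i + 1):(i + w)])
    }
    C[matrix$mask] <- NA
  }
  valid <- !is.na(C)
  chrom_mean <- if (any(valid)) mean(C[valid]) else NA_real_
  score <- rep(NA_real_, nb)
  n_capped <- 0L
  if (any(valid) && chrom_mean > 0) {
    score[valid] <- log2(C[valid] / chrom_mean)
    inf <- valid & C == 0
    n_capped <- sum(inf)
    if (n_capped > 0) {
      floor_val <- min(score[valid & C > 0]) - 1
      score[inf] <- floor_val
      warning(sprintf("%d bin(s) with zero community contacts capped", n_capped))
    }
  }
  out <- data.frame(chrom = matrix$bins$chrom, start = matrix$bins$start,
                    end = matrix$bins$end, community_contacts = C,
                    score = score, stringsAsFactors = FALSE)
  attr(out, "window_bp") <- window_bp
  attr(out, "bin_size") <- bs
  attr(out, "chrom_mean") <- chrom_mean
  attr(out, "n_capped") <- n_capped
  class(out) <- c("insulation_track", "data.frame")
  out
}

#' Candidate TAD boundaries from an insulation track
#'
#' A bin is a candidate when the insulation score decreases monotonically
#' into it from `search_range_bp` upstream and increases monotonically away
#' from it downstream. Equal-value plateaus are allowed along the slopes;
#' a plateau at the minimum itself is resolved to its leftmost bin (the
#' entry from the left must be a strict drop).
#'
#' @param track an [insulation_score()] track.
#' @param search_range_bp range checked on each side (default 200 kb).
#' @return Integer vector of candidate bin indices.
#' @export
find_candidate_boundaries <- function(track, search_range_bp = 200000) {
  stopifnot(inherits(track, "insulation_track"))
  bs <- attr(track, "bin_size")
  r <- as.integer(round(search_range_bp / bs))
  if (r < 1) stop("search_range_bp smaller than one bin")
  s <- track$score
  nb <- length(s)
  cand <- integer(0)
  for (i in seq_len(nb)) {
    if (i - r < 1 || i + r > nb) next
    win <- s[(i - r):(i + r)]
    if (any(is.na(win))) next
    left <- diff(s[(i - r):i])
    right <- diff(s[i:(i + r)])
    if (all(left <= 0) && all(right >= 0) &&
        s[i - 1] > s[i] && s[i + r] > s[i]) {
      cand <- c(cand, i)
    }
  }
  cand
}

#' Flank means, delta and strength at a bin
#'
#' Computes the mean insulation score over `flank_bp` upstream (mean_left)
#' and downstream (mean_right) of the bin, excluding the bin itself;
#' delta = mean_left - mean_right, and the valley strength is the average
#' flank level minus the score at the bin.
#'
#' @param track an [insulation_score()] track.
#' @param bin bin index.
#' @param flank_bp flank width in bp (default 100 kb).
#' @return List with `mean_left`, `mean_right`, `delta`, `strength`,
#'   `n_left`, `n_right` (non-NA flank bins used).
#' @export
boundary_delta <- function(track, bin, flank_bp = 100000) {
  stopifnot(inherits(track, "insulation_track"))
  bs <- attr(track, "bin_size")
  f <- as.integer(round(flank_bp / bs))
  nb <- nrow(track)
  if (f < 1) stop("flank_bp smaller than one bin")
  if (bin - f < 1 || bin + f > nb) stop("flank does not fit within the chromosome")
  left <- track$score[(bin - f):(bin - 1)]
  right <- track$score[(bin + 1):(bin + f)]
  if (all(is.na(left)) || all(is.na(right))) stop("all-NA flank at bin ", bin)
  ml <- mean(left, na.rm = TRUE)
  mr <- mean(right, na.rm = TRUE)
  list(mean_left = ml, mean_right = mr, delta = ml - mr,
       strength = (ml + mr) / 2 - track$score[bin],
       n_left = sum(!is.na(left)), n_right = sum(!is.na(right)))
}

#' Call TAD boundaries on one chromosome
#'
#' Pipeline [insulation_score()] -> [find_candidate_boundaries()] ->
#' [boundary_delta()], retaining candidates that pass the filter. The
#' default filter keeps candidates whose valley strength (flank mean minus
#' valley score) reaches `min_strength`; `filter = "delta"` applies the
#' literal |delta| >= min_strength rule instead (that rule rejects
#' perfectly symmetric valleys, where delta is 0 by construction, so
#' strength is the default).
#'
#' @param matrix a balanced cis [contact_matrix()].
#' @param window_bp insulation window (default 200 kb, 5 bins at 40-kb
#'   resolution: narrow enough that the 100-kb flanks sit on the valley
#'   shoulders, so strength reflects valley depth).
#' @param search_range_bp candidate search range (default 200 kb).
#' @param flank_bp delta/strength flank (default 100 kb).
#' @param min_strength retention threshold in log2 units (default 0.1).
#' @param filter `"strength"` (default) or `"delta"`.
#' @param smooth_bins width (odd, in bins) of the running mean applied to
#'   the insulation score before candidate detection; 1 disables. Default
#'   3: single-bin noise bumps break the monotone-slope candidate rule at
#'   shallow valleys, and a minimal running mean removes them without
#'   displacing minima by more than a bin. Delta and strength are always
#'   quantified on the unsmoothed score, so retention and
#'   strength-change classification are not attenuated by the filter.
#' @return Object of class `boundary_set`: data frame with columns
#'   `chrom, bin, start, end, score, mean_left, mean_right, delta,
#'   strength`; the insulation track is attached as attribute `track`.
#' @export
call_boundaries <- function(matrix, window_bp = 200000,
                            search_range_bp = 200000, flank_bp = 100000,
                            min_strength = 0.1,
                            filter = c("strength", "delta"),
                            smooth_bins = 3) {
  filter <- match.arg(filter)
  track <- insulation_score(matrix, window_bp)
  smoothed <- smooth_insulation(track, smooth_bins)
  cand <- find_candidate_boundaries(smoothed, search_range_bp)
  rows <- lapply(cand, function(i) {
    d <- boundary_delta(track, i, flank_bp)
    data.frame(chrom = track$chrom[i], bin = i, start = track$start[i],
               end = track$end[i], score = track$score[i],
               mean_left = d$mean_left, mean_right = d$mean_right,
               delta = d$delta, strength = d$strength,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(0), bin = integer(0), start = numeric(0),
               end = numeric(0), score = numeric(0), mean_left = numeric(0),
               mean_right = numeric(0), delta = numeric(0),
               strength = numeric(0), stringsAsFactors = FALSE)
  keep <- if (filter == "strength") out$strength >= min_strength
          else abs(out$delta) >= min_strength
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "track") <- track
  attr(out, "bin_size") <- attr(track, "bin_size")
  attr(out, "params") <- list(window_bp = window_bp,
                              search_range_bp = search_range_bp,
                              flank_bp = flank_bp,
                              min_strength = min_strength, filter = filter)
  class(out) <- c("boundary_set", "data.frame")
  out
}

#' Directionality index track
#'
#' For each bin, A is the contact sum to bins within `span_bp` upstream
#' and B the sum downstream; with E = (A + B)/2 the DI is
#' sign(B - A) * ((A - E)^2/E + (B - E)^2/E), 0 when A = B.
#' Large positive DI marks downstream preference (domain starts), large
#' negative upstream preference (domain ends); sign flips from negative to
#' positive mark boundaries.
#'
#' @param matrix a cis [contact_matrix()] (raw or balanced).
#' @param span_bp span on each side (default 2 Mb).
#' @return Numeric per-bin DI vector.
#' @export
directional_index <- function(matrix, span_bp = 2000000) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (length(unique(matrix$bins$chrom)) > 1) {
    stop("directional_index requires a single-chromosome (cis) matrix")
  }
  bs <- bin_size_of(matrix$bins)
  s <- max(1L, as.integer(round(span_bp / bs)))
  nb <- n_bins(matrix)
  vals <- matrix$values
  if (length(matrix$mask) > 0) {
    vals[matrix$mask, ] <- 0
    vals[, matrix$mask] <- 0
  }
  di <- numeric(nb)
  for (i in seq_len(nb)) {
    up <- max(1, i - s):(i - 1)
    dn <- (i + 1):min(nb, i + s)
    A <- if (i > 1) sum(vals[i, up]) else 0
    B <- if (i < nb) sum(vals[i, dn]) else 0
    if (A == B) next
    E <- (A + B) / 2
    di[i] <- sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  di[matrix$mask] <- NA
  di
}

#' DI sign-flip boundary loci
#'
#' Bins where the directionality index crosses from negative (upstream
#' preference, domain end) to positive (domain start); used as a
#' cross-check on insulation boundaries.
#'
#' @param di per-bin DI vector from [directional_index()].
#' @param min_abs minimum |DI| on both sides of the flip to suppress noise
#'   crossings (default 0).
#' @return Integer bin indices of upward sign flips.
#' @export
di_sign_flips <- function(di, min_abs = 0) {
  ok <- which(!is.na(di))
  flips <- integer(0)
  for (k in seq_len(length(ok) - 1)) {
    i <- ok[k]; j <- ok[k + 1]
    if (di[i] < -min_abs && di[j] > min_abs) flips <- c(flips, j)
  }
  flips
}

#' Build TADs from a boundary set
#'
#' Boundaries split the chromosome into TADs at their bin-start positions;
#' adjacent boundaries closer than `min_tad_bp` are merged into one
#' extended boundary region, which is excluded from the TAD list rather
#' than reported as a domain. Chromosome ends close the first and last
#' TAD.
#'
#' @param bset a [call_boundaries()] set (one chromosome).
#' @param chrom_length chromosome length in bp.
#' @param min_tad_bp minimum inter-boundary distance (default 400 kb).
#' @return Object of class `tad_set`: data frame `chrom, start, end, size`;
#'   attribute `boundary_regions` lists merged regions.
#' @export
boundaries_to_tads <- function(bset, chrom_length, min_tad_bp = 400000) {
  stopifnot(inherits(bset, "boundary_set"))
  chrom <- if (nrow(bset) > 0) bset$chrom[1] else NA_character_
  pos <- sort(bset$start)
  # merge boundary points closer than min_tad_bp into one region
  regions <- list()
  i <- 1
  while (i <= length(pos)) {
    j <- i
    while (j < length(pos) && pos[j + 1] - pos[j] < min_tad_bp) j <- j + 1
    regions[[length(regions) + 1]] <- c(pos[i], pos[j])
    i <- j + 1
  }
  cuts <- c(0, unlist(regions), chrom_length)
  starts <- cuts[seq(1, length(cuts) - 1, by = 2)]
  ends <- cuts[seq(2, length(cuts), by = 2)]
  keep <- ends > starts
  tads <- data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
                     stringsAsFactors = FALSE)
  tads$size <- tads$end - tads$start
  merged <- Filter(function(r) r[2] > r[1], regions)
  attr(tads, "boundary_regions") <- merged
  class(tads) <- c("tad_set", "data.frame")
  tads
}

#' Match boundaries between two conditions
#'
#' Boundary bin intervals are dilated by `slack_bins` bins on each side;
#' overlapping intervals across conditions are candidate matches, resolved
#' greedily nearest-first into one-to-one pairs.
#'
#' @param set1,set2 [call_boundaries()] sets on the same layout and bin
#'   size.
#' @param slack_bins dilation in bins (default 1).
#' @return Object of class `boundary_comparison`: list with `pairs` (data
#'   frame `chrom, bin1, bin2, start1, start2, strength1, strength2,
#'   log2_ratio`), `unmatched1`, `unmatched2` (row indices into the input
#'   sets).
#' @export
match_boundaries <- function(set1, set2, slack_bins = 1) {
  stopifnot(inherits(set1, "boundary_set"), inherits(set2, "boundary_set"))
  bs1 <- attr(set1, "bin_size"); bs2 <- attr(set2, "bin_size")
  if (!isTRUE(all.equal(bs1, bs2))) stop("bin-size mismatch between boundary sets")
  cand <- NULL
  if (nrow(set1) > 0 && nrow(set2) > 0) {
    for (a in seq_len(nrow(set1))) {
      same <- which(set2$chrom == set1$chrom[a] &
                      abs(set2$bin - set1$bin[a]) <= 2 * slack_bins + 1)
      # dilated bin intervals overlap iff bin distance <= 2*slack + 1... use
      # strict interval overlap on dilated coordinates
      for (b in same) {
        s1 <- set1$start[a] - slack_bins * bs1; e1 <- set1$end[a] + slack_bins * bs1
        s2 <- set2$start[b] - slack_bins * bs1; e2 <- set2$end[b] + slack_bins * bs1
        if (s1 < e2 && s2 < e1) {
          cand <- rbind(cand, data.frame(a = a, b = b,
                                         dist = abs(set1$bin[a] - set2$bin[b])))
        }
      }
    }
  }
  pairs <- data.frame(chrom = character(0), bin1 = integer(0),
                      bin2 = integer(0), start1 = numeric(0),
                      start2 = numeric(0), strength1 = numeric(0),
                      strength2 = numeric(0), log2_ratio = numeric(0),
                      stringsAsFactors = FALSE)
  used1 <- logical(nrow(set1)); used2 <- logical(nrow(set2))
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist, cand$a, cand$b), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      a <- cand$a[k]; b <- cand$b[k]
      if (used1[a] || used2[b]) next
      used1[a] <- TRUE; used2[b] <- TRUE
      lr <- if (set1$strength[a] > 0 && set2$strength[b] > 0) {
        log2(set2$strength[b] / set1$strength[a])
      } else NA_real_
      pairs <- rbind(pairs, data.frame(
        chrom = set1$chrom[a], bin1 = set1$bin[a], bin2 = set2$bin[b],
        start1 = set1$start[a], start2 = set2$start[b],
        strength1 = set1$strength[a], strength2 = set2$strength[b],
        log2_ratio = lr, stringsAsFactors = FALSE))
    }
  }
  structure(list(pairs = pairs,
                 unmatched1 = which(!used1), unmatched2 = which(!used2)),
            class = "boundary_comparison")
}

#' Classify boundary strength changes
#'
#' Per matched pair r = log2(strength2 / strength1); a boundary is
#' weakened when r < -threshold, strengthened when r > +threshold, stable
#' otherwise. Pairs with non-positive strength on either side are excluded
#' and counted.
#'
#' @param cmp a [match_boundaries()] comparison.
#' @param log2_ratio_threshold classification threshold (default
#'   log2(1.25), a 25% strength change).
#' @return List with `frac_weakened`, `frac_strengthened`, `frac_stable`,
#'   `n_pairs` (pairs classified), `n_excluded`, and the per-pair table
#'   with a `class` column.
#' @export
classify_boundary_changes <- function(cmp, log2_ratio_threshold = log2(1.25)) {
  stopifnot(inherits(cmp, "boundary_comparison"))
  p <- cmp$pairs
  ok <- !is.na(p$log2_ratio)
  n_excluded <- sum(!ok)
  p <- p[ok, , drop = FALSE]
  if (nrow(p) == 0) stop("no classifiable boundary pairs")
  p$class <- ifelse(p$log2_ratio < -log2_ratio_threshold, "weakened",
                    ifelse(p$log2_ratio > log2_ratio_threshold,
                           "strengthened", "stable"))
  list(frac_weakened = mean(p$class == "weakened"),
       frac_strengthened = mean(p$class == "strengthened"),
       frac_stable = mean(p$class == "stable"),
       n_pairs = nrow(p), n_excluded = n_excluded, pairs = p)
}

#' Per-condition TAD summary
#'
#' @param tads1,tads2 [boundaries_to_tads()] sets for conditions 1 and 2.
#' @return Data frame with one row per condition: `condition, n_tads,
#'   q25, median, q75` of TAD size in bp.
#' @export
tad_summary <- function(tads1, tads2) {
  one <- function(t, name) {
    if (nrow(t) == 0) {
      return(data.frame(condition = name, n_tads = 0L, q25 = NA_real_,
                        median = NA_real_, q75 = NA_real_))
    }
    q <- stats::quantile(t$size, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(condition = name, n_tads = nrow(t), q25 = q[1], median = q[2],
               q75 = q[3])
  }
  rbind(one(tads1, "cond1"), one(tads2, "cond2"))
}


#' Running-mean smoothing of an insulation track
#'
#' Centred moving average over `width` bins (NA-aware: each bin averages
#' the non-NA scores in its window; bins with all-NA windows stay NA).
#'
#' @param track an [insulation_score()] track.
#' @param width odd window width in bins; 1 returns the track unchanged.
#' @return The track with smoothed `score`.
#' @export
smooth_insulation <- function(track, width = 3) {
  stopifnot(inherits(track, "insulation_track"))
  if (width <= 1) return(track)
  if (width %% 2 == 0) stop("smoothing width must be odd")
  h <- (width - 1) / 2
  s <- track$score
  n <- length(s)
  sm <- vapply(seq_len(n), function(i) {
    win <- s[max(1, i - h):min(n, i + h)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  sm[is.na(s)] <- NA
  track$score <- sm
  attr(track, "smooth_bins") <- width
  track
}
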