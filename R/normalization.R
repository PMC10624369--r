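#' Iterative correction (ICE) of a raw contact matrix
#'
#' Estimates a multiplicative per-bin bias b so that
#' `balanced[i, j] = raw[i, j] / (b[i] * b[j])` has equal marginal sums over
#' all unmasked bins. Biases are reported normalised to geometric mean 1
#' over unmasked bins; masked bins get NA bias and keep their raw values
#' zeroed out of the equal-marginal contract.
#'
#' @param matrix a raw [contact_matrix()], masked bins already identified
#'   (see [mask_low_coverage()]).
#' @param max_iter iteration cap (default 300).
#' @param tol relative tolerance on marginal equality (default 1e-6).
#' @return List with `matrix` (a balanced [contact_matrix()]), `bias`
#'   (numeric vector, NA on masked bins), `converged` (logical) and
#'   `n_iter`.
#' @export
ice_balance <- function(matrix, max_iter = 300, tol = 1e-6) {
  stopifnot(inherits(matrix, "contact_matrix"))
  # zero-marginal bins can never satisfy the equal-marginal contract
  matrix$mask <- sort(union(matrix$mask, which(rowSums(matrix$values) == 0)))
  keep <- unmasked_idx(matrix)
  if (length(keep) < 2) stop("fewer than 2 unmasked bins: cannot balance")
  W <- matrix$values[keep, keep, drop = FALSE]
  nb <- length(keep)
  bias <- rep(1, nb)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    s <- rowSums(W)
    if (all(s == 0)) stop("all unmasked marginals are zero: cannot balance")
    s <- s / mean(s)
    W <- W / outer(s, s)
    bias <- bias * s
    if (max(abs(s - 1)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("ICE did not converge in %d iterations", max_iter))
  }
  # geometric-mean-1 convention; rescales the balanced matrix accordingly
  g <- exp(mean(log(bias)))
  bias <- bias / g
  full_bias <- rep(NA_real_, n_bins(matrix))
  full_bias[keep] <- bias
  vals <- base::matrix(0, n_bins(matrix), n_bins(matrix))
  vals[keep, keep] <- matrix$values[keep, keep] / outer(bias, bias)
  out <- contact_matrix(vals, matrix$bins, kind = "balanced",
                        mask = matrix$mask)
  list(matrix = out, bias = full_bias, converged = converged, n_iter = it)
}

#' Mean contact frequency by genomic distance
#'
#' For a cis matrix, `e(d)` is the mean of `matrix[i, i + d]` over all
#' unmasked pairs at bin distance `d`. The d = 0 (diagonal) value is
#' reported but is dominated by self-ligation artifacts and is excluded
#' from O/E downstream.
#'
#' @param matrix a cis [contact_matrix()].
#' @return Object of class `decay_curve`: data frame with columns `d`
#'   (bin distance, 0-based), `expected`, `n_cells` (contributing unmasked
#'   cells); `expected` is NA where no unmasked cell contributes.
#' @export
expected_by_distance <- function(matrix) {
  stopifnot(inherits(matrix, "contact_matrix"))
  nb <- n_bins(matrix)
  if (nb == 0) stop("empty matrix")
  if (length(unique(matrix$bins$chrom)) > 1) {
    stop("expected_by_distance requires a single-chromosome (cis) matrix")
  }
  ok <- rep(TRUE, nb)
  ok[matrix$mask] <- FALSE
  expected <- rep(NA_real_, nb)
  n_cells <- integer(nb)
  for (d in 0:(nb - 1)) {
    i <- seq_len(nb - d)
    j <- i + d
    use <- ok[i] & ok[j]
    n_cells[d + 1] <- sum(use)
    if (n_cells[d + 1] > 0) {
      expected[d + 1] <- mean(matrix$values[cbind(i[use], j[use])])
    }
  }
  out <- data.frame(d = 0:(nb - 1), expected = expected, n_cells = n_cells)
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Observed/expected transform
#'
#' Divides each cell by the expected value at its genomic distance,
#' removing the distance-decay trend. Cells at distances with zero or
#' undefined expectation, and the diagonal (d = 0), are NA.
#'
#' @param matrix a cis [contact_matrix()].
#' @param decay a [expected_by_distance()] curve; computed from `matrix`
#'   itself when NULL.
#' @param keep_diagonal retain d = 0 in the output (default FALSE).
#' @return An `oe` [contact_matrix()].
#' @export
observed_over_expected <- function(matrix, decay = NULL,
                                   keep_diagonal = FALSE) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (is.null(decay)) decay <- expected_by_distance(matrix)
  nb <- n_bins(matrix)
  if (nrow(decay) != nb) stop("decay curve does not match matrix dimension")
  dmat <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  e <- decay$expected[dmat + 1]
  e[e == 0] <- NA
  vals <- matrix$values / e
  dim(vals) <- c(nb, nb)
  if (!keep_diagonal) diag(vals) <- NA
  if (length(matrix$mask) > 0) {
    vals[matrix$mask, ] <- NA
    vals[, matrix$mask] <- NA
  }
  contact_matrix(vals, matrix$bins, kind = "oe", mask = matrix$mask)
}
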