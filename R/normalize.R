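#' Pooled deconvolution size factors for sparse single-cell counts
#'
#' Estimates per-cell size factors by summing counts over pools of cells
#' (robust to stochastic zeros), taking the median ratio of each pooled
#' profile to an average reference pseudo-cell, and deconvolving the
#' pool-level factors back to cells by least squares. Cells are arranged on
#' a ring ordered by library size so each pool mixes small and large cells;
#' for every cell and every pool size a pool of consecutive ring neighbours
#' contributes one linear equation, and one low-weight augmentation row per
#' cell (tying it to its library-size factor) pins the scale and removes
#' any null space without ridge-penalising the fit.
#'
#' @param counts gene-by-cell count matrix.
#' @param pool_sizes pool sizes; defaults to \code{c(21, 41, 61, 81, 101)}
#'   clipped to \code{ncol(counts) - 1}.
#' @param min_mean genes with average count below this are ignored when
#'   taking medians.
#' @param augment_weight weight of the per-cell library-size augmentation
#'   rows.
#' @return Numeric vector of strictly positive size factors, one per cell,
#'   rescaled to mean 1. Negative least-squares solutions are floored to a
#'   small positive value with a warning.
#' @export
deconvolution_size_factors <- function(counts,
                                       pool_sizes = c(21L, 41L, 61L, 81L, 101L),
                                       min_mean = 0.1,
                                       augment_weight = 0.01) {
  counts <- .check_counts(counts)
  n <- ncol(counts)
  pool_sizes <- unique(pmin(as.integer(pool_sizes), n - 1L))
  pool_sizes <- pool_sizes[pool_sizes >= 1L]
  if (length(pool_sizes) == 0) .stopf("need at least 2 cells")
  keep <- rowMeans(counts) >= min_mean
  if (!any(keep)) .stopf("no genes pass min_mean = %g; cannot normalize", min_mean)
  x <- counts[keep, , drop = FALSE]

  lib <- colSums(x)
  ring <- order(lib)                       # cell order around the ring
  ref <- rowMeans(x)                       # average reference pseudo-cell
  pos <- ref > 0
  x <- x[pos, , drop = FALSE]; ref <- ref[pos]

  # pooled equations: rows of A mark pool membership, b holds the median
  # ratio of the pooled profile to the reference
  n_eq <- n * length(pool_sizes)
  cum <- cbind(x[, ring, drop = FALSE], x[, ring, drop = FALSE])  # unrolled ring
  cum <- t(apply(cum, 1, cumsum))
  ii <- integer(0); jj <- integer(0); bb <- numeric(n_eq)
  row_i <- 0L
  for (ps in pool_sizes) {
    for (start in seq_len(n)) {
      row_i <- row_i + 1L
      members <- ring[((start - 1L) + seq_len(ps) - 1L) %% n + 1L]
      pooled <- if (start == 1L) cum[, ps] else cum[, start + ps - 1L] - cum[, start - 1L]
      bb[row_i] <- median(pooled / ref)
      ii <- c(ii, rep(row_i, ps)); jj <- c(jj, members)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n_eq, n))
  # augmentation: weight * t_c = weight * libsize factor
  lib_factor <- lib / mean(lib)
  A <- rbind(A, augment_weight * Matrix::Diagonal(n))
  b <- c(bb, augment_weight * lib_factor)

  sol <- Matrix::solve(Matrix::crossprod(A), Matrix::crossprod(A, b))
  sf <- as.numeric(sol)
  if (any(sf <= 0)) {
    .warnf("%d non-positive deconvolved factor(s) floored to 1e-8", sum(sf <= 0))
    sf[sf <= 0] <- 1e-8
  }
  sf <- sf / mean(sf)
  names(sf) <- colnames(counts)
  sf
}

#' Library-size factors
#'
#' Per-cell total counts rescaled to mean 1; the baseline the deconvolution
#' estimator refines.
#'
#' @param counts gene-by-cell count matrix.
#' @return Positive numeric vector, mean 1.
#' @export
library_size_factors <- function(counts) {
  counts <- .check_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) .stopf("cells with zero total count cannot be normalized")
  setNames(lib / mean(lib), colnames(counts))
}

#' Log-normalize counts with size factors
#'
#' Returns \code{log2(count / sf + pseudocount)} per entry; non-negative
#' whenever \code{pseudocount >= 1}.
#'
#' @param counts gene-by-cell count matrix.
#' @param sf per-cell size factors (positive).
#' @param pseudocount positive offset added before the log (default 1).
#' @return Numeric matrix of the same shape.
#' @export
log_normalize <- function(counts, sf, pseudocount = 1) {
  counts <- .check_counts(counts)
  if (pseudocount <= 0) .stopf("pseudocount must be positive")
  if (length(sf) != ncol(counts)) .stopf("need one size factor per cell")
  if (any(sf <= 0)) .stopf("size factors must be strictly positive")
  log2(sweep(counts, 2, sf, "/") + pseudocount)
}
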