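# Multivariate distance correlation with the unbiased (U-centered)
# estimator. Observations are time points (or trials); each observation is
# the multi-voxel pattern of one region, so dependence is assessed on whole
# voxel patterns rather than on a region-average series.

# U-centering of a T x T distance matrix (unbiased estimator):
# for i != j, U_ij = d_ij - rowsum_i/(n-2) - colsum_j/(n-2)
#                  + total/((n-1)(n-2)); diagonal 0.
u_center <- function(D) {
  n <- nrow(D)
  if (n < 4L) stop("U-centering requires at least 4 observations")
  rs <- rowSums(D)
  U <- D - rs / (n - 2) - rep(rs / (n - 2), each = n) + sum(D) / ((n - 1) * (n - 2))
  diag(U) <- 0
  U
}

# Inner product of two U-centered matrices -> unbiased dCov^2.
dcov2_u <- function(U, V) {
  n <- nrow(U)
  sum(U * V) / (n * (n - 3))
}

#' Distance-correlation statistics between two multi-voxel series
#'
#' Pairwise Euclidean distances between the T observation patterns of each
#' series are U-centered and combined into the unbiased distance covariance
#' and variances. The squared unbiased dCov can be negative; it is clipped at
#' 0 before the square root. When either distance variance is nonpositive
#' (a constant pattern), the correlation is 0 by convention.
#'
#' @param X,Y voxels x T matrices with the same T (>= 4).
#' @return list(dcor, dcov2, dvar_x, dvar_y).
#' @export
dcor_stats <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must share the observation count")
  n <- ncol(X)
  if (n < 4L) stop("need at least 4 observations")
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("non-finite inputs")
  A <- u_center(as.matrix(dist(t(X))))
  B <- u_center(as.matrix(dist(t(Y))))
  dcov2 <- dcov2_u(A, B)
  dvar_x <- dcov2_u(A, A)
  dvar_y <- dcov2_u(B, B)
  dcor <- if (dvar_x <= 0 || dvar_y <= 0) 0 else {
    sqrt(max(dcov2, 0) / sqrt(dvar_x * dvar_y))
  }
  list(dcor = min(dcor, 1), dcov2 = dcov2, dvar_x = dvar_x, dvar_y = dvar_y)
}

#' Distance correlation between two multi-voxel series
#'
#' @inheritParams dcor_stats
#' @return scalar in [0, 1].
#' @export
distance_correlation <- function(X, Y) {
  dcor_stats(X, Y)$dcor
}
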