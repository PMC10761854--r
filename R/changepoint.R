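# Change-point significance thresholding: the map's values are sorted and a
# single split minimizing the summed within-segment squared error is found;
# the first value of the upper segment becomes the significance threshold.

#' Change-point threshold of a sorted value vector
#'
#' Sorts the finite values ascending and finds the split index k (1 <= k < n)
#' minimizing SSE(left segment about its mean) + SSE(right segment about its
#' mean), by exhaustive search in O(n) via prefix sums. The threshold is the
#' sorted value at the first element of the right segment, so the detected
#' high segment itself survives thresholding. Ties take the smallest k.
#'
#' When all values are identical there is no change point: the result is
#' flagged degenerate with threshold +Inf (nothing survives).
#'
#' @param values numeric vector (>= 3 finite values).
#' @return list(threshold, change_index, degenerate, sse), where
#'   `change_index` is the size of the lower segment.
#' @export
changepoint_threshold <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite values")
  x <- sort(x)
  if (x[n] == x[1]) {
    return(list(threshold = Inf, change_index = NA_integer_,
                degenerate = TRUE, sse = NA_real_))
  }
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq_len(n - 1L)
  nr <- n - k
  sse_l <- cs2[k] - cs[k]^2 / k
  sse_r <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / nr
  sse <- sse_l + sse_r
  kbest <- which.min(sse)
  list(threshold = x[kbest + 1L], change_index = kbest,
       degenerate = FALSE, sse = sse[kbest])
}

#' Apply a threshold to a variance map
#'
#' Voxels whose value is at least the threshold are kept; all others
#' (including voxels where the statistic is undefined) are set to 0. The
#' threshold is recorded on the result. A +Inf threshold (degenerate change
#' point) yields an all-zero map.
#'
#' @param vmap a `variance_map`.
#' @param threshold scalar (finite or +Inf sentinel).
#' @return the thresholded `variance_map`.
#' @export
apply_threshold <- function(vmap, threshold) {
  stopifnot(length(threshold) == 1L, !is.na(threshold))
  v <- vmap$values
  v[is.na(v) | v < threshold] <- 0
  variance_map(v, vmap$kind, vmap$geometry, threshold = threshold,
               mask = vmap$mask)
}

#' Change-point threshold a variance map
#'
#' Convenience wrapper: fits [changepoint_threshold()] to the map's defined
#' voxel values and applies it.
#'
#' @param vmap a `variance_map`.
#' @return the thresholded `variance_map`; the fit is attached as attribute
#'   "changepoint".
#' @export
threshold_variance_map <- function(vmap) {
  cp <- changepoint_threshold(as.numeric(vmap$values))
  out <- apply_threshold(vmap, cp$threshold)
  attr(out, "changepoint") <- cp
  out
}
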