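# Series cleaning: nuisance regression, zero-phase bandpass, truncation and
# z-normalization. Series are voxels x observations matrices.

#' Regress confounds out of a multi-voxel series
#'
#' Replaces each voxel series by its least-squares residual against the
#' confound design (an intercept is always included). Rank-deficient designs
#' drop the offending columns with a warning naming them.
#'
#' @param series voxels x T matrix.
#' @param confounds T x p matrix or data.frame of confound series.
#' @return residual series, same dims as the input.
#' @export
regress_confounds <- function(series, confounds) {
  series <- as.matrix(series)
  X <- cbind(intercept = 1, as.matrix(confounds))
  if (nrow(X) != ncol(series)) {
    stop("confound rows must align with series observations")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning("rank-deficient confound design; dropping: ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  t(qr.resid(qrX, t(series)))
}

#' Zero-phase bandpass filter
#'
#' Attenuates frequency content outside `[f_min, f_max]` Hz with a
#' Butterworth filter of the given order applied forwards and backwards
#' (`signal::filtfilt`), hence zero phase.
#'
#' @param series voxels x T matrix (or a numeric vector).
#' @param tr_seconds sampling interval, s.
#' @param f_min,f_max passband edges, Hz; `0 <= f_min < f_max < ` Nyquist.
#' @param order Butterworth order (default 2; the effective order doubles
#'   under forward-backward filtering).
#' @return filtered series, same shape.
#' @export
bandpass <- function(series, tr_seconds, f_min, f_max, order = 2) {
  vec <- is.null(dim(series))
  m <- if (vec) matrix(series, nrow = 1L) else as.matrix(series)
  fs <- 1 / tr_seconds
  ny <- fs / 2
  if (!(f_min >= 0 && f_min < f_max && f_max < ny)) {
    stop("need 0 <= f_min < f_max < Nyquist (", signif(ny, 4), " Hz)")
  }
  n_t <- ncol(m)
  warmup <- 3 * (2 * order + 1)
  if (n_t <= warmup) stop("series too short for the filter warm-up")
  bf <- signal::butter(order, c(f_min, f_max) / ny, type = "pass")
  # remove the DC component exactly; it lies outside any passband and would
  # otherwise leave boundary transients under forward-backward filtering
  mu <- rowMeans(m)
  out <- t(apply(m - mu, 1L, function(x) signal::filtfilt(bf, x)))
  if (vec) as.numeric(out) else out
}

#' Truncate a resting series to its first n volumes
#'
#' @param series voxels x T matrix.
#' @param n volumes to keep (default 316).
#' @return voxels x n matrix.
#' @export
truncate_rest <- function(series, n = 316) {
  series <- as.matrix(series)
  if (ncol(series) < n) {
    stop("series has ", ncol(series), " observations; cannot truncate to ", n)
  }
  series[, seq_len(n), drop = FALSE]
}

#' Z-normalize each voxel series
#'
#' Each voxel's series is centred and scaled to unit sample SD (denominator
#' T - 1) across observations. Zero-variance voxels are dropped with a
#' warning; an all-zero-variance input is an error.
#'
#' @param series voxels x T matrix.
#' @return normalized series (possibly fewer rows).
#' @export
znormalize <- function(series) {
  series <- as.matrix(series)
  mu <- rowMeans(series)
  sds <- apply(series, 1L, sd)
  keep <- sds > 0
  if (!any(keep)) stop("all voxels have zero variance")
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " zero-variance voxel(s)")
  }
  (series[keep, , drop = FALSE] - mu[keep]) / sds[keep]
}

#' Clean a ROV series set
#'
#' Applies the configured cleaning chain to every subject and ROV, in the
#' order: confound regression, bandpass, truncation, z-normalization.
#' Defaults by state: resting series get the full chain (band 0.009-0.08 Hz);
#' task beta-series get z-normalization only (their nuisance structure is
#' removed upstream of beta estimation). Every step is switchable.
#'
#' @param series_set a `roi_series_set`.
#' @param confounds list of per-subject confound tables (required when
#'   `regress = TRUE`).
#' @param regress run confound regression (default: state == "rest").
#' @param do_bandpass run the bandpass (default: state == "rest").
#' @param f_min,f_max passband, Hz (defaults 0.009 and 0.08 for rest, 0.25
#'   upper edge for task).
#' @param truncate_to volumes to keep; NULL takes the state default (316 for
#'   rest, none for task), NA skips truncation.
#' @param znorm z-normalize (default TRUE).
#' @return the cleaned `roi_series_set`; the applied steps are recorded in
#'   the `cleaning` field.
#' @export
clean_roi_series <- function(series_set, confounds = NULL,
                             regress = NULL, do_bandpass = NULL,
                             f_min = 0.009, f_max = NULL,
                             truncate_to = NULL, znorm = TRUE) {
  rest <- series_set$state == "rest"
  if (is.null(regress)) regress <- rest
  if (is.null(do_bandpass)) do_bandpass <- rest
  if (is.null(f_max)) f_max <- if (rest) 0.08 else 0.25
  if (is.null(truncate_to)) truncate_to <- if (rest) 316L else NA
  if (regress && is.null(confounds)) {
    stop("confound tables required for confound regression")
  }
  out <- series_set
  out$subjects <- lapply(seq_along(series_set$subjects), function(i) {
    lapply(series_set$subjects[[i]], function(m) {
      if (regress) m <- regress_confounds(m, confounds[[i]])
      if (do_bandpass) m <- bandpass(m, series_set$tr_seconds, f_min, f_max)
      if (!is.na(truncate_to)) m <- truncate_rest(m, truncate_to)
      if (znorm) m <- znormalize(m)
      m
    })
  })
  out$cleaning <- list(regress = regress, bandpass = do_bandpass,
                       f_min = f_min, f_max = f_max,
                       truncate_to = truncate_to, znorm = znorm,
                       filter = "butterworth order 2, zero-phase")
  out
}
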