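# ROV markers and brain-behavior correlation with outlier replacement,
# covariate control and Bonferroni correction.

#' Extract per-subject ROV markers
#'
#' Per subject and ROV, the mean of the volume over the ROV's member voxels:
#' mean contrast beta for functional ROVs, mean GM volume for structural
#' ROVs.
#'
#' @param volumes list over subjects of 3-D arrays or `subject_contrast`
#'   objects (whose `con` field is used).
#' @param rovs list of `rov` defined on the same grid.
#' @return subjects x ROVs numeric matrix, columns named by ROV label.
#' @export
extract_markers <- function(volumes, rovs) {
  vols <- lapply(volumes, function(v) {
    if (inherits(v, "subject_contrast")) v$con else v
  })
  d <- dim(vols[[1]])
  nvox <- prod(d)
  for (r in rovs) {
    if (max(r$voxel_ids) > nvox) stop("ROV ", r$label, " outside volume coverage")
  }
  m <- matrix(NA_real_, nrow = length(vols), ncol = length(rovs),
              dimnames = list(NULL, vapply(rovs, `[[`, character(1), "label")))
  for (j in seq_along(rovs)) {
    m[, j] <- vapply(vols, function(v) mean(v[rovs[[j]]$voxel_ids]), numeric(1))
  }
  m
}

#' Clean behavioral scores
#'
#' Reports a Shapiro-Wilk normality statistic (not enforced) and replaces
#' outliers - values more than `z_threshold` sample SDs from the mean - by
#' the mean of the remaining values. Aborts when more than
#' `max_outlier_frac` of the values are outliers.
#'
#' @param scores numeric vector (n >= 8).
#' @param z_threshold outlier criterion on |z| (default 3).
#' @param max_outlier_frac abort threshold on the outlier fraction.
#' @return cleaned scores with attributes `n_replaced`, `shapiro_w`,
#'   `shapiro_p`.
#' @export
clean_scores <- function(scores, z_threshold = 3, max_outlier_frac = 0.2) {
  n <- length(scores)
  if (n < 8L) stop("need at least 8 scores")
  if (!all(is.finite(scores))) stop("scores must be finite")
  sw <- tryCatch(shapiro.test(scores),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  s <- sd(scores)
  out <- if (s == 0) rep(FALSE, n) else {
    abs((scores - mean(scores)) / s) > z_threshold
  }
  if (mean(out) > max_outlier_frac) {
    stop(sprintf("%d of %d values (%.0f%%) flagged as outliers; aborting",
                 sum(out), n, 100 * mean(out)))
  }
  cleaned <- scores
  if (any(out)) cleaned[out] <- mean(scores[!out])
  attr(cleaned, "n_replaced") <- sum(out)
  attr(cleaned, "shapiro_w") <- unname(sw$statistic)
  attr(cleaned, "shapiro_p") <- sw$p.value
  cleaned
}

# First-order partial Pearson correlation of x and y given c.
partial_cor <- function(x, y, covar) {
  rxy <- cor(x, y)
  rxc <- cor(x, covar)
  ryc <- cor(y, covar)
  (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
}

#' Correlate ROV markers with behavioral scores
#'
#' Pearson correlation of every marker-score pair; when a covariate is
#' supplied, the first-order partial correlation controlling for it. Two-sided
#' p values from the t transform (df = n - 2, or n - 3 with a covariate) and
#' Bonferroni correction `p_bonferroni = min(1, p_raw * family_size)`.
#'
#' @param markers subjects x markers matrix (named columns).
#' @param scores subjects x scores matrix/data.frame (named columns) or a
#'   vector.
#' @param covariate optional numeric vector (e.g. brain size).
#' @param family_size Bonferroni family (default markers x scores).
#' @return data.frame(marker, score, n, r, p_raw, p_bonferroni).
#' @export
marker_correlations <- function(markers, scores, covariate = NULL,
                                family_size = NULL) {
  markers <- as.matrix(markers)
  if (is.null(colnames(markers))) {
    colnames(markers) <- sprintf("marker%02d", seq_len(ncol(markers)))
  }
  if (is.null(dim(scores))) scores <- matrix(scores, dimnames = list(NULL, "score"))
  scores <- as.matrix(scores)
  stopifnot(nrow(markers) == nrow(scores))
  if (!is.null(covariate)) stopifnot(length(covariate) == nrow(markers))
  if (is.null(family_size)) family_size <- ncol(markers) * ncol(scores)
  rows <- list()
  for (j in seq_len(ncol(markers))) {
    x <- markers[, j]
    if (sd(x) == 0) stop("zero-variance marker: ", colnames(markers)[j])
    for (s in seq_len(ncol(scores))) {
      y <- scores[, s]
      cc <- complete.cases(x, y, if (is.null(covariate)) rep(0, length(x)) else covariate)
      if (sum(cc) < 4L) stop("fewer than 4 complete cases")
      n <- sum(cc)
      if (is.null(covariate)) {
        r <- cor(x[cc], y[cc])
        df <- n - 2L
      } else {
        r <- partial_cor(x[cc], y[cc], covariate[cc])
        df <- n - 3L
      }
      t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
      p <- 2 * pt(-abs(t_stat), df = df)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = colnames(markers)[j], score = colnames(scores)[s],
        n = n, r = r, p_raw = p,
        p_bonferroni = min(1, p * family_size))
    }
  }
  do.call(rbind, rows)
}
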