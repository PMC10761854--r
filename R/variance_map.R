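# Cohort-level variance maps: between/within-subject variance, the F ratio,
# across-subject GM SD, and the group one-sample t mask.

#' Variance map container
#'
#' @param values 3-D array (F ratio or SD; NA marks voxels where the
#'   statistic is undefined).
#' @param kind "functional_F" or "structural_SD".
#' @param geometry a `vol_geometry`.
#' @param threshold scalar recorded after thresholding (NULL before).
#' @param mask binary 3-D array recorded after masking (NULL before).
#' @return an object of class `variance_map`.
#' @export
variance_map <- function(values, kind = c("functional_F", "structural_SD"),
                         geometry, threshold = NULL, mask = NULL) {
  kind <- match.arg(kind)
  if (any(values < 0, na.rm = TRUE)) stop(kind, " values must be nonnegative")
  structure(list(values = values, kind = kind, geometry = geometry,
                 threshold = threshold, mask = mask),
            class = "variance_map")
}

#' @export
print.variance_map <- function(x, ...) {
  nz <- sum(x$values > 0, na.rm = TRUE)
  cat(sprintf("<variance_map:%s> %s voxels, %d nonzero%s%s\n", x$kind,
              paste(dim(x$values), collapse = "x"), nz,
              if (!is.null(x$threshold)) sprintf(", threshold %.4g", x$threshold) else "",
              if (!is.null(x$mask)) ", masked" else ""))
  invisible(x)
}

# Stack a contrast cohort into an n_subjects x n_voxels matrix after
# validating shared geometry and scan count.
stack_cohort <- function(cohort, field = "con") {
  stopifnot(length(cohort) >= 2L)
  geom <- cohort[[1]]$geometry
  ns <- cohort[[1]]$n_scans
  for (s in cohort) {
    if (!same_geometry(s$geometry, geom)) stop("mismatched volume dims across subjects")
    if (s$n_scans != ns) stop("mismatched n_scans across subjects")
  }
  m <- do.call(rbind, lapply(cohort, function(s) as.numeric(s[[field]])))
  list(m = m, geometry = geom, n_scans = ns)
}

#' Between-subject variance map
#'
#' Per voxel, the across-subject sample variance of the contrast divided by 2
#' and multiplied by the scan count:
#' `S_B^2 = [ (1/(NSubj-1)) * sum_i (con_i - mean(con))^2 ] / 2 * NScan`.
#' `scale_by_scans = FALSE` drops the `/2 * NScan` factor for sensitivity
#' analyses and returns the plain sample variance.
#'
#' @param cohort list of `subject_contrast` sharing dims and n_scans.
#' @param scale_by_scans apply the `/2 * NScan` factor (default TRUE).
#' @return 3-D array of S_B^2 with a `geometry` attribute.
#' @export
between_subject_variance <- function(cohort, scale_by_scans = TRUE) {
  st <- stack_cohort(cohort, "con")
  n <- nrow(st$m)
  mu <- colMeans(st$m)
  ss <- colSums((st$m - rep(mu, each = n))^2) / (n - 1)
  if (scale_by_scans) ss <- ss / 2 * st$n_scans
  out <- array(ss, dim = st$geometry$dims)
  attr(out, "geometry") <- st$geometry
  out
}

#' Within-subject variance map
#'
#' Per voxel, `S_W^2 = mean_i(ResMS_i) / (NScan - 1)`.
#'
#' @inheritParams between_subject_variance
#' @return 3-D array of S_W^2 with a `geometry` attribute.
#' @export
within_subject_variance <- function(cohort) {
  st <- stack_cohort(cohort, "resms")
  if (st$n_scans < 2L) stop("n_scans must be >= 2")
  out <- array(colMeans(st$m) / (st$n_scans - 1), dim = st$geometry$dims)
  attr(out, "geometry") <- st$geometry
  out
}

#' Between- to within-subject variance ratio (F) map
#'
#' `F = S_B^2 / S_W^2` voxelwise. Voxels with `S_W^2 = 0` are set to NA
#' (undefined, excluded from thresholding) rather than +Inf.
#'
#' @inheritParams between_subject_variance
#' @return a `variance_map` of kind "functional_F".
#' @export
f_ratio_map <- function(cohort, scale_by_scans = TRUE) {
  sb2 <- between_subject_variance(cohort, scale_by_scans = scale_by_scans)
  sw2 <- within_subject_variance(cohort)
  f <- sb2 / sw2
  f[sw2 == 0] <- NA_real_
  geom <- attr(sb2, "geometry")
  attr(f, "geometry") <- NULL
  variance_map(f, "functional_F", geom)
}

#' Across-subject SD map of grey-matter volume
#'
#' Per voxel, the sample standard deviation (denominator NSubj - 1) of the GM
#' value across subjects.
#'
#' @param gm_cohort list of 3-D arrays sharing dims (as from
#'   [gen_gm_cohort()]).
#' @param geometry a `vol_geometry`; defaults to the maps' own attribute.
#' @return a `variance_map` of kind "structural_SD".
#' @export
sd_map <- function(gm_cohort, geometry = attr(gm_cohort[[1]], "geometry")) {
  stopifnot(length(gm_cohort) >= 2L)
  d <- dim(gm_cohort[[1]])
  for (g in gm_cohort) {
    if (!identical(dim(g), d)) stop("mismatched volume dims across subjects")
  }
  if (is.null(geometry)) geometry <- vol_geometry(d)
  m <- do.call(rbind, lapply(gm_cohort, as.numeric))
  n <- nrow(m)
  mu <- colMeans(m)
  v <- colSums((m - rep(mu, each = n))^2) / (n - 1)
  variance_map(array(sqrt(v), dim = d), "structural_SD", geometry)
}

#' Group one-sample t map with voxelwise FWE and cluster-size filtering
#'
#' Voxelwise one-sample t of the contrast against 0 (df = NSubj - 1,
#' one-sided activation tail), Bonferroni family-wise error control at `alpha`
#' over the in-analysis voxels, 26-connected components of the survivors, and
#' removal of components smaller than `min_cluster_size`. Voxels with zero
#' across-subject variance are excluded (their count is recorded).
#'
#' @param cohort list of `subject_contrast` (>= 3 subjects).
#' @param alpha family-wise error level.
#' @param min_cluster_size minimum surviving cluster extent, voxels.
#' @return an object of class `group_tmap`: list(t_values, df, binary_mask,
#'   alpha, min_cluster_size, n_excluded, geometry).
#' @export
group_tmap <- function(cohort, alpha = 0.05, min_cluster_size = 10) {
  stopifnot(length(cohort) >= 3L)
  st <- stack_cohort(cohort, "con")
  n <- nrow(st$m)
  mu <- colMeans(st$m)
  s <- sqrt(colSums((st$m - rep(mu, each = n))^2) / (n - 1))
  ok <- s > 0
  n_excluded <- sum(!ok)
  tvals <- rep(NA_real_, length(mu))
  tvals[ok] <- mu[ok] / (s[ok] / sqrt(n))
  n_test <- sum(ok)
  sig <- rep(FALSE, length(mu))
  if (n_test > 0L) {
    p <- pt(tvals[ok], df = n - 1, lower.tail = FALSE)
    sig[ok] <- p <= alpha / n_test
  }
  sig_arr <- array(sig, dim = st$geometry$dims)
  lab <- label_components(sig_arr)
  mask <- array(0L, dim = st$geometry$dims)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_cluster_size)
    mask[lab %in% keep] <- 1L
  }
  structure(list(t_values = array(tvals, dim = st$geometry$dims),
                 df = n - 1L, binary_mask = mask, alpha = alpha,
                 min_cluster_size = as.integer(min_cluster_size),
                 n_excluded = n_excluded, geometry = st$geometry),
            class = "group_tmap")
}

#' Restrict a variance map to a group mask
#'
#' Sets values outside the binary mask to 0 and records the mask on the
#' result.
#'
#' @param vmap a `variance_map`.
#' @param tmap a `group_tmap` (or a binary array of the same dims).
#' @return the masked `variance_map`.
#' @export
mask_variance_map <- function(vmap, tmap) {
  mask <- if (inherits(tmap, "group_tmap")) tmap$binary_mask else tmap
  if (!identical(dim(mask), dim(vmap$values))) stop("mismatched dims")
  v <- vmap$values
  v[mask == 0L] <- 0
  variance_map(v, vmap$kind, vmap$geometry, threshold = vmap$threshold,
               mask = mask)
}
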