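#' Volume geometry
#'
#' Minimal description of a regular 3-D voxel grid: dimensions, isotropic voxel
#' size in mm and the mm coordinate of the first voxel centre. The affine is
#' diagonal: `mm = (ijk - 1) * voxel_size_mm + origin_mm` for 1-based voxel
#' indices `ijk`.
#'
#' @param dims integer vector of 3 voxel counts.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param origin_mm mm coordinate of voxel (1,1,1); default centres the grid
#'   on (0,0,0).
#' @return an object of class `vol_geometry`.
#' @export
vol_geometry <- function(dims, voxel_size_mm = 3, origin_mm = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), voxel_size_mm > 0)
  if (is.null(origin_mm)) origin_mm <- -(dims - 1) * voxel_size_mm / 2
  stopifnot(length(origin_mm) == 3L)
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "vol_geometry")
}

#' Standard 3 mm MNI-like grid
#'
#' A 61 x 73 x 61 grid at 3 mm whose mm frame matches the usual MNI152
#' bounding box (first voxel centre at (-90, -126, -72) mm), so published peak
#' coordinates can be mapped to voxels directly.
#'
#' @return a `vol_geometry`.
#' @export
mni_geometry <- function() {
  vol_geometry(c(61L, 73L, 61L), 3, c(-90, -126, -72))
}

#' @export
print.vol_geometry <- function(x, ...) {
  cat(sprintf("<vol_geometry> %d x %d x %d voxels @ %g mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_mm,
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Convert voxel indices to mm coordinates
#'
#' @param geometry a `vol_geometry`.
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates of the voxel centres.
#' @export
vox_to_mm <- function(geometry, ijk) {
  ijk <- rbind_coords(ijk)
  sweep((ijk - 1) * geometry$voxel_size_mm, 2, geometry$origin_mm, "+")
}

#' Convert mm coordinates to nearest voxel indices
#'
#' @param geometry a `vol_geometry`.
#' @param mm n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return n x 3 integer matrix of 1-based voxel indices.
#' @export
mm_to_vox <- function(geometry, mm) {
  mm <- rbind_coords(mm)
  ijk <- sweep(mm, 2, geometry$origin_mm, "-") / geometry$voxel_size_mm
  matrix(as.integer(round(ijk)) + 1L, ncol = 3L)
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == 3L)
  x
}

# Per-axis vectors of voxel-centre mm coordinates.
axis_coords <- function(geometry) {
  lapply(1:3, function(a) {
    geometry$origin_mm[a] + (seq_len(geometry$dims[a]) - 1) * geometry$voxel_size_mm
  })
}

# Squared Euclidean mm distance from every voxel centre to a point, as a 3-D
# array matching the grid.
dist2_to_point <- function(geometry, center_mm) {
  ax <- axis_coords(geometry)
  dx2 <- (ax[[1]] - center_mm[1])^2
  dy2 <- (ax[[2]] - center_mm[2])^2
  dz2 <- (ax[[3]] - center_mm[3])^2
  d <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(d, dim = geometry$dims)
}

n_voxels <- function(geometry) prod(geometry$dims)

same_geometry <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}
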