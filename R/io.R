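# Thin NIfTI-1 and table IO around the in-memory containers.

#' Write a volume as NIfTI-1
#'
#' @param x 3-D array.
#' @param geometry a `vol_geometry` (sets the voxel size; the mm frame is the
#'   package's diagonal affine).
#' @param path output file (.nii or .nii.gz).
#' @export
write_volume <- function(x, geometry, path) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep(geometry$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path input file.
#' @return 3-D array with a `geometry` attribute built from the pixdim.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "geometry") <- vol_geometry(dim(arr), RNifti::pixdim(img)[1])
  arr
}

#' Write a contrast cohort as NIfTI-1 volumes
#'
#' One `con` and one `resms` file per subject, plus a JSON sidecar with the
#' scan count.
#'
#' @param cohort list of `subject_contrast`.
#' @param dir output directory (created if needed).
#' @export
write_contrast_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    write_volume(s$con, s$geometry, file.path(dir, sprintf("con_sub%03d.nii.gz", i)))
    write_volume(s$resms, s$geometry, file.path(dir, sprintf("resms_sub%03d.nii.gz", i)))
  }
  jsonlite::write_json(list(n_subjects = length(cohort),
                            n_scans = cohort[[1]]$n_scans),
                       file.path(dir, "cohort.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a network cohort as tab-delimited matrices
#'
#' One K x K table per subject plus a JSON header (state, node order).
#'
#' @param nets list of K x K matrices.
#' @param dir output directory.
#' @param state "task" or "rest".
#' @export
write_networks <- function(nets, dir, state = attr(nets[[1]], "state")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(nets)) {
    if (is.null(nets[[i]])) next
    write.table(nets[[i]], file.path(dir, sprintf("net_sub%03d.tsv", i)),
                sep = "\t", quote = FALSE)
  }
  jsonlite::write_json(list(state = state, nodes = rownames(nets[[1]]),
                            n_subjects = length(nets)),
                       file.path(dir, "networks.json"), auto_unbox = TRUE)
  invisible(dir)
}
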