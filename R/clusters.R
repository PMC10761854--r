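# Connected-component cluster extraction from thresholded maps
# (26-connectivity, the SPM cluster convention).

# Label the 26-connected components of a logical 3-D array. Returns an
# integer array of the same dims: 0 = background, 1..n = component labels.
label_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  dims <- dim(mask)
  idx <- which(mask != 0)
  lab <- array(0L, dim = dims)
  if (length(idx) == 0L) return(lab)
  vmap <- integer(prod(dims))
  vmap[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, dims)
  # 13 half-neighbourhood offsets (the other 13 are their negations)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
              (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(ijk, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
              (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    hit <- vmap[nb_lin] > 0L
    if (!any(hit)) next
    edges <- rbind(edges, cbind(vmap[idx[ok][hit]], vmap[nb_lin[hit]]))
  }
  if (is.null(edges)) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, as.vector(t(edges)))
    memb <- igraph::components(g)$membership
  }
  lab[idx] <- as.integer(memb)
  lab
}

#' Extract clusters from a thresholded variance map
#'
#' 26-connected components of the nonzero voxels with at least `min_size`
#' members. Each cluster carries its peak voxel (maximum value; ties broken by
#' lowest linear voxel index) converted to mm through the grid geometry.
#' Clusters are returned sorted by descending peak value.
#'
#' @param vmap a `variance_map` (thresholded: zeros are background).
#' @param min_size minimum cluster extent, voxels.
#' @return list of clusters, each list(voxel_ids, size, peak_value, peak_mm);
#'   empty list for an empty map.
#' @export
extract_clusters <- function(vmap, min_size = 10) {
  v <- vmap$values
  mask <- !is.na(v) & v > 0
  lab <- label_components(mask)
  if (max(lab) == 0L) return(list())
  out <- list()
  for (cl in seq_len(max(lab))) {
    ids <- which(lab == cl)
    if (length(ids) < min_size) next
    peak_id <- ids[which.max(v[ids])]  # which.max takes the first = lowest index
    out[[length(out) + 1L]] <- list(
      voxel_ids = ids, size = length(ids), peak_value = v[peak_id],
      peak_mm = as.numeric(vox_to_mm(vmap$geometry,
                                     arrayInd(peak_id, dim(v)))))
  }
  out[order(vapply(out, `[[`, numeric(1), "peak_value"), decreasing = TRUE)]
}

#' Tabulate a cluster list
#'
#' @param clusters as returned by [extract_clusters()].
#' @return data.frame(label, size, peak_value, x, y, z).
#' @export
clusters_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(label = character(), size = integer(),
                      peak_value = numeric(), x = numeric(), y = numeric(),
                      z = numeric()))
  }
  data.frame(label = sprintf("C%02d", seq_along(clusters)),
             size = vapply(clusters, `[[`, numeric(1), "size"),
             peak_value = vapply(clusters, `[[`, numeric(1), "peak_value"),
             x = vapply(clusters, function(c) c$peak_mm[1], numeric(1)),
             y = vapply(clusters, function(c) c$peak_mm[2], numeric(1)),
             z = vapply(clusters, function(c) c$peak_mm[3], numeric(1)))
}
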