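# Per-subject distance-correlation networks and edge-variability statistics.

#' Build per-subject functional connectivity networks
#'
#' Evaluates the distance correlation for every unordered ROV pair of every
#' subject (K(K-1)/2 evaluations), filling a symmetric K x K matrix with a
#' zero diagonal. Series should already be cleaned/normalized (see
#' [clean_roi_series()]). A pair that fails poisons that subject: its network
#' is NULL and the reason is attached as a warning.
#'
#' @param series_set a `roi_series_set`.
#' @param labels node order (default the set's labels).
#' @return list of K x K symmetric matrices (state recorded as an
#'   attribute), one per subject; NULL for poisoned subjects.
#' @export
build_fc_network <- function(series_set, labels = series_set$labels) {
  K <- length(labels)
  stopifnot(K >= 2L)
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  lapply(seq_along(series_set$subjects), function(i) {
    subj <- series_set$subjects[[i]]
    m <- matrix(0, K, K, dimnames = list(labels, labels))
    res <- tryCatch({
      for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1]; b <- pairs[r, 2]
        d <- distance_correlation(subj[[labels[a]]], subj[[labels[b]]])
        m[a, b] <- d
        m[b, a] <- d
      }
      attr(m, "state") <- series_set$state
      m
    }, error = function(e) {
      warning(sprintf("subject %d poisoned: %s", i, conditionMessage(e)))
      NULL
    })
    res
  })
}

#' Flatten networks to a subjects x edges matrix
#'
#' One column per unordered node pair (upper triangle, column-major order).
#'
#' @param nets list of K x K symmetric matrices.
#' @return n x K(K-1)/2 matrix with attributes `pairs` (m x 2 node indices)
#'   and `labels` ("A--B" per edge).
#' @export
nets_to_edge_matrix <- function(nets) {
  nets <- Filter(Negate(is.null), nets)
  stopifnot(length(nets) >= 1L)
  K <- nrow(nets[[1]])
  ut <- upper.tri(nets[[1]])
  pairs <- which(ut, arr.ind = TRUE)
  E <- do.call(rbind, lapply(nets, function(m) m[ut]))
  node_labels <- rownames(nets[[1]])
  if (is.null(node_labels)) node_labels <- as.character(seq_len(K))
  attr(E, "pairs") <- pairs
  attr(E, "labels") <- paste(node_labels[pairs[, 1]], node_labels[pairs[, 2]],
                             sep = "--")
  attr(E, "n_nodes") <- K
  E
}

#' Compare edge-level individual variability between task and rest
#'
#' Per edge, the across-subject sample SD of connectivity strength in each
#' state; the two SD vectors (length K(K-1)/2) are compared with a paired
#' t-test (df = K(K-1)/2 - 1). The paired difference is rest minus task.
#'
#' @param task_nets,rest_nets lists of K x K matrices over the same node set
#'   and subjects.
#' @return list(mean_sd_task, mean_sd_rest, t, df, p, note, edge_sd), where
#'   `edge_sd` is a per-edge data.frame. `t` is NA with an explanatory note
#'   when the paired differences have zero variance.
#' @export
edge_variability <- function(task_nets, rest_nets) {
  Et <- nets_to_edge_matrix(task_nets)
  Er <- nets_to_edge_matrix(rest_nets)
  if (!identical(attr(Et, "labels"), attr(Er, "labels"))) {
    stop("task and rest networks must share the node set")
  }
  if (nrow(Et) != nrow(Er)) stop("task and rest cohorts must share subjects")
  m <- ncol(Et)
  if (m < 3L) stop("need at least 3 edges")
  sd_task <- apply(Et, 2L, sd)
  sd_rest <- apply(Er, 2L, sd)
  diffs <- sd_rest - sd_task
  if (sd(diffs) == 0) {
    t_stat <- if (all(diffs == 0)) 0 else NA_real_
    res <- list(t = t_stat, df = m - 1L, p = NA_real_,
                note = "zero variance of paired differences")
  } else {
    ht <- t.test(sd_rest, sd_task, paired = TRUE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, note = NULL)
  }
  list(mean_sd_task = mean(sd_task), mean_sd_rest = mean(sd_rest),
       t = res$t, df = as.integer(res$df), p = res$p, note = res$note,
       edge_sd = data.frame(edge = attr(Et, "labels"),
                            sd_task = sd_task, sd_rest = sd_rest))
}
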