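# Connectome-based predictive modeling: per-fold edge screening, summed-edge
# positive/negative linear models, leave-one-out prediction and permutation
# inference.

# Pearson r and two-sided p of every edge against the score. Zero-variance
# edges give NA and are excluded from selection.
edge_score_cor <- function(E, y) {
  n <- length(y)
  r <- suppressWarnings(as.numeric(cor(E, y)))
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p)
}

#' Select behavior-related edges
#'
#' Pearson-correlates each unique edge with the score across training
#' subjects, keeps edges with two-sided p <= alpha, and splits them by the
#' sign of r into a positive and a negative mask (disjoint by construction).
#'
#' @param E training subjects x edges matrix (see [nets_to_edge_matrix()]).
#' @param y training scores.
#' @param alpha selection threshold on the edge-score p value.
#' @return list(pos, neg (integer edge indices), r, p, excluded (count of
#'   zero-variance edges)).
#' @export
select_edges <- function(E, y, alpha = 0.05) {
  stopifnot(nrow(E) >= 4L, all(is.finite(y)))
  es <- edge_score_cor(E, y)
  ok <- !is.na(es$r)
  sel <- ok & es$p <= alpha
  list(pos = which(sel & es$r > 0), neg = which(sel & es$r < 0),
       r = es$r, p = es$p, excluded = sum(!ok))
}

# Ordinary least-squares line of score on the summed masked edge strength.
# NULL when the mask is empty or the sums are constant (undefined slope).
fit_sum_model <- function(E, y, idx) {
  if (length(idx) == 0L) return(NULL)
  s <- rowSums(E[, idx, drop = FALSE])
  vs <- var(s)
  if (!is.finite(vs) || vs == 0) return(NULL)
  slope <- cov(s, y) / vs
  c(intercept = mean(y) - slope * mean(s), slope = slope)
}

#' Fit the positive and negative summed-edge models
#'
#' Per training subject, edge strengths are summed over the unique unordered
#' pairs in each mask (each edge counted once) and a least-squares line
#' score ~ sum is fitted per model.
#'
#' @param E training subjects x edges matrix.
#' @param y training scores.
#' @param masks list(pos, neg) of edge indices, as from [select_edges()].
#' @return list(pos, neg): each c(intercept, slope) or NULL when the mask is
#'   empty or degenerate.
#' @export
fit_models <- function(E, y, masks) {
  list(pos = fit_sum_model(E, y, masks$pos),
       neg = fit_sum_model(E, y, masks$neg))
}

# LOOCV engine. keep_folds = FALSE skips per-fold bookkeeping (used inside
# the permutation loop). Per-fold edge-score correlations are obtained by
# leave-one-out updates of full-sample sufficient statistics (O(edges) per
# fold); the edge columns are pre-centred, which leaves every fold's
# correlations invariant and well conditioned.
loocv_core <- function(E, y, alpha, keep_folds) {
  n <- length(y)
  m <- ncol(E)
  Ec <- E - rep(colMeans(E), each = n)
  Sx <- colSums(Ec)
  Sxx <- colSums(Ec^2)
  Sxy <- as.numeric(crossprod(Ec, y))
  Sy <- sum(y)
  Syy <- sum(y^2)
  pred_pos <- numeric(n)
  pred_neg <- numeric(n)
  any_pos <- FALSE
  any_neg <- FALSE
  folds <- if (keep_folds) vector("list", n) else NULL
  fit_from_sum <- function(s_tr, y_tr) {
    ms <- sum(s_tr) / n1
    ds <- s_tr - ms
    vs <- sum(ds^2)
    if (!is.finite(vs) || vs == 0) return(NULL)
    my <- sum(y_tr) / n1
    slope <- sum(ds * (y_tr - my)) / vs
    c(intercept = my - slope * ms, slope = slope)
  }
  n1 <- n - 1L
  # p <= alpha on the two-sided edge-score t is equivalent to |r| >= r_crit
  tc <- stats::qt(1 - alpha / 2, df = n1 - 2L)
  r_crit <- tc / sqrt(n1 - 2L + tc^2)
  # all folds' edge-score correlations at once (edges x folds)
  EX <- t(Ec)
  SX <- Sx - EX
  VX <- (Sxx - EX^2) - SX^2 / n1
  sy <- Sy - y
  vy <- (Syy - y^2) - sy^2 / n1
  NUM <- (Sxy - EX * rep(y, each = m)) - SX * rep(sy / n1, each = m)
  R <- NUM / sqrt(VX * rep(vy, each = m))
  R[VX <= 0] <- NA_real_
  R[, vy <= 0] <- NA_real_
  R <- pmin(pmax(R, -1), 1)
  for (i in seq_len(n)) {
    r <- R[, i]
    pos <- which(!is.na(r) & r >= r_crit)
    neg <- which(!is.na(r) & r <= -r_crit)
    y_tr <- y[-i]
    mtr <- mean(y_tr)
    fit_pos <- if (length(pos) > 0L) {
      s_all <- rowSums(E[, pos, drop = FALSE])
      fit_from_sum(s_all[-i], y_tr)
    } else NULL
    fit_neg <- if (length(neg) > 0L) {
      s_all_n <- rowSums(E[, neg, drop = FALSE])
      fit_from_sum(s_all_n[-i], y_tr)
    } else NULL
    pred_pos[i] <- if (is.null(fit_pos)) mtr else {
      any_pos <- TRUE
      fit_pos["intercept"] + fit_pos["slope"] * sum(E[i, pos])
    }
    pred_neg[i] <- if (is.null(fit_neg)) mtr else {
      any_neg <- TRUE
      fit_neg["intercept"] + fit_neg["slope"] * sum(E[i, neg])
    }
    if (keep_folds) {
      folds[[i]] <- list(held_out = i, pos_mask = pos, neg_mask = neg,
                         fit_pos = fit_pos, fit_neg = fit_neg,
                         r = r, train_mean = mtr,
                         empty_pos = is.null(fit_pos),
                         empty_neg = is.null(fit_neg))
    }
  }
  if (any(!is.finite(pred_pos)) || any(!is.finite(pred_neg))) {
    stop("non-finite predictions in LOOCV")
  }
  r_pos <- if (any_pos) suppressWarnings(cor(y, pred_pos)) else NA_real_
  r_neg <- if (any_neg) suppressWarnings(cor(y, pred_neg)) else NA_real_
  list(observed = y, predicted_pos = pred_pos, predicted_neg = pred_neg,
       r_positive = r_pos, r_negative = r_neg,
       status_pos = if (any_pos) "ok" else "failed_no_edges",
       status_neg = if (any_neg) "ok" else "failed_no_edges",
       folds = folds)
}

#' Leave-one-out connectome-based prediction
#'
#' For each fold, edges are selected and the positive/negative summed-edge
#' models fitted on the n - 1 training subjects; the held-out subject's score
#' is predicted from its own masked edge sums. Folds whose mask is empty (or
#' whose sums are constant) predict the training-mean score; a model fails
#' outright (`failed_no_edges`) only when every fold lacked edges of that
#' sign. Model validity is the Pearson correlation between observed and
#' predicted scores.
#'
#' @param nets list of K x K networks, or a subjects x edges matrix from
#'   [nets_to_edge_matrix()].
#' @param y behavioral scores (length = subjects, >= 5).
#' @param alpha edge-selection threshold.
#' @param keep_folds keep per-fold masks and coefficients (default TRUE).
#' @return an object of class `cpm_result`.
#' @export
loocv_predict <- function(nets, y, alpha = 0.05, keep_folds = TRUE) {
  E <- if (is.matrix(nets)) nets else nets_to_edge_matrix(nets)
  stopifnot(nrow(E) == length(y))
  if (length(y) < 5L) stop("need at least 5 subjects for LOOCV")
  if (!all(is.finite(y))) stop("scores must be finite")
  out <- loocv_core(E, y, alpha, keep_folds)
  out$alpha <- alpha
  out$edge_labels <- attr(E, "labels")
  out$pairs <- attr(E, "pairs")
  class(out) <- "cpm_result"
  out
}

#' @export
print.cpm_result <- function(x, ...) {
  cat(sprintf("<cpm_result> n = %d\n", length(x$observed)))
  cat(sprintf("  positive model: %s, r = %s\n", x$status_pos,
              format(x$r_positive, digits = 3)))
  cat(sprintf("  negative model: %s, r = %s\n", x$status_neg,
              format(x$r_negative, digits = 3)))
  invisible(x)
}

#' Permutation test of LOOCV prediction performance
#'
#' Scores are permuted across subjects and the full LOOCV pipeline (including
#' per-fold edge selection) is re-run for each permutation. For each model the
#' add-one estimator `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)` is
#' computed on that model's own prediction r. Permutations in which a model
#' fails contribute r_perm = -Inf.
#'
#' @param nets networks or edge matrix, as in [loocv_predict()].
#' @param y behavioral scores.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param alpha edge-selection threshold.
#' @return list(observed (`cpm_result`), p_positive, p_negative, r_perm_pos,
#'   r_perm_neg, n_perm, seed).
#' @export
permutation_test <- function(nets, y, n_perm = 1000, seed = 1, alpha = 0.05) {
  E <- if (is.matrix(nets)) nets else nets_to_edge_matrix(nets)
  obs <- loocv_predict(E, y, alpha = alpha, keep_folds = TRUE)
  rp <- rn <- rep(-Inf, n_perm)
  with_preserved_seed(seed, {
    for (b in seq_len(n_perm)) {
      yp <- sample(y)
      res <- loocv_core(E, yp, alpha, keep_folds = FALSE)
      if (res$status_pos == "ok" && is.finite(res$r_positive)) rp[b] <- res$r_positive
      if (res$status_neg == "ok" && is.finite(res$r_negative)) rn[b] <- res$r_negative
    }
  })
  p_pos <- if (obs$status_pos == "ok" && is.finite(obs$r_positive)) {
    (1 + sum(rp >= obs$r_positive)) / (1 + n_perm)
  } else NA_real_
  p_neg <- if (obs$status_neg == "ok" && is.finite(obs$r_negative)) {
    (1 + sum(rn >= obs$r_negative)) / (1 + n_perm)
  } else NA_real_
  list(observed = obs, p_positive = p_pos, p_negative = p_neg,
       r_perm_pos = rp, r_perm_neg = rn, n_perm = n_perm, seed = seed)
}

#' Edges contributing to the positive prediction
#'
#' The edges present in the positive mask of every fold (intersection across
#' folds; set `mode = "union"` for any fold), ranked by their mean training
#' correlation with the score.
#'
#' @param result a `cpm_result` fitted with `keep_folds = TRUE`.
#' @param mode "intersection" (default) or "union".
#' @return data.frame(edge, node_a, node_b, mean_r), possibly empty (with a
#'   warning for an empty intersection).
#' @export
report_contributing_network <- function(result,
                                        mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (result$status_pos != "ok") stop("positive model did not run ok")
  if (is.null(result$folds)) stop("result was fitted without keep_folds")
  masks <- lapply(result$folds, `[[`, "pos_mask")
  idx <- if (mode == "intersection") Reduce(intersect, masks) else {
    sort(unique(unlist(masks)))
  }
  if (length(idx) == 0L) {
    warning("no edge is selected in ", mode, " across folds")
    return(data.frame(edge = character(), node_a = integer(),
                      node_b = integer(), mean_r = numeric()))
  }
  r_mat <- vapply(result$folds, function(f) f$r[idx], numeric(length(idx)))
  mean_r <- if (length(idx) == 1L) mean(r_mat) else rowMeans(r_mat)
  labs <- if (!is.null(result$edge_labels)) result$edge_labels[idx] else
    as.character(idx)
  pairs <- result$pairs
  out <- data.frame(edge = labs,
                    node_a = if (!is.null(pairs)) pairs[idx, 1] else NA,
                    node_b = if (!is.null(pairs)) pairs[idx, 2] else NA,
                    mean_r = mean_r)
  out[order(out$mean_r, decreasing = TRUE), , drop = FALSE]
}
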