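# Independent brute-force oracles and small fixture builders. The oracles are
# literal transcriptions of the definitions and share no code with the
# package implementations they check.

# Unbiased (U-centered) squared distance covariance by four nested loops.
dcov2_brute <- function(X, Y) {
  n <- ncol(X)
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- sqrt(sum((X[, i] - X[, j])^2))
      B[i, j] <- sqrt(sum((Y[, i] - Y[, j])^2))
    }
  }
  Au <- matrix(0, n, n)
  Bu <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        Au[i, j] <- A[i, j] - sum(A[i, ]) / (n - 2) - sum(A[, j]) / (n - 2) +
          sum(A) / ((n - 1) * (n - 2))
        Bu[i, j] <- B[i, j] - sum(B[i, ]) / (n - 2) - sum(B[, j]) / (n - 2) +
          sum(B) / ((n - 1) * (n - 2))
      }
    }
  }
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + Au[i, j] * Bu[i, j]
    }
  }
  acc / (n * (n - 3))
}

dcor_brute <- function(X, Y) {
  v <- dcov2_brute(X, Y)
  vx <- dcov2_brute(X, X)
  vy <- dcov2_brute(Y, Y)
  if (vx <= 0 || vy <= 0) return(0)
  sqrt(max(v, 0) / sqrt(vx * vy))
}

# Exhaustive single-split segmentation: direct SSE of each candidate split.
changepoint_brute <- function(values) {
  x <- sort(values[is.finite(values)])
  n <- length(x)
  sse <- vapply(seq_len(n - 1L), function(k) {
    l <- x[1:k]
    r <- x[(k + 1):n]
    sum((l - mean(l))^2) + sum((r - mean(r))^2)
  }, numeric(1))
  k <- which.min(sse)
  list(threshold = x[k + 1L], change_index = k, sse = sse[k])
}

# Literal per-voxel loop transcription of the variance-ratio formulas.
f_map_brute <- function(cohort) {
  n <- length(cohort)
  nscan <- cohort[[1]]$n_scans
  d <- dim(cohort[[1]]$con)
  out <- array(NA_real_, d)
  for (v in seq_len(prod(d))) {
    con <- vapply(cohort, function(s) s$con[v], numeric(1))
    resms <- vapply(cohort, function(s) s$resms[v], numeric(1))
    sb2 <- (sum((con - mean(con))^2) / (n - 1)) / 2 * nscan
    sw2 <- (sum(resms) / n) / (nscan - 1)
    out[v] <- if (sw2 == 0) NA_real_ else sb2 / sw2
  }
  out
}

# Tiny cohort builders ------------------------------------------------------

one_voxel_contrast <- function(con_values, resms_values, n_scans = 10) {
  g <- vol_geometry(c(1, 1, 1))
  mapply(function(cv, rv) {
    subject_contrast(array(cv, c(1, 1, 1)), array(rv, c(1, 1, 1)), n_scans, g)
  }, con_values, resms_values, SIMPLIFY = FALSE)
}

random_contrast_cohort <- function(n_subjects, dims, n_scans = 10, seed = 1) {
  set.seed(seed)
  g <- vol_geometry(dims)
  nv <- prod(dims)
  lapply(seq_len(n_subjects), function(i) {
    subject_contrast(array(rnorm(nv), dims),
                     array(rchisq(nv, 5), dims), n_scans, g)
  })
}

# Two latent-coupled multi-voxel series with a given latent correlation.
coupled_series_pair <- function(rho, n_voxels = 15, n_obs = 200,
                                noise_sd = 0.5) {
  z1 <- rnorm(n_obs)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_obs)
  X <- outer(runif(n_voxels, 0.8, 1.2), z1) +
    matrix(rnorm(n_voxels * n_obs, 0, noise_sd), n_voxels)
  Y <- outer(runif(n_voxels, 0.8, 1.2), z2) +
    matrix(rnorm(n_voxels * n_obs, 0, noise_sd), n_voxels)
  list(X = X, Y = Y)
}

small_sim_config <- function(...) {
  defaults <- list(n_subjects = 8, grid_dims = c(10, 10, 10), n_scans = 20,
                   n_trials_task = 12, n_timepoints_rest = 60)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
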