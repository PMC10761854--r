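test_that("confound regression produces residuals orthogonal to the design", {
  set.seed(81)
  n_t <- 80
  conf <- matrix(rnorm(n_t * 4), n_t, dimnames = list(NULL, paste0("c", 1:4)))
  series <- matrix(rnorm(6 * n_t), 6)
  res <- regress_confounds(series, conf)
  for (j in 1:4) {
    expect_true(all(abs(cor(t(res), conf[, j])) < 1e-8))
  }

  # a voxel equal to a confound column is annihilated
  series2 <- rbind(conf[, 2], rnorm(n_t))
  res2 <- regress_confounds(series2, conf)
  expect_lt(max(abs(res2[1, ])), 1e-10)

  # matches an explicit pseudoinverse solve
  X <- cbind(1, conf)
  beta <- solve(t(X) %*% X) %*% t(X) %*% t(series)
  expect_equal(res, series - t(X %*% beta), tolerance = 1e-8)

  # duplicated column: dropped with a warning naming it
  dup <- cbind(conf, c5 = conf[, 1])
  expect_warning(r3 <- regress_confounds(series, dup), "c5")
  expect_equal(r3, res, tolerance = 1e-10)
})

test_that("the zero-phase bandpass keeps the passband and rejects outside it", {
  tr <- 0.72
  tt <- seq(0, by = tr, length.out = 600)
  amp_at <- function(x, f) {
    sp <- Mod(stats::fft(x))
    fr <- (seq_along(x) - 1) / (length(x) * tr)
    sp[which.min(abs(fr - f))]
  }
  s_in <- sin(2 * pi * 0.05 * tt)
  s_out <- sin(2 * pi * 0.30 * tt)
  expect_gt(amp_at(bandpass(s_in, tr, 0.009, 0.08), 0.05) / amp_at(s_in, 0.05), 0.9)
  expect_lt(amp_at(bandpass(s_out, tr, 0.009, 0.08), 0.30) / amp_at(s_out, 0.30), 0.1)

  # DC is outside the passband
  expect_lt(max(abs(bandpass(rep(3, 400), tr, 0.009, 0.08))), 1e-10)

  expect_error(bandpass(rnorm(8), tr, 0.009, 0.08), "too short")
  expect_error(bandpass(rnorm(400), tr, 0.08, 0.009), "Nyquist")
})

test_that("truncation keeps the first n volumes and rejects shorter input", {
  m <- matrix(seq_len(2 * 400), 2, byrow = TRUE)
  expect_equal(ncol(truncate_rest(m, 316)), 316)
  expect_equal(truncate_rest(m, 316)[1, ], seq_len(316))
  m316 <- m[, 1:316]
  expect_equal(truncate_rest(m316, 316), m316)
  expect_error(truncate_rest(m[, 1:315], 316), "cannot truncate")
})

test_that("z-normalization centres and scales each voxel and is affine-invariant", {
  set.seed(82)
  m <- matrix(rnorm(5 * 40, 10, 4), 5)
  z <- znormalize(m)
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5))
  expect_equal(znormalize(3 * m + 7), z, tolerance = 1e-12)

  # hand formula for two observations
  # hand formula: {2, 6} -> mean 4, sample SD 2*sqrt(2) -> +-1/sqrt(2)
  z2 <- znormalize(matrix(c(2, 6), 1))
  expect_equal(as.numeric(z2), c(-1, 1) / sqrt(2))

  expect_warning(zk <- znormalize(rbind(m[1, ], rep(1, 40))), "zero-variance")
  expect_equal(nrow(zk), 1L)
  expect_error(znormalize(matrix(1, 2, 10)), "all voxels")
})

test_that("distance correlation obeys its identities and brute-force definition", {
  set.seed(83)
  X <- matrix(rnorm(3 * 10), 3)
  expect_equal(distance_correlation(X, X), 1, tolerance = 1e-12)
  expect_equal(distance_correlation(X, 2 * X + 1), 1, tolerance = 1e-10)

  # constant pattern: dVar <= 0 convention
  expect_equal(distance_correlation(matrix(1, 3, 10), X), 0)

  # brute-force equivalence on small instances
  for (t_obs in c(4, 6, 8, 12)) {
    X <- matrix(rnorm(3 * t_obs), 3)
    Y <- matrix(rnorm(3 * t_obs), 3)
    expect_equal(dcor_stats(X, Y)$dcov2, dcov2_brute(X, Y), tolerance = 1e-12)
    expect_equal(distance_correlation(X, Y), dcor_brute(X, Y), tolerance = 1e-12)
  }

  # independence: mean dCor small at T = 300
  d0 <- vapply(1:50, function(i) {
    distance_correlation(matrix(rnorm(5 * 300), 5), matrix(rnorm(5 * 300), 5))
  }, numeric(1))
  expect_lt(mean(d0), 0.1)
  expect_true(all(d0 >= 0 & d0 <= 1))

  expect_error(distance_correlation(matrix(1:6, 2), matrix(1:6, 2)), "at least 4")
  expect_error(distance_correlation(matrix(c(NA, rnorm(7)), 2),
                                    matrix(rnorm(8), 2)), "non-finite")
})

test_that("network construction fills a symmetric zero-diagonal matrix per subject", {
  cfg <- small_sim_config(seed = 84)
  s <- gen_roi_series(cfg, "task")
  nets <- build_fc_network(s)
  m <- nets[[1]]
  expect_equal(dim(m), c(13, 13))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  E <- nets_to_edge_matrix(nets)
  expect_equal(ncol(E), 13 * 12 / 2)

  # node-order permutation permutes rows/cols consistently
  perm <- rev(s$labels)
  nets_p <- build_fc_network(s, labels = perm)
  expect_equal(nets_p[[1]][s$labels, s$labels], m, ignore_attr = TRUE)
})

test_that("edge estimates increase with the configured coupling target", {
  set.seed(85)
  levels <- c(0.05, 0.25, 0.45, 0.65, 0.85)
  means <- vapply(levels, function(rho) {
    mean(vapply(1:40, function(i) {
      p <- coupled_series_pair(rho, n_obs = 200)
      distance_correlation(p$X, p$Y)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(levels, means, method = "spearman"), 0.9)
})

test_that("edge variability compares task and rest SDs with a paired t-test", {
  # hand-built 3-edge fixture across 4 subjects
  mk <- function(vals) {
    m <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
    m[upper.tri(m)] <- vals
    m + t(m)
  }
  task <- list(mk(c(0.1, 0.2, 0.3)), mk(c(0.2, 0.2, 0.4)),
               mk(c(0.3, 0.2, 0.5)), mk(c(0.4, 0.2, 0.6)))
  rest <- list(mk(c(0.1, 0.5, 0.1)), mk(c(0.5, 0.1, 0.4)),
               mk(c(0.9, 0.7, 0.7)), mk(c(1.3, 0.3, 1.0)))
  ev <- edge_variability(task, rest)
  # edge order follows the upper triangle: (A,B), (A,C), (B,C)
  sd_t <- c(sd(c(.1, .2, .3, .4)), sd(c(.2, .2, .2, .2)), sd(c(.3, .4, .5, .6)))
  sd_r <- c(sd(c(.1, .5, .9, 1.3)), sd(c(.5, .1, .7, .3)), sd(c(.1, .4, .7, 1.0)))
  d <- sd_r - sd_t
  expect_equal(ev$df, 2L)
  expect_equal(ev$t, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-12)
  expect_equal(ev$mean_sd_task, mean(sd_t))
  expect_equal(ev$mean_sd_rest, mean(sd_r))

  # identical SD vectors: zero difference, t = 0 reported as such
  ev0 <- edge_variability(task, task)
  expect_equal(ev0$t, 0)
  expect_match(ev0$note, "zero variance")
})

test_that("the rest cleaning chain removes injected confound structure", {
  cfg <- sim_config(n_subjects = 4, n_timepoints_rest = 316, seed = 86,
                    confound_leak = c(global = 2, motion = 1.5))
  conf <- gen_confounds(cfg)
  raw <- gen_roi_series(cfg, "rest", confounds = conf)
  cleaned <- clean_roi_series(raw, confounds = conf)
  r_raw <- r_cln <- numeric(4)
  for (i in 1:4) {
    r_raw[i] <- abs(cor(colMeans(raw$subjects[[i]]$ROV01), conf[[i]]$global))
    r_cln[i] <- abs(cor(colMeans(cleaned$subjects[[i]]$ROV01), conf[[i]]$global))
    expect_lt(r_cln[i], r_raw[i])
  }
  # filtering after regression does not preserve exact orthogonality, but the
  # injected leakage must be largely gone
  expect_gt(mean(r_raw), 0.5)
  expect_lt(mean(r_cln), 0.2)
  expect_equal(cleaned$cleaning$f_max, 0.08)
  # task default: z-normalization only
  task <- clean_roi_series(gen_roi_series(cfg, "task"))
  expect_false(task$cleaning$regress)
  expect_true(all(abs(rowMeans(task$subjects[[1]]$ROV01)) < 1e-10))
})
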