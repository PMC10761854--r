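test_that("cohort generation is deterministic in the seed and stable under n_subjects", {
  cfg <- small_sim_config(seed = 42)
  a <- gen_contrast_cohort(cfg)
  b <- gen_contrast_cohort(cfg)
  expect_identical(a, b)

  s1 <- gen_roi_series(cfg, "task")
  s2 <- gen_roi_series(cfg, "task")
  expect_identical(s1, s2)

  beh1 <- gen_behavior(gen_fc_cohort(cfg, "rest"), cfg)
  beh2 <- gen_behavior(gen_fc_cohort(cfg, "rest"), cfg)
  expect_identical(beh1, beh2)

  # per-subject sub-streams: a larger cohort reproduces the smaller one
  cfg12 <- small_sim_config(seed = 42, n_subjects = 12)
  big <- gen_contrast_cohort(cfg12)
  expect_identical(big[seq_along(a)], a)

  # different seeds differ
  other <- gen_contrast_cohort(small_sim_config(seed = 43))
  expect_false(identical(other[[1]]$con, a[[1]]$con))
})

test_that("zero between-subject SD collapses contrast maps onto the template", {
  cfg <- small_sim_config(seed = 5, sigma_b_base = 0, func_sd_multiplier = 1)
  co <- gen_contrast_cohort(cfg)
  expect_equal(co[[1]]$con, co[[5]]$con)
  sb2 <- between_subject_variance(co)
  expect_true(all(sb2 == 0))
})

test_that("high-variance spheres elevate across-subject contrast SD inside them", {
  wins <- vapply(1:20, function(s) {
    cfg <- sim_config(n_subjects = 40, seed = 100 + s,
                      func_high_variance = "ROV01", func_sd_multiplier = 4)
    co <- gen_contrast_cohort(cfg)
    geom <- co[[1]]$geometry
    stack <- do.call(rbind, lapply(co, function(x) as.numeric(x$con)))
    sds <- apply(stack, 2, sd)
    rov <- define_rov("hv", "functional", c(-18, -18, -18), geom, 10)
    mean(sds[rov$voxel_ids]) > mean(sds[-rov$voxel_ids])
  }, logical(1))
  expect_true(all(wins))
})

test_that("GM maps respect zero-SD, regional elevation and the nonnegativity clip", {
  cfg0 <- small_sim_config(seed = 2, sigma_gm_base = 0, struct_sd_multiplier = 1)
  gm0 <- gen_gm_cohort(cfg0)
  expect_true(all(sd_map(gm0)$values == 0))

  # elevated region ranks first among all 13 sphere means of the SD map
  ranks <- vapply(1:10, function(s) {
    cfg <- sim_config(n_subjects = 40, seed = 200 + s,
                      struct_high_variance = "ROV07", struct_sd_multiplier = 3)
    gm <- gen_gm_cohort(cfg)
    sm <- sd_map(gm)
    rovs <- rovs_from_table(cfg$rov_specs, geometry = sm$geometry)
    means <- vapply(rovs, function(r) mean(sm$values[r$voxel_ids]), numeric(1))
    names(which.max(means))
  }, character(1))
  expect_true(all(ranks == "ROV07"))

  # clipping: template 0, large sigma -> no negative values
  cfgc <- small_sim_config(seed = 3, gm_template = 0, sigma_gm_base = 5)
  gmc <- gen_gm_cohort(cfgc)
  expect_true(all(vapply(gmc, function(g) all(g >= 0), logical(1))))
})

test_that("latent coupling targets translate into distance-correlation levels", {
  # null coupling: mean dCor across 50 subjects stays near zero
  cfg0 <- sim_config(n_subjects = 50, n_timepoints_rest = 300, seed = 10,
                     coupling = list(target = matrix(0, 13, 13),
                                     edge_sd = c(task = 0, rest = 0)),
                     confound_leak = c(global = 0, motion = 0))
  s0 <- gen_roi_series(cfg0, "rest")
  d0 <- vapply(s0$subjects, function(su) {
    distance_correlation(su$ROV01, su$ROV02)
  }, numeric(1))
  expect_lt(mean(d0), 0.1)

  # near-unit coupling: strong dependence
  tgt <- matrix(0.95, 13, 13); diag(tgt) <- 0
  cfg1 <- sim_config(n_subjects = 10, n_timepoints_rest = 300, seed = 11,
                     coupling = list(target = tgt,
                                     edge_sd = c(task = 0, rest = 0)),
                     voxel_noise_sd = 0.2,
                     confound_leak = c(global = 0, motion = 0))
  s1 <- gen_roi_series(cfg1, "rest")
  d1 <- vapply(s1$subjects, function(su) {
    distance_correlation(su$ROV01, su$ROV02)
  }, numeric(1))
  expect_gt(mean(d1), 0.8)
})

test_that("series generation rejects degenerate observation counts and grids", {
  expect_error(gen_roi_series(small_sim_config(n_trials_task = 3), "task"),
               "fewer than 4")
  expect_error(gen_contrast_cohort(small_sim_config(grid_dims = c(2, 10, 10))),
               "degenerate grid")
})

test_that("behavior scores track the designated edge sum exactly at zero noise", {
  cfg <- small_sim_config(seed = 9)
  cfg$behavior_coupling$noise_sd <- 0
  nets <- gen_fc_cohort(cfg, "rest")
  beh <- gen_behavior(nets, cfg)
  truth <- attr(beh, "truth")
  expect_equal(cor(beh$score_read, truth$edge_sum), 1)
})

test_that("null behavior coupling produces a nominal edge-screening rate", {
  # slope 0: ~5% of edge-score correlations pass p <= 0.05
  hits <- 0; total <- 0
  for (s in 1:13) {
    cfg <- sim_config(n_subjects = 97, seed = 300 + s)
    cfg$behavior_coupling$slope <- 0
    nets <- gen_fc_cohort(cfg, "rest")
    beh <- gen_behavior(nets, cfg)
    E <- nets_to_edge_matrix(nets)
    sel <- select_edges(E, beh$score_read, alpha = 0.05)
    hits <- hits + length(sel$pos) + length(sel$neg)
    total <- total + ncol(E)
  }
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.08)
})

test_that("behavior generation validates its edge set", {
  cfg <- small_sim_config(seed = 1)
  nets <- gen_fc_cohort(cfg, "rest")
  cfg$behavior_coupling$edges <- NULL
  expect_error(gen_behavior(nets, cfg), "empty edge set")
  cfg$behavior_coupling$edges <- rbind(c(1, 99))
  expect_error(gen_behavior(nets, cfg), "nonexistent nodes")
})
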