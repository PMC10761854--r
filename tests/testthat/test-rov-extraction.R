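test_that("change-point split matches hand examples and is permutation-invariant", {
  cp <- changepoint_threshold(c(1, 1, 1, 1, 10, 10))
  expect_equal(cp$change_index, 4L)
  expect_equal(cp$threshold, 10)
  expect_false(cp$degenerate)

  # degenerate: all identical
  cpd <- changepoint_threshold(c(5, 5, 5))
  expect_true(cpd$degenerate)
  expect_identical(cpd$threshold, Inf)

  expect_error(changepoint_threshold(c(1, 2)), "at least 3")

  set.seed(71)
  x <- c(rnorm(50), rnorm(20, 8))
  ref <- changepoint_threshold(x)
  for (i in 1:5) {
    perm <- changepoint_threshold(sample(x))
    expect_identical(perm[c("threshold", "change_index")],
                     ref[c("threshold", "change_index")])
  }
})

test_that("change-point split equals exhaustive direct-SSE search", {
  set.seed(72)
  for (n in c(10, 100, 1000)) {
    x <- c(rnorm(n * 0.8), rnorm(ceiling(n * 0.2), 6))
    got <- changepoint_threshold(x)
    want <- changepoint_brute(x)
    expect_identical(got$change_index, want$change_index)
    expect_identical(got$threshold, want$threshold)
  }
})

test_that("thresholding keeps exactly the voxels at or above the cutoff", {
  set.seed(73)
  g <- vol_geometry(c(5, 5, 5))
  vm <- variance_map(array(rchisq(125, 3), c(5, 5, 5)), "functional_F", g)

  thr <- 2.5
  out <- apply_threshold(vm, thr)
  expect_equal(sum(out$values > 0), sum(vm$values >= thr))
  expect_true(all(out$values[out$values > 0] >= thr))
  expect_equal(out$threshold, thr)

  # +Inf sentinel: all-zero map
  expect_true(all(apply_threshold(vm, Inf)$values == 0))
  # threshold at the minimum: identity on the support
  expect_equal(apply_threshold(vm, min(vm$values))$values, vm$values)

  # monotonicity: higher thresholds never increase survivors or clusters
  thrs <- sort(c(1, 2, 3, 5))
  surv <- vapply(thrs, function(t) sum(apply_threshold(vm, t)$values > 0),
                 numeric(1))
  ncl <- vapply(thrs, function(t) {
    length(extract_clusters(apply_threshold(vm, t), min_size = 1))
  }, numeric(1))
  expect_true(all(diff(surv) <= 0))
  expect_true(all(ncl <= surv))
})

test_that("cluster extraction respects size filtering, 26-connectivity and the affine", {
  dims <- c(12, 12, 12)
  g <- vol_geometry(dims)
  v <- array(0, dims)
  blob12 <- c(outer(outer(1:3, (1:2 - 1) * 12, "+"), (1:2 - 1) * 144, "+"))
  blob5 <- (10 - 1) + (10 - 1) * 12 + ((8:12) - 1) * 144 + 1
  v[blob12] <- 5
  v[blob5] <- 7
  vm <- variance_map(v, "functional_F", g)
  cl <- extract_clusters(vm, min_size = 10)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 12)

  # single voxel: peak coordinate equals the affine image of its index
  v1 <- array(0, dims)
  v1[3, 4, 5] <- 2
  c1 <- extract_clusters(variance_map(v1, "functional_F", g), min_size = 1)
  expect_equal(c1[[1]]$peak_mm, as.numeric(vox_to_mm(g, c(3, 4, 5))))

  # two blobs touching only at a corner merge under 26-connectivity
  v2 <- array(0, dims)
  v2[1:2, 1:2, 1:2] <- 1
  v2[3:4, 3:4, 3:4] <- 1
  c2 <- extract_clusters(variance_map(v2, "functional_F", g), min_size = 1)
  expect_length(c2, 1L)
  expect_equal(c2[[1]]$size, 16)

  # clusters come back sorted by descending peak value
  v3 <- array(0, dims)
  v3[1:2, 1:2, 1:2] <- 3
  v3[8:9, 8:9, 8:9] <- 9
  c3 <- extract_clusters(variance_map(v3, "functional_F", g), min_size = 1)
  expect_equal(vapply(c3, `[[`, numeric(1), "peak_value"), c(9, 3))

  expect_length(extract_clusters(variance_map(array(0, dims), "functional_F", g)), 0L)
})

test_that("sphere membership follows the lattice geometry", {
  g <- vol_geometry(c(15, 15, 15), 3)  # centres at -21..21 mm
  center <- c(0, 0, 0)

  # centre on a voxel centre: that voxel is a member; tiny radius keeps only it
  r_tiny <- define_rov("t", "functional", center, g, radius_mm = 0.1)
  expect_equal(length(r_tiny$voxel_ids), 1L)
  expect_equal(as.numeric(vox_to_mm(g, arrayInd(r_tiny$voxel_ids, g$dims))), center)

  # 10 mm radius on a 3 mm lattice: count equals brute-force enumeration of
  # the 7x7x7 neighbourhood
  rov <- define_rov("s", "functional", center, g, radius_mm = 10)
  lattice <- expand.grid(x = -3:3, y = -3:3, z = -3:3) * 3
  n_brute <- sum(sqrt(rowSums(lattice^2)) <= 10)
  expect_equal(length(rov$voxel_ids), n_brute)

  # every member centre is inside the sphere
  mm <- vox_to_mm(g, arrayInd(rov$voxel_ids, g$dims))
  expect_true(all(sqrt(rowSums(sweep(mm, 2, center)^2)) <= 10))

  expect_error(define_rov("out", "functional", c(999, 0, 0), g), "bounding box")
})

test_that("the packaged ROV coordinate table has the published structure", {
  tab <- published_rovs()
  expect_equal(nrow(tab), 13L)
  expect_equal(sum(tab$kind == "functional"), 6L)
  expect_equal(sum(tab$kind == "structural"), 7L)
  expect_equal(anyDuplicated(tab$node), 0L)
  expect_true(all(tab$radius == 10))
  rovs <- rovs_from_table(tab)
  expect_true(all(vapply(rovs, function(r) length(r$voxel_ids) > 0, logical(1))))
})

test_that("extracted functional ROV centres recover the configured spheres", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_subjects = 40, seed = 400 + s)
    co <- gen_contrast_cohort(cfg)
    fm <- threshold_variance_map(f_ratio_map(co))
    cl <- extract_clusters(fm, min_size = 10)
    centers <- cfg$rov_specs[cfg$rov_specs$label %in% cfg$func_high_variance,
                             c("x", "y", "z")]
    peaks <- t(vapply(cl, `[[`, numeric(3), "peak_mm"))
    for (i in seq_len(nrow(centers))) {
      total <- total + 1
      d <- apply(abs(sweep(peaks, 2, as.numeric(centers[i, ]))), 1, max)
      if (any(d <= cfg$voxel_size_mm)) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
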