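# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analyses assume: subject
# contrast maps with spatially heterogeneous between-subject variance and
# chi-square-distributed residual mean squares, grey-matter maps with
# region-dependent SD, multi-voxel ROV series from a latent-factor model with
# subject-varying cross-ROV coupling, realistic confound series, and behavior
# scores linearly coupled to a designated edge set. Every draw flows from one
# seed through per-subject sub-streams.

#' Default synthetic ROV specification
#'
#' Thirteen spherical regions (6 "functional", 7 "structural", mirroring the
#' study design) placed on a +-18 mm lattice inside the default 24^3 x 3 mm
#' grid, pairwise at least 18 mm apart.
#'
#' @return data.frame with columns label, kind, x, y, z, radius (mm).
#' @export
default_rov_specs <- function() {
  centers <- rbind(
    c(-18, -18, -18), c(18, 18, -18), c(-18, 18, 18), c(18, -18, 18),
    c(0, 0, 0), c(18, 0, 0),
    c(18, -18, -18), c(-18, 18, -18), c(-18, -18, 18), c(18, 18, 18),
    c(-18, 0, 0), c(0, 18, 0), c(0, -18, 0))
  data.frame(label = sprintf("ROV%02d", 1:13),
             kind = c(rep("functional", 6), rep("structural", 7)),
             x = centers[, 1], y = centers[, 2], z = centers[, 3],
             radius = 10)
}

#' Synthetic cohort configuration
#'
#' Bundles every parameter of the generator. Defaults are the study
#' conditions: 97 subjects, a 24^3 grid at 3 mm, 316 scans per first-level
#' model, 8 task trials, 316 resting volumes at TR = 0.72 s, and 13 ROVs.
#'
#' @param n_subjects cohort size (>= 4).
#' @param grid_dims 3 voxel counts.
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param n_scans scans entering each subject's first-level model (NScan).
#' @param n_trials_task task beta-series length (trials).
#' @param n_timepoints_rest resting series length (volumes).
#' @param tr_seconds repetition time of the resting series, s.
#' @param rov_specs data.frame like [default_rov_specs()].
#' @param func_high_variance,struct_high_variance labels of rov_specs rows that
#'   receive elevated between-subject SD in contrast / GM maps.
#' @param func_sd_multiplier,struct_sd_multiplier peak SD multiplier at the
#'   centre of each high-variance sphere (Gaussian radial profile,
#'   scale = radius/2).
#' @param mu_contrast population mean contrast value (arbitrary units).
#' @param sigma_b_base baseline between-subject SD of the contrast.
#' @param sigma_w within-subject residual SD (ResMS expectation = sigma_w^2).
#' @param gm_template,sigma_gm_base GM template value and baseline SD.
#' @param n_voxels_per_rov voxels simulated per ROV series.
#' @param loading_range uniform range of voxel loadings on the ROV latent.
#' @param voxel_noise_sd SD of iid voxel noise around the latent.
#' @param coupling list(target = K x K population coupling targets in [0, 1),
#'   edge_sd = c(task =, rest =) across-subject SD of each edge).
#' @param confound_leak c(global =, motion =) leakage coefficients of the
#'   global/motion confounds into resting voxel series.
#' @param behavior_coupling list(edges = m x 2 node-index pairs, slope,
#'   intercept, noise_sd (NULL derives it from snr), snr,
#'   score_sd_uncoupled).
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 97,
                       grid_dims = c(24, 24, 24),
                       voxel_size_mm = 3,
                       n_scans = 316,
                       n_trials_task = 8,
                       n_timepoints_rest = 316,
                       tr_seconds = 0.72,
                       rov_specs = default_rov_specs(),
                       func_high_variance = c("ROV01", "ROV02", "ROV03"),
                       func_sd_multiplier = 4,
                       struct_high_variance = c("ROV07", "ROV08", "ROV09"),
                       struct_sd_multiplier = 3,
                       mu_contrast = 1,
                       sigma_b_base = 0.5,
                       sigma_w = 1,
                       gm_template = 0.5,
                       sigma_gm_base = 0.02,
                       n_voxels_per_rov = 20,
                       loading_range = c(0.8, 1.2),
                       voxel_noise_sd = 0.5,
                       coupling = NULL,
                       confound_leak = c(global = 0.3, motion = 0.2),
                       behavior_coupling = NULL,
                       seed = 1) {
  K <- nrow(rov_specs)
  if (is.null(coupling)) {
    target <- matrix(0.35, K, K)
    diag(target) <- 0
    coupling <- list(target = target, edge_sd = c(task = 0.03, rest = 0.15))
  }
  if (is.null(behavior_coupling)) {
    behavior_coupling <- list(edges = rbind(c(1, 2), c(3, 4), c(5, 6)),
                              slope = 20, intercept = 115,
                              noise_sd = NULL, snr = 1,
                              score_sd_uncoupled = 10)
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), grid_dims = as.integer(grid_dims),
    voxel_size_mm = voxel_size_mm, n_scans = as.integer(n_scans),
    n_trials_task = as.integer(n_trials_task),
    n_timepoints_rest = as.integer(n_timepoints_rest),
    tr_seconds = tr_seconds, rov_specs = rov_specs,
    func_high_variance = func_high_variance,
    func_sd_multiplier = func_sd_multiplier,
    struct_high_variance = struct_high_variance,
    struct_sd_multiplier = struct_sd_multiplier,
    mu_contrast = mu_contrast, sigma_b_base = sigma_b_base, sigma_w = sigma_w,
    gm_template = gm_template, sigma_gm_base = sigma_gm_base,
    n_voxels_per_rov = as.integer(n_voxels_per_rov),
    loading_range = loading_range, voxel_noise_sd = voxel_noise_sd,
    coupling = coupling, confound_leak = confound_leak,
    behavior_coupling = behavior_coupling, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 4L)
  stopifnot(all(cfg$rov_specs$radius > 0))
  off <- cfg$coupling$target[upper.tri(cfg$coupling$target)]
  if (any(off < 0 | off >= 1)) {
    stop("coupling targets must lie in [0, 1)")
  }
  stopifnot(all(cfg$coupling$edge_sd >= 0))
  if (!is.null(cfg$behavior_coupling$noise_sd)) {
    stopifnot(cfg$behavior_coupling$noise_sd >= 0)
  }
  stopifnot(cfg$sigma_b_base >= 0, cfg$sigma_w >= 0, cfg$sigma_gm_base >= 0)
  invisible(cfg)
}

sim_geometry <- function(config) {
  vol_geometry(config$grid_dims, config$voxel_size_mm)
}

# Between-subject SD field: baseline times a Gaussian radial bump (peak =
# multiplier) around each designated high-variance sphere centre.
sigma_field <- function(config, base, labels, multiplier) {
  geom <- sim_geometry(config)
  profile <- array(1, dim = geom$dims)
  specs <- config$rov_specs
  for (lab in labels) {
    row <- specs[specs$label == lab, , drop = FALSE]
    if (nrow(row) == 0L) stop("unknown high-variance region label: ", lab)
    s2 <- (row$radius / 2)^2
    d2 <- dist2_to_point(geom, c(row$x, row$y, row$z))
    profile <- profile + (multiplier - 1) * exp(-d2 / (2 * s2))
  }
  base * profile
}

#' One subject's contrast and residual mean-square volumes
#'
#' @param con 3-D array of contrast values.
#' @param resms 3-D array of residual mean squares (same dims, nonnegative).
#' @param n_scans scan count of the first-level model (>= 2).
#' @param geometry a `vol_geometry`.
#' @return an object of class `subject_contrast`.
#' @export
subject_contrast <- function(con, resms, n_scans, geometry) {
  stopifnot(identical(dim(con), dim(resms)),
            identical(as.integer(dim(con)), geometry$dims))
  if (any(resms < 0)) stop("resms must be nonnegative everywhere")
  if (n_scans < 2) stop("n_scans must be >= 2")
  structure(list(con = con, resms = resms, n_scans = as.integer(n_scans),
                 geometry = geometry),
            class = "subject_contrast")
}

#' Generate a cohort of contrast / ResMS volumes
#'
#' Per voxel v and subject i, `con_i(v) = mu(v) + b_i(v)` with
#' `b_i(v) ~ N(0, sigma_B(v)^2)`; sigma_B is elevated inside the configured
#' high-variance spheres. `ResMS_i(v) = sigma_W^2 * chisq(NScan - 1)/(NScan - 1)`,
#' so its expectation is the configured within-subject variance.
#'
#' @param config a `sim_config`.
#' @return list of `subject_contrast`, one per subject.
#' @export
gen_contrast_cohort <- function(config) {
  validate_sim_config(config)
  if (any(config$grid_dims < 3L)) stop("degenerate grid: every dim must be >= 3")
  geom <- sim_geometry(config)
  nv <- n_voxels(geom)
  sig_b <- sigma_field(config, config$sigma_b_base,
                       config$func_high_variance, config$func_sd_multiplier)
  df <- config$n_scans - 1L
  lapply(seq_len(config$n_subjects), function(i) {
    with_preserved_seed(seed_stream(config$seed, 1L, i), {
      con <- array(config$mu_contrast + rnorm(nv) * sig_b, dim = geom$dims)
      resms <- array(config$sigma_w^2 * rchisq(nv, df) / df, dim = geom$dims)
      subject_contrast(con, resms, config$n_scans, geom)
    })
  })
}

#' Generate a cohort of grey-matter volume maps
#'
#' Per voxel, `gm_i(v) = template(v) + N(0, sigma_GM(v)^2)` clipped at 0;
#' sigma_GM is elevated inside the configured structural high-variance spheres.
#'
#' @param config a `sim_config`.
#' @return list of 3-D arrays with a `geometry` attribute.
#' @export
gen_gm_cohort <- function(config) {
  validate_sim_config(config)
  if (any(config$grid_dims < 3L)) stop("degenerate grid: every dim must be >= 3")
  geom <- sim_geometry(config)
  nv <- n_voxels(geom)
  sig <- sigma_field(config, config$sigma_gm_base,
                     config$struct_high_variance, config$struct_sd_multiplier)
  lapply(seq_len(config$n_subjects), function(i) {
    with_preserved_seed(seed_stream(config$seed, 2L, i), {
      gm <- array(pmax(config$gm_template + rnorm(nv) * sig, 0),
                  dim = geom$dims)
      attr(gm, "geometry") <- geom
      gm
    })
  })
}

#' Generate per-subject confound tables
#'
#' 24 motion columns (6 smooth random walks, their one-volume lag, and the 12
#' squares) plus CSF, WM and global signal modelled as low-frequency Gaussian
#' processes. One table per subject, rows = resting volumes.
#'
#' @param config a `sim_config`.
#' @return list of data.frames (n_timepoints_rest x 27).
#' @export
gen_confounds <- function(config) {
  validate_sim_config(config)
  n_t <- config$n_timepoints_rest
  smooth_gp <- function(n, width = 21L) {
    x <- stats::filter(rnorm(n + 2L * width), rep(1 / width, width),
                       sides = 2L)
    x <- x[(width + 1L):(width + n)]
    as.numeric(scale(x))
  }
  lapply(seq_len(config$n_subjects), function(i) {
    with_preserved_seed(seed_stream(config$seed, 3L, i), {
      mot <- sapply(1:6, function(j) cumsum(rnorm(n_t, 0, 0.02)))
      mot_lag <- rbind(0, mot[-n_t, , drop = FALSE])
      out <- cbind(mot, mot_lag, mot^2, mot_lag^2,
                   smooth_gp(n_t), smooth_gp(n_t), smooth_gp(n_t))
      colnames(out) <- c(sprintf("mot%02d", 1:6), sprintf("mot_lag%02d", 1:6),
                         sprintf("mot_sq%02d", 1:6),
                         sprintf("mot_lag_sq%02d", 1:6),
                         "csf", "wm", "global")
      as.data.frame(out)
    })
  })
}

# Subject-specific latent coupling matrix: population target plus edge noise,
# clipped to [0, 0.97], unit diagonal. Shared by the series generator and
# gen_fc_cohort so ground-truth networks and series agree.
gen_subject_coupling <- function(config, state, subject) {
  K <- nrow(config$rov_specs)
  code <- if (state == "task") 4L else 5L
  sd_e <- unname(config$coupling$edge_sd[state])
  with_preserved_seed(seed_stream(config$seed, code, subject), {
    C <- config$coupling$target
    noise <- matrix(0, K, K)
    noise[upper.tri(noise)] <- rnorm(K * (K - 1) / 2, 0, sd_e)
    C <- C + noise + t(noise)
    C <- pmin(pmax(C, 0), 0.97)
    diag(C) <- 1
    C
  })
}

# Nearest positive-definite repair: clamp eigenvalues, restore unit diagonal.
make_pd <- function(C, eps = 1e-6) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) > eps) return(C)
  v <- pmax(e$values, eps)
  C2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(C2))
  C2 / tcrossprod(d)
}

#' Generate ground-truth connectivity networks directly
#'
#' Emits each subject's latent coupling matrix (population target + edge
#' noise, diagonal set to 0) as a K x K network. These are the same matrices
#' that drive [gen_roi_series()], so they serve as ground truth for network
#' estimation and as fast inputs for prediction experiments.
#'
#' @param config a `sim_config`.
#' @param state "task" or "rest".
#' @return list of K x K symmetric matrices, diagonal 0, labelled by ROV.
#' @export
gen_fc_cohort <- function(config, state = c("rest", "task")) {
  state <- match.arg(state)
  validate_sim_config(config)
  labels <- config$rov_specs$label
  lapply(seq_len(config$n_subjects), function(i) {
    C <- gen_subject_coupling(config, state, i)
    diag(C) <- 0
    dimnames(C) <- list(labels, labels)
    attr(C, "state") <- state
    C
  })
}

#' Generate multi-voxel ROV series
#'
#' Latent-factor model: each ROV has one latent series; the K latents of a
#' subject are drawn jointly with the subject's coupling matrix as their
#' correlation. Each voxel series is loading x latent + iid noise. Resting
#' series additionally receive configured leakage from the global and motion
#' confounds so the cleaning stage has structure to remove.
#'
#' @param config a `sim_config`.
#' @param state "task" (beta-series, n_trials_task observations) or "rest"
#'   (n_timepoints_rest volumes).
#' @param confounds optional list of confound tables (as from
#'   [gen_confounds()]); regenerated from the config seed when NULL and
#'   leakage is requested.
#' @return an object of class `roi_series_set`: list(state, tr_seconds,
#'   labels, subjects), where `subjects[[i]]` is a named list of
#'   voxels x observations matrices.
#' @export
gen_roi_series <- function(config, state = c("rest", "task"),
                           confounds = NULL) {
  state <- match.arg(state)
  validate_sim_config(config)
  K <- nrow(config$rov_specs)
  if (K < 2L) stop("need at least 2 ROVs")
  n_t <- if (state == "task") config$n_trials_task else config$n_timepoints_rest
  if (n_t < 4L) stop("fewer than 4 observations: distance correlation undefined")
  leak <- config$confound_leak
  use_leak <- state == "rest" && any(leak > 0)
  if (use_leak && is.null(confounds)) confounds <- gen_confounds(config)
  labels <- config$rov_specs$label
  nv <- config$n_voxels_per_rov
  latent_code <- if (state == "task") 6L else 7L
  voxel_code <- if (state == "task") 8L else 9L
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    C <- make_pd(gen_subject_coupling(config, state, i))
    L <- with_preserved_seed(seed_stream(config$seed, latent_code, i), {
      crossprod(chol(C), matrix(rnorm(K * n_t), K, n_t))
    })
    with_preserved_seed(seed_stream(config$seed, voxel_code, i), {
      rovs <- lapply(seq_len(K), function(k) {
        load <- runif(nv, config$loading_range[1], config$loading_range[2])
        m <- outer(load, L[k, ]) +
          matrix(rnorm(nv * n_t, 0, config$voxel_noise_sd), nv, n_t)
        if (use_leak) {
          cf <- confounds[[i]]
          drift <- leak[["global"]] * cf$global + leak[["motion"]] * cf$mot01
          m <- m + matrix(drift, nv, n_t, byrow = TRUE)
        }
        m
      })
      names(rovs) <- labels
      rovs
    })
  })
  structure(list(state = state,
                 tr_seconds = if (state == "rest") config$tr_seconds else NA_real_,
                 labels = labels, subjects = subjects),
            class = "roi_series_set")
}

#' Generate behavior scores coupled to a designated edge set
#'
#' `score_i = intercept + slope * sum of designated edges + N(0, noise_sd)`.
#' When `noise_sd` is NULL it is derived from the configured signal-to-noise
#' ratio as sd(signal)/snr. A second, uncoupled score and a brain-size
#' covariate are also emitted.
#'
#' @param networks list of K x K matrices (one per subject).
#' @param config a `sim_config`.
#' @param gm_cohort optional GM maps; when given, brain_size is total GM
#'   volume (value sum x voxel volume, cm^3), otherwise N(1250, 100).
#' @return data.frame(subject_id, score_read, score_vocab, brain_size) with a
#'   `truth` attribute (edges, slope, noise_sd, edge_sum).
#' @export
gen_behavior <- function(networks, config, gm_cohort = NULL) {
  validate_sim_config(config)
  n <- length(networks)
  bc <- config$behavior_coupling
  K <- nrow(networks[[1]])
  edges <- bc$edges
  if ((is.null(edges) || nrow(edges) == 0L) && bc$slope != 0) {
    stop("empty edge set with nonzero slope")
  }
  if (!is.null(edges) && nrow(edges) > 0L &&
      any(edges < 1L | edges > K)) {
    stop("behavior edge set refers to nonexistent nodes")
  }
  edge_sum <- if (is.null(edges) || nrow(edges) == 0L) rep(0, n) else {
    vapply(networks, function(m) {
      sum(m[cbind(edges[, 1], edges[, 2])])
    }, numeric(1))
  }
  signal <- bc$slope * edge_sum
  noise_sd <- bc$noise_sd
  if (is.null(noise_sd)) {
    s <- sd(signal)
    # no signal (e.g. slope 0): scores are pure noise on the uncoupled scale
    noise_sd <- if (is.finite(s) && s > 0) s / bc$snr else bc$score_sd_uncoupled
  }
  with_preserved_seed(seed_stream(config$seed, 10L), {
    score_read <- bc$intercept + signal + rnorm(n, 0, noise_sd)
    score_vocab <- rnorm(n, bc$intercept, bc$score_sd_uncoupled)
    brain_size <- if (is.null(gm_cohort)) rnorm(n, 1250, 100) else {
      vs <- config$voxel_size_mm^3 / 1000
      vapply(gm_cohort, function(g) sum(g) * vs, numeric(1))
    }
    out <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                      score_read = score_read, score_vocab = score_vocab,
                      brain_size = brain_size)
    attr(out, "truth") <- list(edges = edges, slope = bc$slope,
                               noise_sd = noise_sd, edge_sum = edge_sum)
    out
  })
}

#' Scores coupled to a single marker at a target correlation
#'
#' Utility for marker-level validation: draws a score with population Pearson
#' correlation `r_target` to `marker`.
#'
#' @param marker numeric vector.
#' @param r_target target correlation.
#' @param mean,sd score scale.
#' @param seed integer seed.
#' @return numeric score vector.
#' @export
gen_marker_coupled_scores <- function(marker, r_target = 0.4,
                                      mean = 115, sd = 10, seed = 1) {
  z <- as.numeric(scale(marker))
  with_preserved_seed(seed, {
    mean + sd * (r_target * z + sqrt(1 - r_target^2) * rnorm(length(z)))
  })
}

#' Generate a full synthetic cohort
#'
#' Assembles every artifact the pipeline consumes: contrast/ResMS maps, GM
#' maps, confound tables, task and rest multi-voxel ROV series, ground-truth
#' coupling networks, a behavior table coupled to rest-network edges, and a
#' ground-truth record.
#'
#' @param config a `sim_config`.
#' @return an object of class `synthetic_cohort`.
#' @export
gen_cohort <- function(config) {
  validate_sim_config(config)
  contrasts <- gen_contrast_cohort(config)
  gm_maps <- gen_gm_cohort(config)
  confounds <- gen_confounds(config)
  task_series <- gen_roi_series(config, "task")
  rest_series <- gen_roi_series(config, "rest", confounds = confounds)
  networks <- list(task = gen_fc_cohort(config, "task"),
                   rest = gen_fc_cohort(config, "rest"))
  behavior <- gen_behavior(networks$rest, config, gm_cohort = gm_maps)
  truth <- list(
    sigma_b_field = sigma_field(config, config$sigma_b_base,
                                config$func_high_variance,
                                config$func_sd_multiplier),
    sigma_gm_field = sigma_field(config, config$sigma_gm_base,
                                 config$struct_high_variance,
                                 config$struct_sd_multiplier),
    func_high_variance = config$func_high_variance,
    struct_high_variance = config$struct_high_variance,
    behavior = attr(behavior, "truth"))
  structure(list(config = config, contrasts = contrasts, gm_maps = gm_maps,
                 confounds = confounds, task_series = task_series,
                 rest_series = rest_series, networks = networks,
                 behavior = behavior, truth = truth),
            class = "synthetic_cohort")
}
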