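#' Configuration for single-vessel studies
#'
#' The head-to-head comparisons (multi- vs single-stage, network vs
#' projection baseline) are run on single RCA vessels. This helper
#' returns a [generator_config()] with only the RCA template, a reduced
#' per-branch point count suited to CPU-scale models, and lesions
#' restricted to the RCA.
#'
#' @param N points per vessel.
#' @param stenosis_count_prob lesion-count distribution.
#' @return a [generator_config()] with `M = 1`.
#' @export
single_vessel_config <- function(N = 20,
                                 stenosis_count_prob = c(0.25, 0.75)) {
  generator_config(N = N,
                   templates = default_branch_templates()["RCA"],
                   stenosis_count_prob = stenosis_count_prob,
                   lesion_branches = "RCA",
                   p_warp = 0.3)
}

#' Acquisition protocol for single-vessel studies
#'
#' Two-view protocol at reduced detector resolution for CPU-scale
#' experiments: nominal working views LAO 45 and RAO 45 with 20-degree
#' sampling windows, and a coarser detector keeping the full-scale 1.6
#' magnification (wider pixels, 192 mm field) so whole vessels stay in
#' view. Models trained under this protocol see inter-view angles near
#' 90 degrees only; see the methods vignette for what that implies for
#' the projection-angle sweep.
#'
#' @param image_size detector pixels per side (multiple of 16).
#' @param pixel_pitch mm per pixel.
#' @return a [view_sampler()] with `views_per_tree = inputs_per_sample = 2`.
#' @export
single_vessel_sampler <- function(image_size = 96L, pixel_pitch = 2.0) {
  view_sampler(nominal_views = rbind(c(-45, 0), c(45, 0)), window = 20,
               views_per_tree = 2L, inputs_per_sample = 2L,
               image_size = image_size, pixel_pitch = pixel_pitch)
}

#' Build network training samples from trees
#'
#' Projects each tree under the sampler, applies the distance transform,
#' and selects `inputs_per_sample` maps per tree (ascending view-index
#' channel order).
#'
#' @param trees list of [coronary_tree()].
#' @param sampler a [view_sampler()].
#' @param seed RNG seed (views and map selection).
#' @return list of `list(maps =, tree =)` samples.
#' @export
make_training_samples <- function(trees, sampler, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  lapply(seq_along(trees), function(i) {
    pset <- build_projection_set(trees[[i]], sampler, tree_id = i)
    maps <- choose_training_inputs(pset, sampler$inputs_per_sample)
    list(maps = maps, tree = trees[[i]])
  })
}

#' Single- versus multi-stage stress comparison
#'
#' Reproduces the stenosis-severity stress design: `base_vessels`
#' lesion-free vessels are generated, and for each one a lesion of every
#' severity on the grid is injected at a fixed (per-vessel) location --
#' `length(severities) * base_vessels` unique geometries (150 under the
#' defaults). Each geometry is projected and reconstructed by both
#' models; centerline RMSE and stenosis MAE are tabulated per geometry.
#'
#' @param model_multi,model_single trained [train_multistage()] /
#'   [train_single_stage()] models sharing input configuration.
#' @param base_vessels number of distinct vessel geometries.
#' @param severities percent-diameter-reduction grid.
#' @param config generator configuration (single vessel).
#' @param sampler acquisition protocol matching the models.
#' @param seed RNG seed.
#' @return data frame, one row per geometry and model.
#' @export
run_stress_set <- function(model_multi, model_single, base_vessels = 10L,
                           severities = seq(20, 90, by = 5),
                           config = single_vessel_config(),
                           sampler = single_vessel_sampler(), seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  config$stenosis_count_prob <- c(1)     # lesion-free base vessels
  rows <- list()
  for (v in seq_len(base_vessels)) {
    base <- generate_tree(config)
    t0 <- stats::runif(1, 0.3, 0.7)
    sigma <- stats::runif(1, 0.04, 0.08)
    for (s in severities) {
      spec <- stenosis_spec(t0, s, sigma, branch = "RCA")
      dat <- unclass(base)
      dat[1, , 4] <- apply_stenoses(base[1, , 4], list(spec))
      tree <- coronary_tree(dat, branch_names = attr(base, "branch_names"),
                            lesions = list(spec))
      pset <- build_projection_set(tree, sampler)
      maps <- pset$distance_maps
      for (mode in c("multi", "single")) {
        model <- if (mode == "multi") model_multi else model_single
        pred <- predict(model, maps)
        rows[[length(rows) + 1L]] <- data.frame(
          vessel = v, severity = s, model = mode,
          centerline_rmse = centerline_rmse(tree, pred),
          stenosis_mae = stenosis_mae(tree, pred),
          radius_rmse = radius_rmse(tree, pred))
      }
    }
  }
  do.call(rbind, rows)
}

#' Projection-angle sweep: network versus projection baseline
#'
#' For each of `vessels` lesion-free single vessels and each angular
#' separation in `dtheta`, renders a pair of projections with the first
#' view fixed at azimuth -45 degrees, elevation 0, and the second at
#' `-45 + dtheta`. The projection-geometry baseline reconstructs from
#' full-resolution binary images with true geometry; the network
#' reconstructs from reduced-resolution distance maps with no geometry.
#' Centerline RMSE against the (arclength-resampled) ground truth is
#' reported per pair and method.
#'
#' @param model trained 2-view single-vessel network.
#' @param vessels number of vessels.
#' @param dtheta angular separations (degrees).
#' @param config generator configuration (single vessel).
#' @param sampler network acquisition protocol (resolution/pitch).
#' @param baseline_image_size detector resolution for the baseline.
#' @param seed RNG seed.
#' @return data frame with one row per vessel x dtheta.
#' @export
run_dtheta_sweep <- function(model, vessels = 5L,
                             dtheta = c(15, 30, 45, 60, 75, 90),
                             config = single_vessel_config(),
                             sampler = single_vessel_sampler(),
                             baseline_image_size = 512L, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  config$stenosis_count_prob <- c(1)
  rows <- list()
  for (v in seq_len(vessels)) {
    tree <- generate_tree(config)
    N <- dim(tree)[2]
    gt_cl <- resample_polyline(matrix(tree[1, , 1:3], N, 3), N)
    for (dt in dtheta) {
      angs <- c(-45, -45 + dt)
      views_hi <- lapply(angs, function(a)
        view_geometry(a, 0, image_size = baseline_image_size))
      views_lo <- lapply(angs, function(a)
        view_geometry(a, 0, image_size = sampler$image_size,
                      pixel_pitch = sampler$pixel_pitch))
      imgs_hi <- lapply(views_hi, function(vw) cone_beam_project(tree, vw))
      maps_lo <- lapply(views_lo, function(vw)
        distance_transform(cone_beam_project(tree, vw)))
      rmse_base <- tryCatch({
        rec <- reconstruct_baseline(imgs_hi, views_hi, n_out = N)
        sqrt(mean(rowSums((gt_cl - matrix(rec[1, , 1:3], N, 3))^2)))
      }, error = function(e) NA_real_)
      pred <- predict(model, maps_lo)
      rmse_net <- sqrt(mean(rowSums(
        (gt_cl - resample_polyline(matrix(pred[1, , 1:3], N, 3), N))^2)))
      rows[[length(rows) + 1L]] <- data.frame(
        vessel = v, dtheta = dt, theta_ref = -45,
        rmse_baseline = rmse_base, rmse_network = rmse_net)
    }
  }
  do.call(rbind, rows)
}

#' Build seeded fixture bundles
#'
#' Deterministic bundles used by tests and examples: `unit` -- 3
#' single-vessel trees with 2-view reduced-resolution projection sets;
#' `smoke` -- 20 four-branch trees with 5-view full-resolution
#' projection sets; `desk` -- the geometry sets of the two comparison
#' studies (the severity-stress geometries and the angle-sweep image
#' pairs), without model predictions.
#'
#' @param scale one of `"unit"`, `"smoke"`, `"desk"`.
#' @param seed RNG seed.
#' @return a named list of fixtures (structure depends on `scale`).
#' @export
make_fixtures <- function(scale = c("unit", "smoke", "desk"), seed = 1L) {
  scale <- match.arg(scale)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  if (scale == "unit") {
    cfg <- single_vessel_config()
    smp <- single_vessel_sampler(image_size = 128L, pixel_pitch = 1.4)
    trees <- lapply(1:3, function(i) generate_tree(cfg))
    psets <- lapply(trees, function(t) build_projection_set(t, smp))
    list(trees = trees, projection_sets = psets, sampler = smp)
  } else if (scale == "smoke") {
    cfg <- generator_config()
    smp <- view_sampler()
    trees <- lapply(1:20, function(i) generate_tree(cfg))
    psets <- lapply(trees, function(t) build_projection_set(t, smp))
    list(trees = trees, projection_sets = psets, sampler = smp)
  } else {
    cfg <- single_vessel_config()
    cfg$stenosis_count_prob <- c(1)
    stress <- list()
    set.seed(seed)
    for (v in 1:10) {
      base <- generate_tree(cfg)
      t0 <- stats::runif(1, 0.3, 0.7); sg <- stats::runif(1, 0.04, 0.08)
      for (s in seq(20, 90, by = 5)) {
        spec <- stenosis_spec(t0, s, sg, branch = "RCA")
        dat <- unclass(base)
        dat[1, , 4] <- apply_stenoses(base[1, , 4], list(spec))
        stress[[length(stress) + 1L]] <-
          coronary_tree(dat, branch_names = "RCA", lesions = list(spec))
      }
    }
    sweep_trees <- lapply(1:5, function(i) generate_tree(cfg))
    list(stress_trees = stress, sweep_trees = sweep_trees,
         dtheta = c(15, 30, 45, 60, 75, 90))
  }
}

#' Train the desk-scale comparison models
#'
#' One call producing the paired multi- and single-stage models used by
#' the severity-stress and angle-sweep studies: generates `n_train`
#' single-vessel trees, projects them under the two-view protocol, and
#' trains both networks with identical hyperparameters. Problem sizes
#' (N = 20 points, 96 px detectors, 25 + 50 epochs) are the package's
#' CPU-scale study conditions; see the methods vignette.
#'
#' @param n_train training-set size.
#' @param seed root seed; data, view sampling and both trainings derive
#'   from it deterministically.
#' @param config generator configuration.
#' @param sampler acquisition protocol.
#' @param epochs_main,epochs_finetune training lengths.
#' @return list with `multi`, `single` (trained models) and `samples`.
#' @export
train_study_models <- function(n_train = 200L, seed = 1L,
                               config = single_vessel_config(),
                               sampler = single_vessel_sampler(),
                               epochs_main = 25L, epochs_finetune = 50L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  trees <- lapply(seq_len(n_train), function(i) generate_tree(config))
  samples <- make_training_samples(trees, sampler, seed = seed + 1L)
  tc <- train_config(epochs_main = epochs_main,
                     epochs_radius_finetune = epochs_finetune,
                     seed = seed + 2L)
  list(multi = train_multistage(samples, tc),
       single = train_single_stage(samples, tc),
       samples = samples)
}
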