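#' Sample one branch centerline from a template
#'
#' Perturbs the template control points with isotropic Gaussian noise,
#' fits a natural cubic spline through them (chord-length
#' parameterization), and evaluates it at `N` uniformly spaced parameter
#' values, ordered proximal to distal. Draws producing a degenerate spline
#' (numerically coincident control points) are redrawn up to `max_retry`
#' times.
#'
#' Uses R's global RNG; seed upstream for reproducibility.
#'
#' @param template a [branch_template()].
#' @param N number of output points.
#' @param max_retry retry cap for degenerate draws.
#' @return `N x 3` matrix (mm).
#' @export
sample_branch_centerline <- function(template, N = 100, max_retry = 20L) {
  K <- nrow(template$control_points)
  for (i in seq_len(max_retry)) {
    noise <- matrix(stats::rnorm(K * 3), K, 3) * template$control_point_sigma
    cp <- template$control_points + noise
    seg <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-K, , drop = FALSE])^2))
    if (all(seg > 1e-6)) return(eval_spline_polyline(cp, N))
  }
  stop("could not sample a non-degenerate centerline after ", max_retry,
       " attempts")
}

# natural cubic spline through control points, chord-length parameterized
eval_spline_polyline <- function(cp, N) {
  K <- nrow(cp)
  seg <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-K, , drop = FALSE])^2))
  t0 <- c(0, cumsum(seg)); t0 <- t0 / t0[length(t0)]
  tt <- seq(0, 1, length.out = N)
  out <- sapply(1:3, function(j)
    stats::splinefun(t0, cp[, j], method = "natural")(tt))
  matrix(out, N, 3)
}

#' Linearly tapering radius profile
#'
#' The lesion-free radius model: `N` radii decreasing linearly from the
#' proximal `r_max` to the distal `r_min`.
#'
#' @param r_max,r_min proximal and distal radius (mm), `r_max > r_min > 0`.
#' @param N number of points (>= 2).
#' @return numeric vector of length `N`.
#' @export
sample_radius_profile <- function(r_max, r_min, N) {
  if (!(r_max > r_min && r_min > 0)) stop("need r_max > r_min > 0")
  if (N < 2L) stop("N must be >= 2")
  seq(r_max, r_min, length.out = N)
}

#' Stenosis specification
#'
#' One focal lesion: a Gaussian-profile multiplicative narrowing of the
#' radius, centred at parametric position `t0` along the branch, with
#' width `sigma` (fraction of the branch's parametric length) and
#' `severity` percent diameter reduction at its centre.
#'
#' @param t0 centre position in `[0, 1]`.
#' @param severity percent diameter reduction in `[20, 90]`.
#' @param sigma Gaussian width in `(0, 0.5)`.
#' @param branch branch label the lesion applies to (bookkeeping).
#' @return an object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(t0, severity, sigma, branch = NA_character_) {
  if (severity < 20 || severity > 90)
    stop("severity must lie in [20, 90] percent")
  if (sigma <= 0 || sigma >= 0.5) stop("sigma must lie in (0, 0.5)")
  if (t0 < 0 || t0 > 1) stop("t0 must lie in [0, 1]")
  structure(list(t0 = t0, severity = severity, sigma = sigma,
                 branch = branch), class = "stenosis_spec")
}

#' Apply Gaussian-profile stenoses to a radius vector
#'
#' Each lesion multiplies the radius by
#' `1 - (severity/100) * exp(-(t - t0)^2 / (2 sigma^2))`
#' on the parametric grid `t = seq(0, 1, length.out = N)`; multiple
#' lesions compound multiplicatively. Severity is thus percent diameter
#' reduction relative to the local lesion-free taper at the lesion centre.
#'
#' @param radii positive radius vector.
#' @param lesions list of [stenosis_spec()] (may be empty).
#' @return narrowed radius vector, same length, all positive.
#' @export
apply_stenoses <- function(radii, lesions) {
  if (any(radii <= 0)) stop("radii must be positive")
  if (!length(lesions)) return(radii)
  tt <- seq(0, 1, length.out = length(radii))
  for (l in lesions) {
    stopifnot(inherits(l, "stenosis_spec"))
    radii <- radii * (1 - (l$severity / 100) *
                        exp(-(tt - l$t0)^2 / (2 * l$sigma^2)))
  }
  radii
}

#' Augmentation parameters
#'
#' A rigid-plus-deforming transform applied to the whole tree about its
#' centroid: an Euler rotation, a unit-diagonal shear, and a smooth
#' low-frequency warp (sum of three 3D cosine displacement modes).
#' Radii are untouched.
#'
#' @param rotation Euler angles (degrees, applied z-y-x).
#' @param shear off-diagonal coefficients `(xy, xz, yx, yz, zx, zy)` of a
#'   unit-diagonal shear matrix.
#' @param warp_amplitude displacement amplitude (mm, >= 0).
#' @param warp_scale spatial scale of the warp modes (mm).
#' @param warp_phase,warp_dirs optional mode phases (length 3) and unit
#'   direction matrix (`3 x 3`); randomized by [augment_tree()] when `NULL`.
#' @return object of class `augmentation_params`.
#' @export
augmentation_params <- function(rotation = c(0, 0, 0),
                                shear = rep(0, 6),
                                warp_amplitude = 0, warp_scale = 60,
                                warp_phase = NULL, warp_dirs = NULL) {
  if (warp_amplitude < 0) stop("warp amplitude must be >= 0")
  structure(list(rotation = rotation, shear = shear,
                 warp_amplitude = warp_amplitude, warp_scale = warp_scale,
                 warp_phase = warp_phase, warp_dirs = warp_dirs),
            class = "augmentation_params")
}

euler_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rz %*% Ry %*% Rx
}

shear_matrix <- function(s) {
  rbind(c(1,    s[1], s[2]),
        c(s[3], 1,    s[4]),
        c(s[5], s[6], 1))
}

#' Augment a coronary tree
#'
#' Applies rotation, shear and warp about the tree centroid, identically
#' to every branch (the tree moves as one unit). Radii are unchanged.
#' When the warp amplitude is positive and no phases/directions are given
#' they are drawn from the global RNG.
#'
#' @param tree a [coronary_tree()].
#' @param params an [augmentation_params()].
#' @return transformed `coronary_tree`.
#' @export
augment_tree <- function(tree, params) {
  M <- dim(tree)[1]; N <- dim(tree)[2]
  pts <- matrix(aperm(unclass(tree)[, , 1:3, drop = FALSE], c(2, 1, 3)),
                M * N, 3)
  centroid <- colMeans(pts)
  x <- sweep(pts, 2, centroid)
  A <- euler_matrix(params$rotation) %*% shear_matrix(params$shear)
  x <- x %*% t(A)
  if (params$warp_amplitude > 0) {
    phase <- params$warp_phase
    dirs <- params$warp_dirs
    if (is.null(phase)) phase <- stats::runif(3, 0, 2 * pi)
    if (is.null(dirs)) {
      dirs <- matrix(stats::rnorm(9), 3, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
    }
    for (k in 1:3) {
      arg <- 2 * pi * (x %*% dirs[k, ]) / params$warp_scale + phase[k]
      x[, k] <- x[, k] + params$warp_amplitude * cos(arg)
    }
  }
  x <- sweep(x, 2, centroid, "+")
  out <- unclass(tree)
  out[, , 1:3] <- aperm(array(x, c(N, M, 3)), c(2, 1, 3))
  coronary_tree(out, branch_names = attr(tree, "branch_names"),
                lesions = attr(tree, "lesions"))
}

#' Generate one randomized coronary tree
#'
#' Full per-tree workflow: sample the RCA centerline, sample side-branch
#' take-off points within their parametric windows on the RCA, sample each
#' side-branch centerline anchored at its take-off, draw radius endpoints
#' and build linear tapers, inject a random number of Gaussian stenoses,
#' assemble the `M x N x 4` matrix, and (optionally) augment.
#'
#' Uses the global RNG; see [generate_dataset()] for seeded batches.
#'
#' @param config a [generator_config()].
#' @param augment apply random rotation/shear/warp augmentation.
#' @return a [coronary_tree()] with its lesion list attached.
#' @export
generate_tree <- function(config, augment = TRUE) {
  N <- config$N
  tmpl <- config$templates
  rca <- sample_branch_centerline(tmpl[[1]], N)
  branches <- vector("list", length(tmpl))
  origins <- vector("list", length(tmpl))
  branches[[1]] <- list(centerline = rca)
  for (m in seq_along(tmpl)[-1]) {
    tw <- tmpl[[m]]$takeoff_window
    if (is.null(tw)) stop("side-branch template lacks a takeoff_window")
    t_take <- stats::runif(1, tw[1], tw[2])
    idx <- t_take * (N - 1) + 1
    i0 <- floor(idx); frac <- idx - i0
    origin <- if (i0 >= N) rca[N, ] else
      (1 - frac) * rca[i0, ] + frac * rca[i0 + 1, ]
    branches[[m]] <- list(centerline = sample_branch_centerline(tmpl[[m]], N))
    origins[[m]] <- origin
  }
  # radii: rejection-sample r_max/r_min pairs
  for (m in seq_along(tmpl)) {
    repeat {
      r_max <- stats::runif(1, tmpl[[m]]$r_max_range[1], tmpl[[m]]$r_max_range[2])
      r_min <- stats::runif(1, tmpl[[m]]$r_min_range[1], tmpl[[m]]$r_min_range[2])
      if (r_min < r_max) break
    }
    branches[[m]]$radius <- sample_radius_profile(r_max, r_min, N)
  }
  # lesions
  n_lesions <- sample.int(length(config$stenosis_count_prob), 1,
                          prob = config$stenosis_count_prob) - 1L
  lesions <- list()
  if (n_lesions > 0) {
    eligible <- which(config$branch_names %in% config$lesion_branches)
    for (i in seq_len(n_lesions)) {
      m <- if (length(eligible) == 1L) eligible else sample(eligible, 1)
      spec <- stenosis_spec(
        t0 = stats::runif(1, config$t0_range[1], config$t0_range[2]),
        severity = stats::runif(1, config$severity_range[1],
                                config$severity_range[2]),
        sigma = stats::runif(1, config$sigma_range[1], config$sigma_range[2]),
        branch = config$branch_names[m])
      branches[[m]]$radius <- apply_stenoses(branches[[m]]$radius, list(spec))
      lesions <- c(lesions, list(spec))
    }
  }
  tree <- assemble_tree(branches, branch_names = config$branch_names,
                        origins = origins, lesions = lesions)
  if (augment) {
    params <- augmentation_params(
      rotation = stats::rnorm(3, 0, config$rotation_sd),
      shear = if (stats::runif(1) < config$p_shear)
        stats::runif(6, config$shear_range[1], config$shear_range[2])
      else rep(0, 6),
      warp_amplitude = if (stats::runif(1) < config$p_warp)
        config$warp_amplitude else 0,
      warp_scale = config$warp_scale)
    tree <- augment_tree(tree, params)
  }
  tree
}

#' Generate a train/validation dataset of coronary trees
#'
#' Generates `count` trees under a fixed seed and splits them disjointly,
#' with `round(split_fraction * count)` trees for training; membership is
#' a pure function of the seed.
#'
#' @param config a [generator_config()].
#' @param count number of trees (>= 1).
#' @param split_fraction training fraction in (0, 1); default the 90/10
#'   convention.
#' @param seed RNG seed.
#' @param augment passed to [generate_tree()].
#' @return `list(train = , validation = )` of `coronary_tree` lists.
#' @export
generate_dataset <- function(config, count, split_fraction = 0.9,
                             seed = 1L, augment = TRUE) {
  if (count < 1L) stop("count must be >= 1")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  trees <- lapply(seq_len(count), function(i) generate_tree(config, augment))
  n_train <- round(split_fraction * count)
  train_idx <- sort(sample.int(count, n_train))
  list(train = trees[train_idx],
       validation = trees[setdiff(seq_len(count), train_idx)])
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
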