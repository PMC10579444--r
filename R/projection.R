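#' Cone-beam view geometry
#'
#' One X-ray acquisition: a point source on a sphere of radius `SOD`
#' (source-to-isocenter distance) around the isocenter, at azimuth
#' `theta` and elevation `phi`, with a flat detector perpendicular to the
#' source-isocenter ray at distance `SID` (source-to-detector) from the
#' source. The source position, detector centre and in-plane axes are
#' pure functions of these parameters, so a view is fully described by
#' five numbers. The detector's horizontal axis is the world-horizontal
#' direction perpendicular to the viewing ray and its vertical axis
#' points towards +z for `phi = 0` ("head-up" display convention).
#'
#' Defaults are typical C-arm values: SOD 750 mm, SID 1200 mm
#' (magnification 1.6), 512 px covering a 200 mm field
#' (0.390625 mm/px).
#'
#' @param theta azimuth (degrees).
#' @param phi elevation (degrees).
#' @param SOD source-to-isocenter distance (mm).
#' @param SID source-to-detector distance (mm), `SID > SOD > 0`.
#' @param pixel_pitch detector sampling (mm/pixel).
#' @param image_size square image side (pixels).
#' @return object of class `view_geometry` with precomputed `source`,
#'   `center` (detector centre) and unit axes `e1`, `e2`, `axis`.
#' @export
view_geometry <- function(theta, phi, SOD = 750, SID = 1200,
                          pixel_pitch = 0.390625, image_size = 512L) {
  if (!(SID > SOD && SOD > 0)) stop("need SID > SOD > 0")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  th <- theta * pi / 180; ph <- phi * pi / 180
  u <- c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))  # isocenter -> source
  source <- SOD * u
  center <- source - SID * u
  e1 <- c(-sin(th), cos(th), 0)                          # horizontal
  e2 <- cross3(u, e1)                                    # "up" for phi = 0
  structure(list(theta = theta, phi = phi, SOD = SOD, SID = SID,
                 pixel_pitch = pixel_pitch, image_size = as.integer(image_size),
                 source = source, center = center, axis = u,
                 e1 = e1, e2 = e2),
            class = "view_geometry")
}

#' Project 3D points into a view's pixel coordinates
#'
#' Perspective projection through the point source onto the detector
#' plane; returns fractional `(row, col)` pixel coordinates (row 1 at the
#' top of the image).
#'
#' @param view a [view_geometry()].
#' @param points `n x 3` matrix (mm).
#' @return `n x 2` matrix of `(row, col)`.
#' @export
project_points <- function(view, points) {
  points <- matrix(points, ncol = 3)
  w <- sweep(points, 2, view$source)                 # source -> point
  denom <- drop(w %*% view$axis)                     # < 0 towards detector
  s <- -view$SID / denom
  P <- sweep(w * s, 2, view$source, "+")             # on detector plane
  d <- sweep(P, 2, view$center)
  a <- drop(d %*% view$e1); b <- drop(d %*% view$e2)
  half <- (view$image_size + 1) / 2
  cbind(row = half - b / view$pixel_pitch,
        col = half + a / view$pixel_pitch)
}

# 3D position of pixel centres (row, col can be fractional)
pixel_points <- function(view, row, col) {
  half <- (view$image_size + 1) / 2
  a <- (col - half) * view$pixel_pitch
  b <- (half - row) * view$pixel_pitch
  sweep(outer(a, view$e1) + outer(b, view$e2), 2, view$center, "+")
}

#' Render the binary cone-beam silhouette of a tree
#'
#' For every detector pixel, the pixel is foreground (1) exactly when the
#' ray from the source through the pixel centre passes within the local
#' (linearly interpolated) radius of any centerline segment -- an exact
#' capsule intersection test on the piecewise-linear centerline. No
#' anti-aliasing or attenuation physics; the output is the binarized
#' angiogram silhouette. Segments are culled by a conservative projected
#' bounding box so cost scales with the silhouette area, not the image.
#'
#' @param tree a [coronary_tree()] (or any `M x N x 4` array; `M = 0`
#'   gives an all-zero image).
#' @param view a [view_geometry()].
#' @return `image_size x image_size` integer matrix of 0/1.
#' @export
cone_beam_project <- function(tree, view) {
  n <- view$image_size
  img <- matrix(0L, n, n)
  if (length(tree) == 0 || dim(tree)[1] == 0) return(img)
  M <- dim(tree)[1]; N <- dim(tree)[2]
  S <- view$source
  mag_px <- view$SID / view$SOD / view$pixel_pitch  # px per mm at isocenter
  clipped <- FALSE
  for (m in seq_len(M)) {
    p <- matrix(tree[m, , 1:3], N, 3)
    r <- tree[m, , 4]
    pix <- project_points(view, p)
    if (any(pix < 1 | pix > n)) clipped <- TRUE
    for (i in seq_len(max(N - 1, 1))) {
      j <- min(i + 1, N)
      A <- p[i, ]; B <- p[j, ]
      rA <- r[i]; rB <- r[j]
      rad_px <- max(rA, rB) * mag_px * 1.6 + 2      # conservative margin
      r0 <- floor(min(pix[i, 1], pix[j, 1]) - rad_px)
      r1 <- ceiling(max(pix[i, 1], pix[j, 1]) + rad_px)
      c0 <- floor(min(pix[i, 2], pix[j, 2]) - rad_px)
      c1 <- ceiling(max(pix[i, 2], pix[j, 2]) + rad_px)
      r0 <- max(r0, 1); r1 <- min(r1, n); c0 <- max(c0, 1); c1 <- min(c1, n)
      if (r0 > r1 || c0 > c1) next
      rows <- r0:r1; cols <- c0:c1
      # pixel rays: direction u = P - S (normalized)
      P <- pixel_points(view, rep(rows, times = length(cols)),
                        rep(cols, each = length(rows)))
      U <- sweep(P, 2, S)
      U <- U / sqrt(rowSums(U^2))
      w0 <- S - A
      v <- B - A
      cc <- sum(v * v)
      dvec <- drop(U %*% w0)                         # u . w0
      if (cc < 1e-12) {
        # degenerate segment: point-capsule (sphere)
        perp2 <- rowSums(sweep(U * dvec, 2, w0, "-")^2)
        hit <- perp2 <= rA^2
      } else {
        bcoef <- drop(U %*% v)                       # u . v
        e <- sum(v * w0)
        denom <- cc - bcoef^2
        tpar <- ifelse(denom > 1e-12, (e - bcoef * dvec) / denom, 0)
        tpar <- pmin(pmax(tpar, 0), 1)
        s <- bcoef * tpar - dvec
        # closest point difference: S + s u - (A + t v)
        diff <- U * s - outer(tpar, v)
        diff <- sweep(diff, 2, w0, "+")
        rloc <- rA + tpar * (rB - rA)
        hit <- rowSums(diff^2) <= rloc^2
      }
      if (any(hit)) {
        idx <- cbind(rep(rows, times = length(cols))[hit],
                     rep(cols, each = length(rows))[hit])
        img[idx] <- 1L
      }
    }
  }
  if (clipped)
    warning("tree extends beyond the detector field of view; silhouette clipped")
  img
}

#' Euclidean distance transform of a binary image
#'
#' Per-pixel Euclidean distance (in pixels) from each foreground pixel to
#' the nearest background pixel; background pixels are 0, so an isolated
#' foreground pixel has value 1. This smooth field implicitly encodes the
#' projected centerline (its ridge) and the projected radius (the ridge
#' height), and is the network's input representation.
#'
#' @param image binary matrix (0/1).
#' @return numeric matrix of the same shape.
#' @export
distance_transform <- function(image) {
  if (!all(image %in% c(0, 1))) stop("image must be binary")
  if (!any(image == 1)) return(matrix(0, nrow(image), ncol(image)))
  dm <- EBImage::distmap(matrix(as.numeric(image), nrow(image), ncol(image)),
                         metric = "euclidean")
  matrix(as.numeric(EBImage::imageData(dm)), nrow(image), ncol(image))
}

#' View sampler
#'
#' Randomized acquisition protocol: a set of nominal clinical working
#' views (azimuth/elevation pairs) with each realized view drawn
#' uniformly from a window of `window` degrees centred on its nominal
#' value. Defaults are five standard right-coronary working views
#' (LAO 45, RAO 30, cranial AP, LAO-caudal, RAO-cranial).
#'
#' @param nominal_views matrix/2-col data of `(theta, phi)` in degrees.
#' @param window full window width in degrees: a scalar (same window for
#'   every view and both angles) or an `n_views x 2` matrix of per-view
#'   `(theta, phi)` windows (wide azimuth windows train a model across a
#'   broad range of inter-view angles).
#' @param views_per_tree views rendered per tree.
#' @param inputs_per_sample distance maps fed to the network per sample.
#' @param SOD,SID,pixel_pitch,image_size forwarded to [view_geometry()].
#' @return object of class `view_sampler`.
#' @export
view_sampler <- function(nominal_views = rbind(c(-45, 0), c(30, 0), c(0, 30),
                                               c(-30, -25), c(45, 25)),
                         window = 20, views_per_tree = 5L,
                         inputs_per_sample = 3L,
                         SOD = 750, SID = 1200, pixel_pitch = 0.390625,
                         image_size = 512L) {
  nominal_views <- matrix(as.numeric(as.matrix(nominal_views)), ncol = 2)
  if (views_per_tree < inputs_per_sample || inputs_per_sample < 2L)
    stop("need views_per_tree >= inputs_per_sample >= 2")
  if (length(window) == 1L)
    window <- matrix(window, nrow(nominal_views), 2)
  window <- matrix(as.numeric(as.matrix(window)), ncol = 2)
  if (nrow(window) != nrow(nominal_views))
    stop("window must be scalar or have one row per nominal view")
  structure(list(nominal_views = nominal_views, window = window,
                 views_per_tree = as.integer(views_per_tree),
                 inputs_per_sample = as.integer(inputs_per_sample),
                 SOD = SOD, SID = SID, pixel_pitch = pixel_pitch,
                 image_size = as.integer(image_size)),
            class = "view_sampler")
}

#' Draw randomized view geometries
#'
#' Returns `views_per_tree` geometries; view `i` is drawn uniformly from
#' `+/- window/2` degrees around nominal view `1 + (i-1) mod n_nominal`
#' in both angles.
#'
#' @param sampler a [view_sampler()].
#' @return list of [view_geometry()].
#' @export
sample_views <- function(sampler) {
  nv <- nrow(sampler$nominal_views)
  lapply(seq_len(sampler$views_per_tree), function(i) {
    k <- 1 + (i - 1) %% nv
    nom <- sampler$nominal_views[k, ]
    h <- sampler$window[k, ] / 2
    view_geometry(theta = nom[1] + stats::runif(1, -h[1], h[1]),
                  phi = nom[2] + stats::runif(1, -h[2], h[2]),
                  SOD = sampler$SOD, SID = sampler$SID,
                  pixel_pitch = sampler$pixel_pitch,
                  image_size = sampler$image_size)
  })
}

#' Render the full projection bundle for one tree
#'
#' Samples the views, renders each binary silhouette, and applies the
#' Euclidean distance transform. View geometries are recorded for the
#' projection-based baseline and for analysis only; the neural network
#' never consumes them (the "uncalibrated" contract).
#'
#' @param tree a [coronary_tree()].
#' @param sampler a [view_sampler()].
#' @param tree_id identifier carried in the result.
#' @return object of class `projection_set` with `images`,
#'   `distance_maps`, `views`, `tree_id`.
#' @export
build_projection_set <- function(tree, sampler, tree_id = NA_character_) {
  views <- sample_views(sampler)
  images <- lapply(views, function(v) cone_beam_project(tree, v))
  dmaps <- lapply(images, distance_transform)
  structure(list(images = images, distance_maps = dmaps, views = views,
                 tree_id = tree_id),
            class = "projection_set")
}

#' Choose the distance maps used as network input
#'
#' Draws `k` distinct views from a projection set; the selected maps are
#' returned in ascending view-index order, so the channel ordering seen
#' by the network is deterministic given the chosen subset.
#'
#' @param pset a [build_projection_set()] result.
#' @param k number of maps.
#' @return list of `k` distance maps, with the chosen indices in
#'   attribute `view_index`.
#' @export
choose_training_inputs <- function(pset, k) {
  n <- length(pset$distance_maps)
  if (k > n) stop("requested more inputs than available views")
  if (k == 0L) return(list())
  idx <- sort(sample.int(n, k))
  structure(pset$distance_maps[idx], view_index = idx)
}

#' @export
print.view_geometry <- function(x, ...) {
  cat(sprintf(
    "Cone-beam view: theta %+.1f deg, phi %+.1f deg | SOD %g mm, SID %g mm, %d px @ %.4g mm/px\n",
    x$theta, x$phi, x$SOD, x$SID, x$image_size, x$pixel_pitch))
  invisible(x)
}

#' @export
print.projection_set <- function(x, ...) {
  cat("Projection set:", length(x$images), "view(s) of tree",
      x$tree_id, "\n")
  for (k in seq_along(x$views))
    cat(sprintf("  view %d: theta %+6.1f phi %+6.1f | %d foreground px\n",
                k, x$views[[k]]$theta, x$views[[k]]$phi, sum(x$images[[k]])))
  invisible(x)
}
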