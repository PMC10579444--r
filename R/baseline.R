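# Classical two-view reconstruction comparator: 2D centerline extraction
# by morphological thinning, epipolar candidate matching, dynamic-
# programming refinement under reprojection-error + ordering costs,
# midpoint triangulation, and spline smoothing. Unlike the neural
# network, this path consumes the true simulated view geometries.

#' Extract an ordered 2D centerline from a binary vessel image
#'
#' Morphological thinning (Zhang-Suen) reduces the silhouette to a
#' single-pixel-wide skeleton; spurs shorter than `prune` pixels are
#' removed iteratively; the remaining path is ordered starting from the
#' endpoint nearer the top of the image (smaller row = proximal, the
#' head-up display convention). Because thinning retracts the skeleton
#' inside the rounded silhouette caps by roughly the local vessel
#' radius, each end is then extended along its tangent by the local
#' distance-transform value (`extend_ends`), restoring the full vessel
#' extent.
#'
#' @param image binary matrix (one connected vessel component).
#' @param prune spur-length threshold in pixels.
#' @param extend_ends extend the skeleton ends by the local radius.
#' @return object of class `centerline_2d`: list with `pixels` (`n x 2`
#'   matrix of row, col).
#' @export
extract_centerline_2d <- function(image, prune = 8L, extend_ends = TRUE) {
  if (!any(image == 1)) stop("blank image: no vessel component")
  comp <- connected_components(image)
  big <- which(tabulate(comp[comp > 0]) > 10L)
  if (length(big) > 1L)
    stop("multiple vessel components found (", length(big), ")")
  skel <- zhang_suen(image == 1)
  pix <- which(skel, arr.ind = TRUE)
  if (nrow(pix) <= prune)                 # degenerate blob (e.g. a disk)
    return(structure(list(pixels = pix[order(pix[, 1]), , drop = FALSE]),
                     class = "centerline_2d"))
  skel <- prune_spurs(skel, prune)
  path <- order_skeleton(skel)
  if (extend_ends && nrow(path) >= 6L) {
    edt <- distance_transform(image)
    extend <- function(pth, flip) {
      if (flip) pth <- pth[rev(seq_len(nrow(pth))), , drop = FALSE]
      n <- nrow(pth)
      dirv <- pth[n, ] - pth[n - 5L, ]
      dirv <- dirv / vnorm(dirv)
      reach <- edt[pth[n, 1], pth[n, 2]]
      if (reach >= 1.5) {
        # walk while the distance map stays on its in-tube plateau
        # (~ local radius); it falls off linearly past the true endpoint
        ext <- NULL
        for (s in seq_len(ceiling(3 * reach))) {
          p <- round(pth[n, ] + s * dirv)
          if (p[1] < 1 || p[2] < 1 || p[1] > nrow(image) ||
              p[2] > ncol(image) || edt[p[1], p[2]] < 0.75 * reach) break
          ext <- rbind(ext, pth[n, ] + s * dirv)
        }
        if (!is.null(ext)) pth <- rbind(pth, ext)
      }
      if (flip) pth[rev(seq_len(nrow(pth))), , drop = FALSE] else pth
    }
    path <- extend(path, flip = FALSE)   # distal end
    path <- extend(path, flip = TRUE)    # proximal end
  }
  path <- smooth_path_2d(path)
  structure(list(pixels = path), class = "centerline_2d")
}

# sub-pixel smoothing of the ordered pixel chain: the underlying
# projected centerline is smooth, so the +/- 0.5 px quantization of the
# skeleton is noise; a light smoothing spline per coordinate removes it
# (and with it the spurious arclength inflation of the chain)
smooth_path_2d <- function(path, df_frac = 0.15) {
  n <- nrow(path)
  if (n < 10L) return(path)
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                         path[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  df <- max(6, round(n * df_frac))
  cbind(stats::predict(stats::smooth.spline(s, path[, 1], df = df), s)$y,
        stats::predict(stats::smooth.spline(s, path[, 2], df = df), s)$y)
}

# 4/8-connected labelling by flood fill (small images; queue-based)
connected_components <- function(image) {
  lab <- matrix(0L, nrow(image), ncol(image))
  cur <- 0L
  fg <- which(image == 1)
  nr <- nrow(image)
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || jj < 1 || ii > nr || jj > ncol(image)) next
        q <- (jj - 1L) * nr + ii
        if (image[q] == 1 && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# vectorized Zhang-Suen thinning on a logical matrix
zhang_suen <- function(img) {
  img <- img * 1L
  pad <- function(m) {
    out <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
    out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(img)
      nr <- nrow(img); nc <- ncol(img)
      ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
      p2 <- p[ri - 1L, ci]; p3 <- p[ri - 1L, ci + 1L]; p4 <- p[ri, ci + 1L]
      p5 <- p[ri + 1L, ci + 1L]; p6 <- p[ri + 1L, ci]; p7 <- p[ri + 1L, ci - 1L]
      p8 <- p[ri, ci - 1L]; p9 <- p[ri - 1L, ci - 1L]
      bp <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ap <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1)
        cond <- img == 1 & bp >= 2 & bp <= 6 & ap == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      else
        cond <- img == 1 & bp >= 2 & bp <= 6 & ap == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}

neighbor_count <- function(skel) {
  m <- skel * 1L
  out <- matrix(0L, nrow(m), ncol(m))
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  ri <- 2:(nrow(m) + 1L); ci <- 2:(ncol(m) + 1L)
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) out <- out + p[ri + di, ci + dj]
  out
}

prune_spurs <- function(skel, prune) {
  repeat {
    nb <- neighbor_count(skel)
    ends <- which(skel & nb == 1L, arr.ind = TRUE)
    if (nrow(ends) <= 2L) return(skel)
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      trace <- trace_from(skel, ends[e, ])
      if (nrow(trace$path) < prune && trace$hit_junction) {
        skel[trace$path] <- FALSE
        removed_any <- TRUE
        break                              # neighbour counts changed; restart
      }
    }
    if (!removed_any) return(skel)
  }
}

# walk from an endpoint until a junction (>=3 neighbours) or a dead end
trace_from <- function(skel, start) {
  nb <- neighbor_count(skel)
  path <- matrix(start, 1, 2)
  cur <- start; prev <- c(NA, NA)
  repeat {
    nbrs <- skel_neighbors(skel, cur)
    if (!is.na(prev[1]))
      nbrs <- nbrs[!(nbrs[, 1] == prev[1] & nbrs[, 2] == prev[2]), ,
                   drop = FALSE]
    if (nrow(nbrs) == 0L) return(list(path = path, hit_junction = FALSE))
    if (nb[cur[1], cur[2]] >= 3L)
      return(list(path = path[-nrow(path), , drop = FALSE],
                  hit_junction = TRUE))
    prev <- cur; cur <- nbrs[1, ]
    path <- rbind(path, cur)
    if (nrow(path) > sum(skel)) return(list(path = path, hit_junction = FALSE))
  }
}

skel_neighbors <- function(skel, p) {
  out <- NULL
  for (di in -1:1) for (dj in -1:1) {
    if (!di && !dj) next
    i <- p[1] + di; j <- p[2] + dj
    if (i >= 1 && j >= 1 && i <= nrow(skel) && j <= ncol(skel) && skel[i, j])
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(0L, 0, 2) else out
}

order_skeleton <- function(skel) {
  nb <- neighbor_count(skel)
  ends <- which(skel & nb == 1L, arr.ind = TRUE)
  if (nrow(ends) == 0L)
    stop("skeleton has no endpoints (loop detected)")
  # proximal end: smallest row, ties by smallest column
  ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE]
  start <- ends[1, ]
  visited <- matrix(FALSE, nrow(skel), ncol(skel))
  path <- matrix(0L, sum(skel), 2)
  cur <- start; n <- 0L
  repeat {
    n <- n + 1L
    path[n, ] <- cur
    visited[cur[1], cur[2]] <- TRUE
    nbrs <- skel_neighbors(skel, cur)
    nbrs <- nbrs[!visited[cbind(nbrs[, 1], nbrs[, 2])], , drop = FALSE]
    if (nrow(nbrs) == 0L) break
    # prefer 4-connected continuation (closest neighbour)
    d <- abs(nbrs[, 1] - cur[1]) + abs(nbrs[, 2] - cur[2])
    cur <- nbrs[which.min(d), ]
  }
  path[seq_len(n), , drop = FALSE]
}

# ---- epipolar machinery ---------------------------------------------------

#' Epipolar candidate correspondences for one centerline point
#'
#' Computes the epipolar line in the second view induced by a reference
#' pixel (the projection of its back-ray), then returns the second
#' image's centerline points lying within `band` pixels of that line,
#' nearest first, capped at `max_candidates`. The candidate cost is the
#' point-to-line distance.
#'
#' @param point length-2 `(row, col)` pixel in the reference view.
#' @param ref_view,second_view calibrated [view_geometry()] objects.
#' @param second_centerline a [extract_centerline_2d()] result for the
#'   second view.
#' @param max_candidates cap on returned candidates.
#' @param band half-width of the acceptance band (pixels).
#' @return list with `candidates` (`k x 2`), `index` (positions along the
#'   second centerline), `costs`.
#' @export
epipolar_candidates <- function(point, ref_view, second_view,
                                second_centerline, max_candidates = 10L,
                                band = 2) {
  if (vnorm(ref_view$source - second_view$source) < 1e-9)
    stop("degenerate epipolar geometry: identical views (zero baseline)")
  P <- pixel_points(ref_view, point[1], point[2])[1, ]
  u <- P - ref_view$source; u <- u / vnorm(u)
  X1 <- ref_view$source + (ref_view$SOD - 80) * u
  X2 <- ref_view$source + (ref_view$SOD + 80) * u
  q <- project_points(second_view, rbind(X1, X2))
  dir <- q[2, ] - q[1, ]; dn <- vnorm(dir)
  if (dn < 1e-9) stop("degenerate epipolar geometry")
  dir <- dir / dn
  nrm <- c(-dir[2], dir[1])
  pts <- second_centerline$pixels
  d <- abs((pts[, 1] - q[1, 1]) * nrm[1] + (pts[, 2] - q[1, 2]) * nrm[2])
  keep <- which(d <= band)
  keep <- keep[order(d[keep])]
  if (length(keep) > max_candidates) keep <- keep[seq_len(max_candidates)]
  list(candidates = pts[keep, , drop = FALSE], index = keep,
       costs = d[keep])
}

#' Triangulate matched pixel pairs from two views
#'
#' Midpoint-of-common-perpendicular triangulation of the two source rays
#' for each correspondence. Near-parallel ray pairs (angle below 0.1
#' degrees) are dropped with a warning.
#'
#' @param correspondences `n x 4` matrix of `(row1, col1, row2, col2)`.
#' @param view1,view2 calibrated [view_geometry()] objects.
#' @return `m x 3` matrix of 3D points (mm), `m <= n`.
#' @export
back_project_pair <- function(correspondences, view1, view2) {
  correspondences <- matrix(correspondences, ncol = 4)
  if (vnorm(view1$source - view2$source) < 1e-9)
    stop("identical views cannot be triangulated")
  out <- matrix(NA_real_, nrow(correspondences), 3)
  for (i in seq_len(nrow(correspondences))) {
    p1 <- pixel_points(view1, correspondences[i, 1], correspondences[i, 2])[1, ]
    p2 <- pixel_points(view2, correspondences[i, 3], correspondences[i, 4])[1, ]
    u1 <- p1 - view1$source; u1 <- u1 / vnorm(u1)
    u2 <- p2 - view2$source; u2 <- u2 / vnorm(u2)
    ang <- acos(pmin(1, abs(sum(u1 * u2))))
    if (ang < 0.1 * pi / 180) next
    w0 <- view1$source - view2$source
    b <- sum(u1 * u2); d <- sum(u1 * w0); e <- sum(u2 * w0)
    denom <- 1 - b^2
    s <- (b * e - d) / denom
    t <- (e - b * d) / denom
    out[i, ] <- ((view1$source + s * u1) + (view2$source + t * u2)) / 2
  }
  dropped <- !stats::complete.cases(out)
  if (any(dropped))
    warning(sum(dropped), " correspondence(s) dropped (near-parallel rays)")
  out[!dropped, , drop = FALSE]
}

#' Refine epipolar candidates into one-to-one correspondences
#'
#' Selects one candidate per reference point by dynamic programming over
#' the candidate lattice. The per-candidate cost is the epipolar distance
#' plus the two-view reprojection error of the triangulated point; the
#' ordering constraint is enforced as a hard monotone condition on the
#' candidate's position along the second centerline (indices may not
#' decrease as the reference centerline is traversed). Reference points
#' with no candidate are left unmatched.
#'
#' @param matches list of [epipolar_candidates()] results, one per
#'   reference centerline point (in order).
#' @param ref_centerline the reference [extract_centerline_2d()].
#' @param view1,view2 calibrated [view_geometry()] objects.
#' @return data frame with `ref_index`, `row1`, `col1`, `row2`, `col2`,
#'   `second_index`, `cost` for the matched points.
#' @export
refine_correspondences <- function(matches, ref_centerline, view1, view2) {
  n_cand <- vapply(matches, function(m) length(m$index), 0L)
  if (all(n_cand == 0L)) stop("no candidates for any reference point")
  live <- which(n_cand > 0L)
  pts1 <- ref_centerline$pixels
  # unary costs: epipolar distance + reprojection error
  unary <- lapply(live, function(i) {
    m <- matches[[i]]
    cost <- m$costs
    for (k in seq_along(m$index)) {
      X <- back_project_quiet(c(pts1[i, ], m$candidates[k, ]), view1, view2)
      if (is.null(X)) { cost[k] <- cost[k] + 1e3; next }
      r1 <- project_points(view1, X)
      r2 <- project_points(view2, X)
      cost[k] <- cost[k] + vnorm(r1 - pts1[i, ]) +
        vnorm(r2 - m$candidates[k, ])
    }
    cost
  })
  idx <- lapply(live, function(i) matches[[i]]$index)
  # DP with hard monotone ordering on second-centerline index
  L <- length(live)
  INF <- 1e18
  dp <- vector("list", L); arg <- vector("list", L)
  dp[[1]] <- unary[[1]]
  for (s in seq_len(max(L - 1, 0))) {
    cur <- idx[[s]]; nxt <- idx[[s + 1]]
    dnext <- rep(INF, length(nxt)); anext <- rep(NA_integer_, length(nxt))
    for (k in seq_along(nxt)) {
      ok <- which(cur <= nxt[k])
      if (length(ok)) {
        j <- ok[which.min(dp[[s]][ok])]
        dnext[k] <- dp[[s]][j] + unary[[s + 1]][k]
        anext[k] <- j
      }
    }
    if (all(!is.finite(dnext) | dnext >= INF)) {
      # no monotone continuation: restart chain at this point
      dnext <- unary[[s + 1]]; anext <- rep(NA_integer_, length(nxt))
    }
    dp[[s + 1]] <- dnext; arg[[s + 1]] <- anext
  }
  sel <- integer(L)
  sel[L] <- which.min(dp[[L]])
  for (s in rev(seq_len(L - 1))) {
    a <- arg[[s + 1]][sel[s + 1]]
    sel[s] <- if (is.na(a)) which.min(dp[[s]]) else a
  }
  data.frame(ref_index = live,
             row1 = pts1[live, 1], col1 = pts1[live, 2],
             row2 = vapply(seq_len(L), function(s)
               matches[[live[s]]]$candidates[sel[s], 1], 0),
             col2 = vapply(seq_len(L), function(s)
               matches[[live[s]]]$candidates[sel[s], 2], 0),
             second_index = vapply(seq_len(L), function(s)
               idx[[s]][sel[s]], 0L),
             cost = vapply(seq_len(L), function(s)
               unary[[s]][sel[s]], 0))
}

back_project_quiet <- function(corr, view1, view2) {
  X <- suppressWarnings(back_project_pair(matrix(corr, 1, 4), view1, view2))
  if (nrow(X) == 0L) NULL else X[1, ]
}

#' Fit and resample a 3D spline through triangulated points
#'
#' Chord-length parameterized cubic spline per coordinate;
#' `smoothing = 0` interpolates, larger values use a smoothing spline
#' (`spar` of [stats::smooth.spline()]). The fit is resampled at `n_out`
#' uniform parameter values.
#'
#' @param points `n x 3` matrix (`n >= 4`).
#' @param smoothing 0 for interpolation, or a `spar` value in (0, 1].
#' @param n_out number of output points.
#' @return `n_out x 3` matrix.
#' @export
fit_bspline_3d <- function(points, smoothing = 0, n_out = 100L) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points for a cubic spline")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  t0 <- c(0, cumsum(seg)); t0 <- t0 / t0[length(t0)]
  keep <- c(TRUE, diff(t0) > 1e-10)
  t0 <- t0[keep]; points <- points[keep, , drop = FALSE]
  tt <- seq(0, 1, length.out = n_out)
  out <- sapply(1:3, function(j) {
    if (smoothing > 0)
      stats::predict(stats::smooth.spline(t0, points[, j], spar = smoothing),
                     tt)$y
    else stats::splinefun(t0, points[, j], method = "natural")(tt)
  })
  matrix(out, n_out, 3)
}

#' Two-view projection-geometry reconstruction of a single vessel
#'
#' The full classical chain: thin both silhouettes to ordered 2D
#' centerlines, generate epipolar candidates for every reference point,
#' refine them with the reprojection-error / ordering-constraint dynamic
#' program, triangulate, and fit a spline resampled to `n_out` points.
#' The output is a single-branch tree matrix with radii set to zero (the
#' baseline reconstructs the centerline only).
#'
#' @param images list of 2 binary images.
#' @param views list of the 2 corresponding [view_geometry()] objects
#'   (the baseline consumes true geometry, unlike the network).
#' @param n_out points in the resampled output centerline.
#' @param smoothing spline smoothing (see [fit_bspline_3d()]).
#' @param band,max_candidates forwarded to [epipolar_candidates()].
#' @return a [coronary_tree()] of dimension `1 x n_out x 4` (r = 0;
#'   validation off).
#' @export
reconstruct_baseline <- function(images, views, n_out = 100L,
                                 smoothing = 0, band = 2,
                                 max_candidates = 10L) {
  cl1 <- extract_centerline_2d(images[[1]])
  cl2 <- extract_centerline_2d(images[[2]])
  matches <- lapply(seq_len(nrow(cl1$pixels)), function(i)
    epipolar_candidates(cl1$pixels[i, ], views[[1]], views[[2]], cl2,
                        max_candidates = max_candidates, band = band))
  n_cand <- vapply(matches, function(m) length(m$index), 0L)
  if (mean(n_cand > 0) < 0.5)
    warning("fewer than half of the reference points have epipolar ",
            "candidates; reconstruction may be unreliable")
  corr <- refine_correspondences(matches, cl1, views[[1]], views[[2]])
  X <- back_project_pair(as.matrix(corr[, c("row1", "col1", "row2", "col2")]),
                         views[[1]], views[[2]])
  if (nrow(X) < 4L) stop("too few triangulated points")
  cl <- fit_bspline_3d(X, smoothing = smoothing, n_out = n_out)
  out <- array(0, c(1L, n_out, 4L))
  out[1, , 1:3] <- cl
  coronary_tree(out, branch_names = "RCA", validate = FALSE)
}
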