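test_that("epipolar consistency holds for exact two-view geometry", {
  v1 <- view_geometry(-45, 0)
  v2 <- view_geometry(20, 15)
  set.seed(60)
  X <- cbind(runif(50, -40, 40), runif(50, -40, 40), runif(50, -40, 40))
  p1 <- project_points(v1, X)
  p2 <- project_points(v2, X)
  for (i in seq_len(10)) {
    # epipolar line in view 2 from the view-1 pixel
    P <- coronary3d:::pixel_points(v1, p1[i, 1], p1[i, 2])[1, ]
    u <- P - v1$source; u <- u / sqrt(sum(u^2))
    q <- project_points(v2, rbind(v1$source + 600 * u, v1$source + 900 * u))
    dir <- q[2, ] - q[1, ]; dir <- dir / sqrt(sum(dir^2))
    nrm <- c(-dir[2], dir[1])
    d <- abs(sum((p2[i, ] - q[1, ]) * nrm))
    expect_lt(d, 1e-6)
  }
})

test_that("triangulation recovers noiseless 3D points exactly", {
  v1 <- view_geometry(-45, 0)
  v2 <- view_geometry(45, 10)
  set.seed(61)
  X <- cbind(runif(100, -40, 40), runif(100, -40, 40), runif(100, -40, 40))
  p1 <- project_points(v1, X)
  p2 <- project_points(v2, X)
  rec <- back_project_pair(cbind(p1, p2), v1, v2)
  expect_identical(nrow(rec), 100L)
  expect_lt(max(sqrt(rowSums((rec - X)^2))), 1e-6)
  expect_error(back_project_pair(cbind(p1, p1), v1, v1), "identical views")
})

test_that("thinning recovers the projected centerline of a straight tube", {
  tree <- straight_tree(N = 30, r = 2, L = 60)
  v <- view_geometry(-45, 0)
  img <- cone_beam_project(tree, v)
  cl <- extract_centerline_2d(img)
  truth <- project_points(v, matrix(tree[1, , 1:3], 30, 3))
  d <- apply(cl$pixels, 1, function(p)
    min(abs(p[2] - truth[, 2])))        # vertical tube: compare columns
  expect_lt(max(d), 1.2)
  expect_error(extract_centerline_2d(matrix(0, 32, 32)), "blank")
})

test_that("thinning a disk collapses to a pruned remnant", {
  xy <- expand.grid(1:64, 1:64)
  disk <- matrix(as.numeric((xy[, 1] - 32)^2 + (xy[, 2] - 32)^2 <= 100),
                 64, 64)
  cl <- extract_centerline_2d(disk)
  expect_lte(nrow(cl$pixels), 10)
})

test_that("epipolar candidates contain the true correspondence", {
  # known 3D helix projected into two views
  v1 <- view_geometry(-45, 0)
  v2 <- view_geometry(30, 0)
  s <- seq(0, 4 * pi, length.out = 120)
  X <- cbind(12 * cos(s), 12 * sin(s), seq(-45, 45, length.out = 120))
  p1 <- project_points(v1, X)
  p2 <- project_points(v2, X)
  cl2 <- structure(list(pixels = p2), class = "centerline_2d")
  hits <- vapply(seq(1, 120, by = 7), function(i) {
    cand <- epipolar_candidates(p1[i, ], v1, v2, cl2)
    expect_lte(nrow(cand$candidates), 10)
    i %in% cand$index
  }, TRUE)
  expect_true(all(hits))
  expect_error(epipolar_candidates(p1[1, ], v1, v1, cl2), "zero baseline")
})

test_that("correspondence refinement selects true matches monotonically", {
  v1 <- view_geometry(-45, 0)
  v2 <- view_geometry(35, 0)
  s <- seq(0, 2.5 * pi, length.out = 90)
  X <- cbind(10 * cos(s), 10 * sin(s), seq(-40, 40, length.out = 90))
  p1 <- project_points(v1, X)
  p2 <- project_points(v2, X)
  cl1 <- structure(list(pixels = p1), class = "centerline_2d")
  cl2 <- structure(list(pixels = p2), class = "centerline_2d")
  matches <- lapply(seq_len(90), function(i)
    epipolar_candidates(p1[i, ], v1, v2, cl2, band = 3))
  corr <- refine_correspondences(matches, cl1, v1, v2)
  expect_true(all(diff(corr$second_index) >= 0))
  frac_true <- mean(corr$second_index == corr$ref_index)
  expect_gte(frac_true, 0.95)
})

test_that("spline fitting interpolates lines and circles", {
  line <- cbind(seq(0, 10, length.out = 20), seq(0, -5, length.out = 20),
                seq(2, 8, length.out = 20))
  fit <- fit_bspline_3d(line, smoothing = 0, n_out = 55)
  expect_identical(nrow(fit), 55L)
  # collinearity: residual from the line direction ~ 0
  d <- sweep(fit, 2, fit[1, ])
  dir <- d[55, ] / sqrt(sum(d[55, ]^2))
  resid <- d - outer(drop(d %*% dir), dir)
  expect_lt(max(abs(resid)), 1e-9)
  th <- seq(0, 1.5 * pi, length.out = 100)
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  cfit <- fit_bspline_3d(circ, smoothing = 0, n_out = 200)
  expect_lt(max(abs(sqrt(cfit[, 1]^2 + cfit[, 2]^2) - 10)), 0.05)
  expect_error(fit_bspline_3d(line[1:3, ]), "at least 4")
})

test_that("two-view reconstruction achieves sub-millimetre accuracy", {
  set.seed(62)
  cfg <- inplane_vessel_config(N = 100)
  tree <- generate_tree(cfg, augment = FALSE)
  views <- list(view_geometry(-45, 0), view_geometry(45, 0))
  imgs <- lapply(views, function(v) cone_beam_project(tree, v))
  rec <- reconstruct_baseline(imgs, views, n_out = 100)
  expect_identical(dim(unclass(rec)), c(1L, 100L, 4L))
  expect_true(all(rec[1, , 4] == 0))
  gt <- resample_polyline(matrix(tree[1, , 1:3], 100, 3), 100)
  rmse <- sqrt(mean(rowSums((gt - matrix(rec[1, , 1:3], 100, 3))^2)))
  expect_lt(rmse, 1.0)
})

test_that("reconstruction degrades monotonically with pixel jitter", {
  set.seed(63)
  v1 <- view_geometry(-45, 0)
  v2 <- view_geometry(45, 0)
  s <- seq(0, 2 * pi, length.out = 80)
  X <- cbind(8 * cos(s), 8 * sin(s), seq(-35, 35, length.out = 80))
  p1 <- project_points(v1, X)
  p2 <- project_points(v2, X)
  rmse_at <- function(sig) {
    mean(replicate(3, {
      q1 <- p1 + matrix(rnorm(length(p1), 0, sig), ncol = 2)
      q2 <- p2 + matrix(rnorm(length(p2), 0, sig), ncol = 2)
      rec <- back_project_pair(cbind(q1, q2), v1, v2)
      sqrt(mean(rowSums((rec - X[seq_len(nrow(rec)), ])^2)))
    }))
  }
  expect_gte(rmse_at(2), rmse_at(0))
})
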