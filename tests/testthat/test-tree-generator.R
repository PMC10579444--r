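test_that("centerline sampling reproduces the nominal spline without noise", {
  tmpl <- default_branch_templates()$RCA
  tmpl$control_point_sigma[] <- 0
  set.seed(1)
  p1 <- sample_branch_centerline(tmpl, N = 50)
  nominal <- coronary3d:::eval_spline_polyline(tmpl$control_points, 50)
  expect_lt(max(abs(p1 - nominal)), 1e-9)
})

test_that("spline interpolation preserves collinearity", {
  tmpl <- branch_template("RCA", cbind(0, 0, c(0, 5, 20, 40)),
                          control_point_sigma = 0,
                          r_max_range = c(2, 2.1), r_min_range = c(1, 1.1))
  p <- sample_branch_centerline(tmpl, N = 30)
  expect_lt(max(abs(p[, 1:2])), 1e-12)
  expect_true(all(diff(p[, 3]) > 0))
})

test_that("centerline sampling is deterministic under a fixed seed", {
  tmpl <- default_branch_templates()$RCA
  set.seed(42); p1 <- sample_branch_centerline(tmpl, N = 40)
  set.seed(42); p2 <- sample_branch_centerline(tmpl, N = 40)
  expect_identical(p1, p2)
})

test_that("radius profile is the exact linear taper", {
  expect_equal(sample_radius_profile(2, 1, 5), c(2, 1.75, 1.5, 1.25, 1))
  expect_equal(sample_radius_profile(1.5, 1, 2), c(1.5, 1))
  v <- sample_radius_profile(2.37, 0.61, 57)
  expect_lt(max(abs(diff(diff(v)))), 1e-12)
  expect_error(sample_radius_profile(1, 1.5, 10), "r_max > r_min")
})

test_that("Gaussian stenosis narrows by the commanded fraction", {
  r <- rep(2, 101)
  out <- apply_stenoses(r, list(stenosis_spec(0.5, 50, 0.1)))
  expect_equal(min(out), 1.0, tolerance = 1e-6)
  expect_equal(which.min(out), 51L)
  expect_identical(apply_stenoses(r, list()), r)
  # profile formula evaluated directly as its own oracle
  out2 <- apply_stenoses(r, list(stenosis_spec(0.5, 90, 0.05)))
  expect_equal(out2[51], 0.2, tolerance = 1e-6)
  at3s <- out2[66]    # t = 0.65 = t0 + 3 sigma; exp(-4.5) ~ 0.0111
  expect_lt(abs(at3s - 2) / 2, 0.012)
  expect_error(stenosis_spec(0.5, 95, 0.1), "severity")
  expect_error(stenosis_spec(0.5, 50, 0.6), "sigma")
})

test_that("stenosed radii never exceed the lesion-free profile", {
  set.seed(3)
  for (i in 1:20) {
    base <- sample_radius_profile(runif(1, 1.5, 2.5), runif(1, 0.5, 1), 80)
    lesions <- lapply(seq_len(sample(1:2, 1)), function(j)
      stenosis_spec(runif(1), runif(1, 20, 90), runif(1, 0.02, 0.3)))
    out <- apply_stenoses(base, lesions)
    expect_true(all(out <= base + 1e-12))
    expect_true(all(out > 0))
  }
})

test_that("tree assembly produces M x N x 4 and round-trips", {
  set.seed(4)
  cfg <- generator_config(N = 100)
  tree <- generate_tree(cfg)
  expect_identical(dim(unclass(tree)), c(4L, 100L, 4L))
  expect_true(all(tree[, , 4] > 0))
  branches <- split_tree(tree)
  re <- assemble_tree(branches, branch_names = attr(tree, "branch_names"))
  expect_identical(dim(unclass(re)), dim(unclass(tree)))
  expect_equal(as.vector(unclass(re)), as.vector(unclass(tree)),
               tolerance = 1e-12)
  # single-vessel mode
  tree1 <- generate_tree(single_vessel_config(N = 30))
  expect_identical(dim(unclass(tree1)), c(1L, 30L, 4L))
  expect_error(assemble_tree(list(
    list(centerline = matrix(rnorm(30), 10, 3), radius = rep(1, 10)),
    list(centerline = matrix(rnorm(36), 12, 3), radius = rep(1, 12)))),
    "same number of points")
})

test_that("side-branch origins lie on the RCA polyline", {
  set.seed(5)
  cfg <- generator_config(N = 200)
  for (i in 1:5) {
    tree <- generate_tree(cfg, augment = FALSE)
    rca <- matrix(tree[1, , 1:3], 200, 3)
    for (m in 2:4) {
      o <- tree[m, 1, 1:3]
      # distance to nearest RCA segment
      d <- min(vapply(seq_len(199), function(i) {
        a <- rca[i, ]; b <- rca[i + 1, ]
        v <- b - a; t <- sum((o - a) * v) / sum(v * v)
        t <- min(max(t, 0), 1)
        sqrt(sum((a + t * v - o)^2))
      }, 0))
      expect_lt(d, 1e-6)
    }
  }
})

test_that("augmentation is an isometry under pure rotation", {
  set.seed(6)
  tree <- generate_tree(generator_config(N = 50), augment = FALSE)
  params <- augmentation_params(rotation = c(35, -20, 10))
  out <- augment_tree(tree, params)
  expect_equal(out[, , 4], tree[, , 4])        # radii untouched
  for (m in 1:4) {
    l0 <- branch_arclength(matrix(tree[m, , 1:3], 50, 3))
    l1 <- branch_arclength(matrix(out[m, , 1:3], 50, 3))
    expect_lt(abs(l0 - l1), 1e-9)
  }
  # pairwise distances preserved
  p0 <- matrix(unclass(tree)[, , 1:3], ncol = 3)
  p1 <- matrix(unclass(out)[, , 1:3], ncol = 3)
  i <- sample(nrow(p0), 20); j <- sample(nrow(p0), 20)
  expect_lt(max(abs(sqrt(rowSums((p0[i, ] - p0[j, ])^2)) -
                    sqrt(rowSums((p1[i, ] - p1[j, ])^2)))), 1e-9)
  # identity transform
  ident <- augment_tree(tree, augmentation_params())
  expect_equal(unclass(ident), unclass(tree), tolerance = 1e-12)
  # 90 degree rotation about z
  one <- array(0, c(1, 2, 4))
  one[1, 1, ] <- c(1, 0, 0, 1); one[1, 2, ] <- c(-1, 0, 0, 1)
  rot <- augment_tree(coronary_tree(one), augmentation_params(c(90, 0, 0)))
  expect_equal(rot[1, 1, 1:3], c(0, 1, 0), tolerance = 1e-12)
})

test_that("tube surface matches the analytic cylinder", {
  tree <- straight_tree(N = 50, r = 2, L = 40)
  surf <- tube_surface(tree, circumferential_samples = 16)
  expect_identical(nrow(surf$vertices), 50L * 16L)
  # every vertex at distance r from the axis (x = y = 0)
  d <- sqrt(surf$vertices[, 1]^2 + surf$vertices[, 2]^2)
  expect_lt(max(abs(d - 2)), 1e-9)
  # lateral area of the triangulation ~ 2 pi r L (polygonal underestimate)
  tri_area <- function(a, b, c) {
    ab <- b - a; ac <- c - a
    0.5 * sqrt(sum(c(ab[2] * ac[3] - ab[3] * ac[2],
                     ab[3] * ac[1] - ab[1] * ac[3],
                     ab[1] * ac[2] - ab[2] * ac[1])^2))
  }
  A <- sum(vapply(seq_len(nrow(surf$faces)), function(f)
    tri_area(surf$vertices[surf$faces[f, 1], ],
             surf$vertices[surf$faces[f, 2], ],
             surf$vertices[surf$faces[f, 3], ]), 0))
  expect_lt(abs(A - 2 * pi * 2 * 40) / (2 * pi * 2 * 40), 0.02)
})

test_that("dataset generation honors the split and the seed", {
  cfg <- single_vessel_config(N = 12)
  ds <- generate_dataset(cfg, count = 10, split_fraction = 0.9, seed = 9)
  expect_length(ds$train, 9)
  expect_length(ds$validation, 1)
  ds2 <- generate_dataset(cfg, count = 10, split_fraction = 0.9, seed = 9)
  expect_equal(unclass(ds$train[[3]]), unclass(ds2$train[[3]]))
  # 90/10 convention scales to the full-size corpus
  expect_identical(round(0.9 * 5000), 4500)
})

test_that("sampled lesion severities stay inside the commanded envelope", {
  set.seed(11)
  cfg <- single_vessel_config(N = 12)
  cfg$stenosis_count_prob <- c(0, 1)     # exactly one lesion per tree
  sev <- replicate(300, {
    tree <- generate_tree(cfg, augment = FALSE)
    attr(tree, "lesions")[[1]]$severity
  })
  expect_gte(min(sev), 20)
  expect_lte(max(sev), 90)
  expect_lt(min(sev), 25)                # approaches bounds from inside
  expect_gt(max(sev), 85)
})
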