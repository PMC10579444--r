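test_that("view geometry satisfies its defining relations", {
  v <- view_geometry(-37, 22)
  expect_equal(sqrt(sum(v$source^2)), 750)
  expect_equal(sum((v$source - v$center) * v$e1), 0, tolerance = 1e-12)
  expect_equal(sum((v$source - v$center) * v$e2), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum((v$source - v$center)^2)), 1200)
  # isocenter projects to the image centre
  expect_equal(unname(project_points(v, rbind(c(0, 0, 0)))[1, ]),
               rep((512 + 1) / 2, 2))
  expect_error(view_geometry(0, 0, SOD = 1300, SID = 1200), "SID > SOD")
})

test_that("silhouette magnification matches the cone-beam oracle", {
  # degenerate sphere-branch at the isocenter: silhouette radius must be
  # r * SID / SOD / pitch pixels for any viewing angle
  sph <- array(0, c(1, 2, 4))
  sph[1, 2, 1] <- 1e-9
  sph[1, , 4] <- 5
  expected <- 5 * 1200 / 750 / 0.390625
  set.seed(20)
  for (i in 1:8) {
    v <- view_geometry(runif(1, -180, 180), runif(1, -60, 60))
    img <- cone_beam_project(sph, v)
    measured <- sqrt(sum(img) / pi)
    expect_lt(abs(measured - expected), 1)
  }
})

test_that("empty trees and output dimensions behave as specified", {
  v <- view_geometry(10, 5)
  img <- cone_beam_project(array(0, c(0, 0, 4)), v)
  expect_identical(dim(img), c(512L, 512L))
  expect_identical(sum(img), 0L)
  set.seed(21)
  tree <- generate_tree(generator_config(N = 40))
  img2 <- cone_beam_project(tree, v)
  expect_identical(dim(img2), c(512L, 512L))
  expect_true(all(img2 %in% c(0L, 1L)))
  expect_gt(sum(img2), 0)
})

test_that("distance transform equals the brute-force oracle", {
  expect_identical(distance_transform(matrix(0, 8, 8)), matrix(0, 8, 8))
  single <- matrix(0, 9, 9); single[5, 5] <- 1
  expect_equal(distance_transform(single)[5, 5], 1)
  set.seed(22)
  for (i in 1:3) {
    img <- matrix(0, 64, 64)
    img[sample(64 * 64, 300)] <- 1
    expect_equal(distance_transform(img), edt_brute_force(img))
  }
  # filled disk: maximum equals the disk radius
  xy <- expand.grid(1:63, 1:63)
  disk <- matrix(as.numeric((xy[, 1] - 32)^2 + (xy[, 2] - 32)^2 <= 100),
                 63, 63)
  mx <- max(distance_transform(disk))
  expect_gte(mx, 9); expect_lte(mx, 11)
})

test_that("view sampling respects nominal windows", {
  smp <- view_sampler(window = 0)
  set.seed(23)
  views <- sample_views(smp)
  expect_length(views, 5)
  expect_equal(vapply(views, function(v) v$theta, 0),
               smp$nominal_views[, 1])
  smp20 <- view_sampler(nominal_views = rbind(c(30, 10)), window = 20,
                        views_per_tree = 2000L, inputs_per_sample = 2L)
  set.seed(24)
  th <- vapply(sample_views(smp20), function(v) v$theta, 0)
  expect_gte(min(th), 20); expect_lte(max(th), 40)
  expect_lt(abs(mean(th) - 30), 0.5)
})

test_that("projection sets bundle images, maps and views coherently", {
  set.seed(25)
  tree <- generate_tree(single_vessel_config(N = 20))
  smp <- single_vessel_sampler()
  pset <- build_projection_set(tree, smp)
  expect_length(pset$images, 2)
  expect_length(pset$views, 2)
  for (k in 1:2) {
    expect_true(all(pset$images[[k]] %in% c(0L, 1L)))
    expect_true(all(pset$distance_maps[[k]] >= 0))
    expect_identical(pset$distance_maps[[k]] > 0, pset$images[[k]] == 1L)
  }
  # determinism
  set.seed(26); psA <- build_projection_set(tree, smp)
  set.seed(26); psB <- build_projection_set(tree, smp)
  expect_identical(psA$images, psB$images)
})

test_that("training-input selection returns k maps in view order", {
  set.seed(27)
  tree <- generate_tree(generator_config(N = 30))
  smp <- view_sampler(image_size = 128L, pixel_pitch = 1.5625)
  pset <- build_projection_set(tree, smp)
  expect_length(pset$images, 5)
  maps <- choose_training_inputs(pset, 3)
  expect_length(maps, 3)
  idx <- attr(maps, "view_index")
  expect_identical(idx, sort(idx))
  all5 <- choose_training_inputs(pset, 5)
  expect_identical(attr(all5, "view_index"), 1:5)
  expect_length(choose_training_inputs(pset, 0), 0)
  expect_error(choose_training_inputs(pset, 6), "more inputs")
})

test_that("EDT ridge height equals the projected radius", {
  # straight vertical tube, not foreshortened in a phi = 0 view
  tree <- straight_tree(N = 40, r = 4, L = 60)
  v <- view_geometry(-45, 0)
  img <- cone_beam_project(tree, v)
  dm <- distance_transform(img)
  expected_px <- 4 * 1200 / 750 / 0.390625
  expect_lt(abs(max(dm) - expected_px), 1.1)
})

test_that("projected centerline points land inside their silhouette", {
  set.seed(28)
  tree <- generate_tree(generator_config(N = 60))
  v <- view_geometry(30, -20)
  img <- cone_beam_project(tree, v)
  pix <- round(project_points(v, matrix(unclass(tree)[, , 1:3], ncol = 3)))
  inside <- img[pix]
  expect_true(all(inside == 1L))
})
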