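make_pair <- function(N = 50, seed = 40) {
  set.seed(seed)
  gt <- generate_tree(generator_config(N = N))
  pr <- unclass(gt)
  pr[, , 1:3] <- pr[, , 1:3] + array(rnorm(length(pr[, , 1:3]), 0, 0.5),
                                     dim(pr[, , 1:3]))
  pr[, , 4] <- pr[, , 4] * runif(length(pr[, , 4]), 0.9, 1.1)
  list(gt = gt, pred = coronary_tree(pr, attr(gt, "branch_names"),
                                     validate = FALSE))
}

test_that("centerline RMSE follows its definition", {
  p <- make_pair()
  expect_equal(centerline_rmse(p$gt, p$gt), 0)
  shifted <- unclass(p$gt)
  shifted[, , 1] <- shifted[, , 1] + 3
  shifted[, , 2] <- shifted[, , 2] + 4
  expect_equal(centerline_rmse(p$gt, coronary_tree(shifted, validate = FALSE)),
               5)
  # one point off by (1,1,1) among 100 otherwise exact
  one <- array(0, c(1, 100, 4)); one[1, , 3] <- 1:100; one[1, , 4] <- 1
  gt1 <- coronary_tree(one)
  off <- one; off[1, 37, 1:3] <- off[1, 37, 1:3] + 1
  expect_equal(centerline_rmse(gt1, coronary_tree(off, validate = FALSE)),
               sqrt(3 / 100))
  expect_error(centerline_rmse(p$gt, straight_tree()), "mismatch")
})

test_that("radius RMSE follows its definition", {
  p <- make_pair()
  expect_equal(radius_rmse(p$gt, p$gt), 0)
  biased <- unclass(p$gt); biased[, , 4] <- biased[, , 4] + 0.1
  expect_equal(radius_rmse(p$gt, coronary_tree(biased, validate = FALSE)),
               0.1, tolerance = 1e-12)
  half <- array(0, c(1, 10, 4)); half[1, , 3] <- 1:10; half[1, , 4] <- 1
  gt <- coronary_tree(half)
  ph <- half; ph[1, 1:5, 4] <- ph[1, 1:5, 4] + 0.2
  expect_equal(radius_rmse(gt, coronary_tree(ph, validate = FALSE)),
               0.2 / sqrt(2))
})

test_that("stenosis MAE compares lesion-window minima", {
  N <- 101
  base <- array(0, c(1, N, 4))
  base[1, , 3] <- seq(0, 100, length.out = N)
  spec <- stenosis_spec(0.5, 70, 0.05, branch = "RCA")
  base[1, , 4] <- apply_stenoses(seq(2, 1.6, length.out = N), list(spec))
  gt <- coronary_tree(base, branch_names = "RCA", lesions = list(spec))
  expect_equal(stenosis_mae(gt, gt), 0)
  # prediction missing the lesion entirely: flat taper in the window
  miss <- unclass(gt)
  miss[1, , 4] <- seq(2, 1.6, length.out = N)
  # lesion trough ~ 0.54 mm vs flat taper ~ 1.74 mm at the window edge
  err <- stenosis_mae(gt, coronary_tree(miss, "RCA"))
  expect_equal(err, 1.2, tolerance = 0.02)
  # no lesions -> metric absent, not zero
  nol <- coronary_tree(unclass(gt), "RCA")
  expect_true(is.na(stenosis_mae(nol, nol)))
})

test_that("vessel length MAE responds to scaling, not rotation", {
  tree <- straight_tree(N = 20, r = 1.5, L = 50)
  expect_equal(vessel_length_mae(tree, tree), 0)
  scaled <- unclass(tree)
  ctr <- colMeans(matrix(scaled[1, , 1:3], 20, 3))
  scaled[1, , 1:3] <- sweep(sweep(matrix(scaled[1, , 1:3], 20, 3), 2, ctr),
                            1, rep(2, 20), "*") + rep(ctr, each = 20)
  expect_equal(vessel_length_mae(tree, coronary_tree(scaled, validate = FALSE)),
               50)
  rot <- augment_tree(tree, augmentation_params(rotation = c(10, 20, 30)))
  expect_lt(vessel_length_mae(tree, rot), 1e-9)
})

test_that("percent diameter reduction inverts the stenosis model", {
  for (s in seq(20, 90, by = 5)) {
    base <- seq(2.2, 1.1, length.out = 120)
    spec <- stenosis_spec(0.45, s, 0.06)
    narrowed <- apply_stenoses(base, list(spec))
    measured <- percent_diameter_reduction(narrowed, 0.45, 0.06)
    expect_lt(abs(measured - s), 0.5)
  }
  expect_lt(abs(percent_diameter_reduction(seq(2, 1, length.out = 80),
                                           0.5, 0.05)), 0.5)
})

test_that("aggregation equals brute-force recomputation", {
  ps <- lapply(c(41, 42, 43), function(s) make_pair(seed = s))
  reports <- lapply(ps, function(p) metrics_report(p$gt, p$pred))
  agg <- aggregate_metrics(reports)
  cl <- vapply(reports, function(r) r$centerline_rmse, 0)
  expect_equal(agg$mean[agg$metric == "centerline_rmse"], mean(cl))
  expect_equal(agg$sd[agg$metric == "centerline_rmse"], sd(cl))
  expect_true(all(agg$n %in% c(0, 3)))
})
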