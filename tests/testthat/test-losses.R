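test_that("radius loss reproduces hand-computed values", {
  expect_equal(radius_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(radius_loss(c(1, 1), c(0, 0)), 1)
  expect_equal(radius_loss(c(2, 0), c(0, 0)), 2)
  expect_error(radius_loss(1:3, 1:2), "shape")
})

test_that("branch arclength matches analytic oracles", {
  expect_equal(branch_arclength(rbind(c(0, 0, 0), c(0, 0, 10))), 10)
  th <- seq(0, pi, length.out = 1000)
  semi <- cbind(cos(th), sin(th), 0)
  expect_lt(abs(branch_arclength(semi) - pi), 1e-4)
  # rotation invariance
  R <- coronary3d:::euler_matrix(c(25, -40, 65))
  expect_lt(abs(branch_arclength(semi %*% t(R)) - branch_arclength(semi)),
            1e-9)
  expect_warning(l <- branch_arclength(rbind(c(1, 2, 3))), "fewer than 2")
  expect_equal(l, 0)
})

test_that("centerline loss matches the worked example", {
  y <- array(0, c(1, 1, 2, 3))
  y[1, 1, 2, 1] <- 1
  yh <- array(0, c(1, 1, 2, 3))
  yh[1, 1, 2, 1] <- 2
  expect_equal(centerline_loss(y, y, 0.1), 0)
  expect_equal(centerline_loss(y, yh, 0), 1 / 6)
  expect_equal(centerline_loss(y, yh, 0.1), 1 / 6 + 0.1, tolerance = 1e-12)
  # signed variant rewards the longer prediction
  expect_equal(centerline_loss(y, yh, 0.1, signed = TRUE), 1 / 6 - 0.1,
               tolerance = 1e-12)
})

test_that("centerline loss is invariant under a common rigid rotation", {
  set.seed(31)
  y <- array(rnorm(2 * 3 * 10 * 3), c(2, 3, 10, 3))
  yh <- y + array(rnorm(length(y), 0, 0.3), dim(y))
  R <- coronary3d:::euler_matrix(c(15, 75, -30))
  rot <- function(a) {
    out <- a
    for (b in 1:2) for (m in 1:3)
      out[b, m, , ] <- matrix(a[b, m, , ], 10, 3) %*% t(R)
    out
  }
  expect_equal(centerline_loss(y, yh, 0.1),
               centerline_loss(rot(y), rot(yh), 0.1), tolerance = 1e-10)
})

test_that("single-stage loss counts coordinates and radius as specified", {
  y <- array(0, c(1, 1, 4, 3)); yh <- y + 1
  r <- array(0, c(1, 1, 4)); rh <- r + 1
  expect_equal(single_stage_loss(y, y, r, r, mu = 1), 0)
  expect_equal(single_stage_loss(y, yh, r, rh, mu = 1), 4)
  expect_equal(mu_balance(4, 0.04), 100)
  expect_error(single_stage_loss(y, yh, r, rh, mu = 0), "mu")
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(32)
  y <- array(rnorm(1 * 2 * 6 * 3), c(1, 2, 6, 3))
  yh <- y + array(rnorm(length(y), 0, 0.5), dim(y))
  r <- array(abs(rnorm(12, 1.5, 0.2)), c(1, 2, 6))
  rh <- r + array(rnorm(12, 0, 0.2), dim(r))
  eps <- 1e-6
  check <- function(f, g, x) {
    ga <- g
    worst <- 0
    for (k in sample(length(x), 12)) {
      xp <- x; xp[k] <- x[k] + eps
      xm <- x; xm[k] <- x[k] - eps
      gn <- (f(xp) - f(xm)) / (2 * eps)
      worst <- max(worst, abs(gn - ga[k]) / max(abs(gn), abs(ga[k]), 1e-8))
    }
    worst
  }
  expect_lt(check(function(p) centerline_loss(y, p, 0.1),
                  centerline_loss_grad(y, yh, 0.1), yh), 1e-4)
  expect_lt(check(function(p) radius_loss(r, p),
                  radius_loss_grad(r, rh), rh), 1e-4)
  gs <- single_stage_loss_grad(y, yh, r, rh, mu = 7)
  expect_lt(check(function(p) single_stage_loss(y, p, r, rh, 7), gs$dy, yh),
            1e-4)
  expect_lt(check(function(p) single_stage_loss(y, yh, r, p, 7), gs$dr, rh),
            1e-4)
})

test_that("losses are positive-definite around the truth", {
  set.seed(33)
  y <- array(rnorm(36), c(1, 2, 6, 3))
  r <- array(abs(rnorm(12)) + 0.5, c(1, 2, 6))
  expect_equal(centerline_loss(y, y, 0.1), 0)
  expect_equal(single_stage_loss(y, y, r, r, 2), 0)
  for (i in 1:5) {
    yh <- y + array(rnorm(36, 0, 0.1), dim(y))
    rh <- r + array(rnorm(12, 0, 0.1), dim(r))
    expect_gt(centerline_loss(y, yh, 0.1), 0)
    expect_gt(radius_loss(r, rh), 0)
    expect_gt(single_stage_loss(y, yh, r, rh, 2), 0)
  }
})
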