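#' Radius-stage loss (mean squared error)
#'
#' Plain MSE over every radius entry: `mean((r - r_hat)^2)`, the
#' denominator being the total number of points across branches and batch
#' items.
#'
#' @param r,r_hat ground-truth and predicted radii, any matching shape.
#' @return nonnegative scalar.
#' @export
radius_loss <- function(r, r_hat) {
  if (!identical(dim(r), dim(r_hat)) || length(r) != length(r_hat))
    stop("shape mismatch between r and r_hat")
  mean((r - r_hat)^2)
}

#' Centerline-stage loss with arclength regularization
#'
#' Coordinate MSE (mean over every scalar coordinate entry) plus a vessel
#' -length penalty: `lambda` times the sum over branches and batch items
#' of the arclength discrepancy between ground truth and prediction,
#' divided by the batch size (the batch normalization of the length term
#' is folded in explicitly, so `lambda = 0.1` is used as-is).
#'
#' The length discrepancy is `|S_y - S_yhat|` by default. With
#' `signed = TRUE` the raw signed difference `S_y - S_yhat` is used
#' instead; the signed form is unbounded below (it rewards arbitrarily
#' long predictions) and is provided only for completeness.
#'
#' @param y,y_hat arrays of shape `batch x M x N x 3` (a single
#'   `M x N x 3` array is promoted to batch size 1).
#' @param lambda length-regularization rate (>= 0).
#' @param signed use the signed length difference.
#' @return scalar loss.
#' @export
centerline_loss <- function(y, y_hat, lambda = 0.1, signed = FALSE) {
  y <- promote_batch(y); y_hat <- promote_batch(y_hat)
  if (!identical(dim(y), dim(y_hat)))
    stop("shape mismatch between y and y_hat")
  mse <- mean((y - y_hat)^2)
  B <- dim(y)[1]; M <- dim(y)[2]; N <- dim(y)[3]
  len_term <- 0
  for (b in seq_len(B)) for (m in seq_len(M)) {
    d <- branch_arclength(matrix(y[b, m, , ], N, 3)) -
      branch_arclength(matrix(y_hat[b, m, , ], N, 3))
    len_term <- len_term + if (signed) d else abs(d)
  }
  mse + lambda * len_term / B
}

promote_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) array(x, c(1L, d)) else x
}

#' Single-stage loss (weighted coordinate + radius MSE)
#'
#' Mean over all points of the squared coordinate error (summed over the
#' three coordinates) plus `mu` times the squared radius error. `mu`
#' balances the two terms; see [mu_balance()] for the order-of-magnitude
#' balancing rule.
#'
#' @param y,y_hat coordinates, `batch x M x N x 3` (or `M x N x 3`).
#' @param r,r_hat radii, `batch x M x N` (or `M x N`).
#' @param mu radius weight (> 0).
#' @return scalar loss.
#' @export
single_stage_loss <- function(y, y_hat, r, r_hat, mu) {
  if (mu <= 0) stop("mu must be > 0")
  y <- promote_batch(y); y_hat <- promote_batch(y_hat)
  if (length(dim(r)) == 2L) { r <- array(r, c(1L, dim(r))) }
  if (length(dim(r_hat)) == 2L) r_hat <- array(r_hat, c(1L, dim(r_hat)))
  if (!identical(dim(y), dim(y_hat)) || !identical(dim(r), dim(r_hat)))
    stop("shape mismatch")
  n_points <- length(r)
  coord <- sum((y - y_hat)^2)
  rad <- sum((r - r_hat)^2)
  (coord + mu * rad) / n_points
}

#' Order-of-magnitude balancing of the radius weight
#'
#' Chooses `mu` as the ratio of the coordinate MSE to the radius MSE
#' measured on a reference batch, so both terms of the single-stage loss
#' are of the same order of magnitude. Typically computed once on the
#' first training epoch and then frozen.
#'
#' @param coord_mse,radius_mse reference mean squared errors (> 0).
#' @return `mu`.
#' @export
mu_balance <- function(coord_mse, radius_mse) {
  if (coord_mse <= 0 || radius_mse <= 0) stop("MSEs must be positive")
  coord_mse / radius_mse
}

# ---- analytic gradients (used by the trainer; exported for gradient checks)

#' Gradient of the radius loss with respect to the prediction
#' @inheritParams radius_loss
#' @return array like `r_hat`.
#' @export
radius_loss_grad <- function(r, r_hat) {
  2 * (r_hat - r) / length(r)
}

# gradient of branch arclength S(p) wrt the N x 3 polyline p
arclength_grad <- function(p) {
  N <- nrow(p)
  d <- p[-1, , drop = FALSE] - p[-N, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  len[len < 1e-12] <- 1e-12
  u <- d / len
  g <- matrix(0, N, 3)
  g[-1, ] <- g[-1, ] + u
  g[-N, ] <- g[-N, ] - u
  g
}

#' Gradient of the centerline loss with respect to the prediction
#' @inheritParams centerline_loss
#' @return array like `y_hat` (batch-promoted).
#' @export
centerline_loss_grad <- function(y, y_hat, lambda = 0.1, signed = FALSE) {
  y <- promote_batch(y); y_hat <- promote_batch(y_hat)
  g <- 2 * (y_hat - y) / length(y)
  B <- dim(y)[1]; M <- dim(y)[2]; N <- dim(y)[3]
  if (lambda > 0) {
    for (b in seq_len(B)) for (m in seq_len(M)) {
      ph <- matrix(y_hat[b, m, , ], N, 3)
      d <- branch_arclength(matrix(y[b, m, , ], N, 3)) - branch_arclength(ph)
      sgn <- if (signed) -1 else -sign(d)   # d/dy_hat of (S_y - S_yhat) is -dS
      if (sgn != 0)
        g[b, m, , ] <- g[b, m, , ] + lambda * sgn * arclength_grad(ph) / B
    }
  }
  g
}

#' Gradients of the single-stage loss
#' @inheritParams single_stage_loss
#' @return list with `dy` (like `y_hat`) and `dr` (like `r_hat`).
#' @export
single_stage_loss_grad <- function(y, y_hat, r, r_hat, mu) {
  y <- promote_batch(y); y_hat <- promote_batch(y_hat)
  if (length(dim(r)) == 2L) r <- array(r, c(1L, dim(r)))
  if (length(dim(r_hat)) == 2L) r_hat <- array(r_hat, c(1L, dim(r_hat)))
  n_points <- length(r)
  list(dy = 2 * (y_hat - y) / n_points,
       dr = 2 * mu * (r_hat - r) / n_points)
}
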