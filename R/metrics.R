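#' Centerline root-mean-squared error
#'
#' RMSE over all `M * N` index-corresponding point pairs of the Euclidean
#' distance between ground-truth and predicted centerline points. The
#' fixed `M x N x 4` representation carries an index correspondence, so
#' no closest-point matching is performed.
#'
#' @param gt,pred trees of identical `M`, `N`.
#' @return mm.
#' @export
centerline_rmse <- function(gt, pred) {
  check_same_shape(gt, pred)
  d2 <- (unclass(gt)[, , 1:3, drop = FALSE] -
           unclass(pred)[, , 1:3, drop = FALSE])^2
  sqrt(mean(apply(d2, c(1, 2), sum)))
}

#' Radius root-mean-squared error
#' @inheritParams centerline_rmse
#' @return mm.
#' @export
radius_rmse <- function(gt, pred) {
  check_same_shape(gt, pred)
  sqrt(mean((unclass(gt)[, , 4] - unclass(pred)[, , 4])^2))
}

check_same_shape <- function(gt, pred) {
  if (!identical(dim(unclass(gt)), dim(unclass(pred))))
    stop("tree shape mismatch")
}

#' Minimum-stenosis-diameter absolute error
#'
#' For each lesion, compares the minimum radius of ground truth and
#' prediction within the lesion window `t0 +/- 3 sigma` (on the branch's
#' parametric grid) and averages the absolute differences. Undefined --
#' returned as `NA` -- when the tree carries no lesions; an absent lesion
#' is not a zero-error lesion.
#'
#' @param gt,pred trees of identical shape.
#' @param lesions list of [stenosis_spec()]; defaults to the ground
#'   truth's attached lesion list.
#' @return mm, or `NA` if no lesions.
#' @export
stenosis_mae <- function(gt, pred, lesions = attr(gt, "lesions")) {
  check_same_shape(gt, pred)
  if (!length(lesions)) return(NA_real_)
  bn <- attr(gt, "branch_names")
  N <- dim(gt)[2]
  tt <- seq(0, 1, length.out = N)
  errs <- vapply(lesions, function(l) {
    m <- match(l$branch, bn)
    if (is.na(m)) stop("lesion branch not present in tree")
    win <- which(tt >= l$t0 - 3 * l$sigma & tt <= l$t0 + 3 * l$sigma)
    abs(min(gt[m, win, 4]) - min(pred[m, win, 4]))
  }, 0)
  mean(errs)
}

#' Vessel-length mean absolute error
#'
#' Mean over branches of the absolute arclength difference.
#' @inheritParams centerline_rmse
#' @return mm.
#' @export
vessel_length_mae <- function(gt, pred) {
  check_same_shape(gt, pred)
  M <- dim(gt)[1]; N <- dim(gt)[2]
  mean(vapply(seq_len(M), function(m)
    abs(branch_arclength(matrix(gt[m, , 1:3], N, 3)) -
          branch_arclength(matrix(pred[m, , 1:3], N, 3))), 0))
}

#' Measure percent diameter reduction in a lesion window
#'
#' Inverts the generator's stenosis parameterization: the reference
#' lumen is the lesion-free linear taper, approximated by interpolating
#' the radii immediately outside the `t0 +/- 3 sigma` window linearly
#' across it; severity is the largest pointwise diameter reduction
#' `100 * max(1 - r(t) / r_ref(t))` inside the window. Diameter and
#' radius reductions coincide for a concentric narrowing.
#'
#' @param radii radius vector.
#' @param t0,sigma lesion centre and width (parametric units).
#' @return percent diameter reduction.
#' @export
percent_diameter_reduction <- function(radii, t0, sigma) {
  N <- length(radii)
  tt <- seq(0, 1, length.out = N)
  win <- which(tt >= t0 - 3 * sigma & tt <= t0 + 3 * sigma)
  if (!length(win)) stop("lesion window outside the branch")
  i_lo <- max(min(win) - 1L, 1L)
  i_hi <- min(max(win) + 1L, N)
  w <- if (i_hi > i_lo) (tt[win] - tt[i_lo]) / (tt[i_hi] - tt[i_lo]) else
    rep(0.5, length(win))
  r_ref <- (1 - w) * radii[i_lo] + w * radii[i_hi]
  100 * max(1 - radii[win] / r_ref)
}

#' Per-tree reconstruction metrics
#'
#' Computes the four headline metrics for one ground-truth/prediction
#' pair, with a per-branch breakdown.
#'
#' @param gt,pred trees of identical shape.
#' @param lesions optional lesion list (defaults to the ground truth's).
#' @return object of class `metrics_report`.
#' @export
metrics_report <- function(gt, pred, lesions = attr(gt, "lesions")) {
  check_same_shape(gt, pred)
  M <- dim(gt)[1]; N <- dim(gt)[2]
  bn <- attr(gt, "branch_names")
  per_branch <- data.frame(
    branch = bn,
    centerline_rmse = vapply(seq_len(M), function(m)
      sqrt(mean(rowSums((matrix(gt[m, , 1:3], N, 3) -
                           matrix(pred[m, , 1:3], N, 3))^2))), 0),
    radius_rmse = vapply(seq_len(M), function(m)
      sqrt(mean((gt[m, , 4] - pred[m, , 4])^2)), 0),
    length_ae = vapply(seq_len(M), function(m)
      abs(branch_arclength(matrix(gt[m, , 1:3], N, 3)) -
            branch_arclength(matrix(pred[m, , 1:3], N, 3))), 0))
  structure(list(centerline_rmse = centerline_rmse(gt, pred),
                 radius_rmse = radius_rmse(gt, pred),
                 stenosis_mae = stenosis_mae(gt, pred, lesions),
                 length_mae = vessel_length_mae(gt, pred),
                 per_branch = per_branch),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Reconstruction metrics\n")
  cat(sprintf("  centerline RMSE : %6.3f mm\n", x$centerline_rmse))
  cat(sprintf("  radius RMSE     : %6.3f mm\n", x$radius_rmse))
  cat(sprintf("  stenosis MAE    : %s\n",
              if (is.na(x$stenosis_mae)) "absent (no lesions)"
              else sprintf("%6.3f mm", x$stenosis_mae)))
  cat(sprintf("  length MAE      : %6.3f mm\n", x$length_mae))
  invisible(x)
}

#' Aggregate metric reports over a set
#'
#' Mean and standard deviation per metric over a list of
#' [metrics_report()]s; stenosis MAE aggregates only trees where it is
#' defined.
#'
#' @param reports list of `metrics_report`.
#' @return data frame with `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(reports) {
  grab <- function(f) vapply(reports, function(r) r[[f]], 0)
  rows <- lapply(c("centerline_rmse", "radius_rmse", "stenosis_mae",
                   "length_mae"), function(f) {
    v <- grab(f); v <- v[!is.na(v)]
    data.frame(metric = f, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  })
  do.call(rbind, rows)
}
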