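#' Coronary tree matrix
#'
#' The universal geometry representation used throughout the package: an
#' `M x N x 4` array holding, for each of `M` branches and `N` ordered
#' centerline points, the 3D coordinate and local lumen radius
#' `(x, y, z, r)` in millimetres. Points within a branch are ordered from
#' proximal (ostium / take-off) to distal. Ground-truth trees, network
#' reconstructions and baseline reconstructions all use this container so
#' that every evaluation metric applies uniformly.
#'
#' @param data numeric array of dimension `M x N x 4` (mm).
#' @param branch_names character vector of length `M`; defaults to the
#'   canonical right-coronary ordering `RCA, SA, AM, PDA` (truncated for
#'   smaller `M`, or `V1..VM` beyond four branches).
#' @param lesions optional list of lesion descriptors (see
#'   [stenosis_spec()]), each carrying a `branch` field; stored as an
#'   attribute for downstream stenosis metrics.
#' @param validate check invariants (positive radii, distinct consecutive
#'   points). Reconstructions produced by approximate methods may switch
#'   this off.
#' @return an object of class `coronary_tree` (the array with attributes).
#' @export
coronary_tree <- function(data, branch_names = NULL, lesions = NULL,
                          validate = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 4L)
    stop("`data` must be an M x N x 4 array")
  M <- dim(data)[1]
  if (is.null(branch_names)) {
    canonical <- c("RCA", "SA", "AM", "PDA")
    branch_names <- if (M <= 4L) canonical[seq_len(M)] else
      c(canonical, paste0("V", 5:M))[seq_len(M)]
  }
  if (length(branch_names) != M) stop("branch_names length must equal M")
  if (validate) {
    if (any(!is.finite(data))) stop("non-finite values in tree matrix")
    if (any(data[, , 4] <= 0)) stop("all radii must be positive")
    if (dim(data)[2] >= 2L) {
      seg <- branch_segment_lengths(data)
      if (any(seg <= 0)) stop("consecutive centerline points must be distinct")
    }
  }
  structure(data, class = "coronary_tree", branch_names = branch_names,
            lesions = lesions)
}

# per-branch segment lengths, (M) x (N-1)
branch_segment_lengths <- function(data) {
  d <- data[, , 1:3, drop = FALSE]
  M <- dim(d)[1]; N <- dim(d)[2]
  out <- matrix(0, M, N - 1L)
  for (m in seq_len(M)) {
    p <- matrix(d[m, , ], N, 3)
    out[m, ] <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-N, , drop = FALSE])^2))
  }
  out
}

#' @export
print.coronary_tree <- function(x, ...) {
  M <- dim(x)[1]; N <- dim(x)[2]
  cat("Coronary tree:", M, "branch(es) x", N, "points\n")
  bn <- attr(x, "branch_names")
  for (m in seq_len(M)) {
    r <- x[m, , 4]
    L <- sum(branch_segment_lengths(unclass(x))[m, ])
    cat(sprintf("  %-4s length %6.1f mm, radius %.2f -> %.2f mm\n",
                bn[m], L, r[1], r[length(r)]))
  }
  les <- attr(x, "lesions")
  if (length(les))
    cat("  lesions:", paste(vapply(les, function(l)
      sprintf("%s %.0f%% @ t=%.2f", l$branch, l$severity, l$t0), ""),
      collapse = "; "), "\n")
  invisible(x)
}

#' Split a tree matrix back into per-branch centerlines and radii
#'
#' Inverse of [assemble_tree()].
#' @param tree a `coronary_tree`.
#' @return named list of `list(centerline = N x 3, radius = N)` per branch.
#' @export
split_tree <- function(tree) {
  M <- dim(tree)[1]; N <- dim(tree)[2]
  bn <- attr(tree, "branch_names")
  out <- lapply(seq_len(M), function(m)
    list(centerline = matrix(tree[m, , 1:3], N, 3), radius = tree[m, , 4]))
  names(out) <- bn
  out
}

#' Combine per-branch geometry into a coronary tree matrix
#'
#' Branches are stacked into a single `M x N x 4` matrix in the order
#' given. Side branches (all but the first) may carry an `origin`: the 3D
#' take-off point on the parent vessel to which their first centerline
#' point is translated, so that branch topology is preserved after random
#' re-sampling of each branch shape.
#'
#' @param branches list of `list(centerline = N x 3 matrix, radius =
#'   length-N vector)`; all with identical `N`.
#' @param branch_names optional character vector naming the branches.
#' @param origins optional list (same length) of 3-vectors or `NULL`
#'   entries; when non-`NULL` the branch is rigidly translated so its
#'   first point equals the origin.
#' @param lesions optional lesion list stored on the result.
#' @return a [coronary_tree()].
#' @export
assemble_tree <- function(branches, branch_names = NULL, origins = NULL,
                          lesions = NULL) {
  M <- length(branches)
  if (M < 1L) stop("need at least one branch")
  Ns <- vapply(branches, function(b) nrow(b$centerline), 0L)
  if (length(unique(Ns)) != 1L)
    stop("all branches must have the same number of points N")
  N <- unname(Ns[1])
  data <- array(0, c(M, N, 4))
  for (m in seq_len(M)) {
    cl <- branches[[m]]$centerline
    if (!is.null(origins) && !is.null(origins[[m]]))
      cl <- sweep(cl, 2, cl[1, ] - origins[[m]], "-")
    data[m, , 1:3] <- cl
    data[m, , 4] <- branches[[m]]$radius
  }
  coronary_tree(data, branch_names = branch_names, lesions = lesions)
}

#' Arclength of a polyline
#'
#' Sum of Euclidean lengths of consecutive segments; the quantity entering
#' the length-regularized centerline loss and the vessel-length error.
#'
#' @param polyline an `N x 3` matrix (mm).
#' @return length in mm; 0 (with a warning) for fewer than 2 points.
#' @export
branch_arclength <- function(polyline) {
  polyline <- as.matrix(polyline)
  n <- nrow(polyline)
  if (n < 2L) {
    warning("polyline has fewer than 2 points; arclength is 0")
    return(0)
  }
  sum(sqrt(rowSums((polyline[-1, , drop = FALSE] -
                      polyline[-n, , drop = FALSE])^2)))
}

#' Resample a polyline
#'
#' Cubic-spline resampling at `n` uniformly spaced parameter values,
#' parameterized by normalized cumulative chord length (an arclength
#' proxy). Used to put reconstructed and ground-truth centerlines on a
#' common index grid before point-wise comparison.
#'
#' @param polyline `N x 3` matrix.
#' @param n number of output points.
#' @return `n x 3` matrix.
#' @export
resample_polyline <- function(polyline, n) {
  polyline <- as.matrix(polyline)
  seg <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                         polyline[-nrow(polyline), , drop = FALSE])^2))
  t0 <- c(0, cumsum(seg)); t0 <- t0 / t0[length(t0)]
  # collapse numerically coincident points
  keep <- c(TRUE, diff(t0) > 1e-12)
  t0 <- t0[keep]; polyline <- polyline[keep, , drop = FALSE]
  tt <- seq(0, 1, length.out = n)
  out <- sapply(1:3, function(j)
    stats::splinefun(t0, polyline[, j], method = "natural")(tt))
  matrix(out, n, 3)
}
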