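#' Branch template
#'
#' A template describes the nominal shape of one vessel branch as a set of
#' 3D spline control points plus per-point Gaussian perturbation scales,
#' and the admissible range of proximal (`r_max`) and distal (`r_min`)
#' radii. Randomized branches are drawn by perturbing the control points
#' and sampling the radius endpoints.
#'
#' Side branches (`SA`, `AM`, `PDA`) additionally carry `takeoff_window`,
#' the parametric interval along the RCA within which their origin is
#' sampled; their first control point has zero perturbation because it is
#' replaced by the sampled take-off point at assembly time.
#'
#' @param branch_id one of `"RCA"`, `"SA"`, `"AM"`, `"PDA"` (or any label
#'   for custom vessels).
#' @param control_points `K x 3` matrix of spline control points (mm),
#'   `K >= 4`, ordered proximal to distal.
#' @param control_point_sigma length-`K` vector (or scalar) of isotropic
#'   perturbation standard deviations (mm).
#' @param r_max_range,r_min_range closed intervals (mm) for the proximal
#'   and distal radius; sampled pairs violating `r_min < r_max` are
#'   redrawn.
#' @param takeoff_window parametric interval on the parent RCA (`NULL`
#'   for the RCA itself).
#' @return an object of class `branch_template`.
#' @export
branch_template <- function(branch_id, control_points, control_point_sigma,
                            r_max_range, r_min_range,
                            takeoff_window = NULL) {
  control_points <- as.matrix(control_points)
  K <- nrow(control_points)
  if (K < 4L) stop("a branch template needs >= 4 control points")
  if (length(control_point_sigma) == 1L)
    control_point_sigma <- rep(control_point_sigma, K)
  if (length(control_point_sigma) != K)
    stop("control_point_sigma must have one value per control point")
  if (any(control_point_sigma < 0)) stop("sigmas must be >= 0")
  stopifnot(length(r_max_range) == 2L, length(r_min_range) == 2L)
  if (!is.null(takeoff_window)) {
    stopifnot(length(takeoff_window) == 2L)
    control_point_sigma[1] <- 0
  }
  structure(list(branch_id = branch_id, control_points = control_points,
                 control_point_sigma = control_point_sigma,
                 r_max_range = sort(as.numeric(r_max_range)),
                 r_min_range = sort(as.numeric(r_min_range)),
                 takeoff_window = takeoff_window),
            class = "branch_template")
}

#' Default right-coronary branch templates
#'
#' Hand-built nominal centerlines for the four main branches of the right
#' coronary tree: the right coronary artery (RCA) sweeping through the
#' right atrioventricular groove, the sino-atrial nodal branch (SA,
#' proximal take-off), the acute marginal branch (AM, mid take-off), and
#' the posterior descending artery (PDA, distal take-off). Shapes and
#' radius ranges reflect typical adult right-dominant anatomy; the tree is
#' roughly centred on the origin (the imaging isocenter). Perturbation
#' scales of 2-4 mm per control point give visibly distinct but plausible
#' trees.
#'
#' Side-branch control points are expressed with their first point on the
#' nominal RCA path; at generation time the first point is re-anchored to
#' the take-off point sampled on the *perturbed* RCA.
#'
#' @return named list of four [branch_template()] objects in canonical
#'   order RCA, SA, AM, PDA.
#' @export
default_branch_templates <- function() {
  rca <- rbind(
    c(  8, 30,  48),
    c( 22, 18,  30),
    c( 28,  6,   8),
    c( 26, -4, -14),
    c( 14, -12, -34),
    c( -4, -16, -48),
    c(-24, -12, -54))
  sa <- rbind(                      # short, runs cranially from proximal RCA
    c( 13.5, 25.3, 40.9),           # on nominal RCA path (t ~ 0.1)
    c( 10,  32,  46),
    c(  4,  38,  52),
    c( -3,  42,  60))
  am <- rbind(                      # toward the apex over the RV free wall
    c( 27.5, 1.1, -3.0),            # on nominal RCA path (t ~ 0.45)
    c( 38,  -6, -16),
    c( 44, -14, -30),
    c( 46, -24, -44))
  pda <- rbind(                     # along the posterior interventricular groove
    c( 7.2, -14.8, -39.4),          # on nominal RCA path (t ~ 0.85)
    c( 12, -26, -44),
    c( 18, -38, -46),
    c( 22, -52, -44))
  # center the nominal tree on the isocenter and scale to a ~110 mm span
  # so the magnified silhouette fits a 200 mm detector field
  centroid <- colMeans(rbind(rca, sa[-1, ], am[-1, ], pda[-1, ]))
  recenter <- function(cp) sweep(cp, 2, centroid) * 0.85
  rca <- recenter(rca); sa <- recenter(sa); am <- recenter(am)
  pda <- recenter(pda)
  list(
    RCA = branch_template("RCA", rca, c(2, 3, 4, 4, 4, 3, 3),
                          r_max_range = c(1.5, 2.2),
                          r_min_range = c(0.8, 1.2)),
    SA  = branch_template("SA", sa, c(0, 2, 2.5, 3),
                          r_max_range = c(0.6, 0.9),
                          r_min_range = c(0.35, 0.55),
                          takeoff_window = c(0.05, 0.15)),
    AM  = branch_template("AM", am, c(0, 2.5, 3, 3.5),
                          r_max_range = c(0.8, 1.2),
                          r_min_range = c(0.45, 0.7),
                          takeoff_window = c(0.40, 0.55)),
    PDA = branch_template("PDA", pda, c(0, 2.5, 3, 3),
                          r_max_range = c(1.0, 1.4),
                          r_min_range = c(0.55, 0.85),
                          takeoff_window = c(0.78, 0.90)))
}

#' Generator configuration
#'
#' Bundles everything the randomized tree generator needs: the branch
#' templates, the per-branch point count `N`, the distribution of lesion
#' counts per tree, where lesions may occur, lesion-shape ranges, and the
#' augmentation magnitudes.
#'
#' @param N points per branch (>= 10).
#' @param templates list of [branch_template()]s; the first must be the
#'   RCA (the parent vessel).
#' @param stenosis_count_prob probabilities of 0, 1, 2, ... lesions per
#'   tree; must sum to 1.
#' @param lesion_branches branches eligible for lesions.
#' @param severity_range percent diameter reduction interval.
#' @param sigma_range Gaussian lesion width (fraction of branch length).
#' @param t0_range parametric interval for lesion centres.
#' @param rotation_sd Euler-angle scale (degrees) for augmentation.
#' @param shear_range shear-coefficient interval for augmentation.
#' @param warp_amplitude,warp_scale smooth-warp displacement amplitude and
#'   spatial scale (mm).
#' @param p_shear,p_warp probability that a given tree is sheared/warped
#'   (rotation is always applied).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(N = 100,
                             templates = default_branch_templates(),
                             stenosis_count_prob = c(0.40, 0.45, 0.15),
                             lesion_branches = c("RCA", "PDA"),
                             severity_range = c(20, 90),
                             sigma_range = c(0.02, 0.08),
                             t0_range = c(0.15, 0.85),
                             rotation_sd = 10,
                             shear_range = c(-0.1, 0.1),
                             warp_amplitude = 2,
                             warp_scale = 60,
                             p_shear = 0.5,
                             p_warp = 0.5) {
  if (N < 10L) stop("N must be >= 10")
  if (abs(sum(stenosis_count_prob) - 1) > 1e-8)
    stop("stenosis_count_prob must sum to 1")
  ids <- unname(vapply(templates, function(t) t$branch_id, ""))
  structure(list(N = as.integer(N), M = length(templates),
                 templates = templates, branch_names = ids,
                 stenosis_count_prob = stenosis_count_prob,
                 lesion_branches = lesion_branches,
                 severity_range = severity_range,
                 sigma_range = sigma_range, t0_range = t0_range,
                 rotation_sd = rotation_sd, shear_range = shear_range,
                 warp_amplitude = warp_amplitude, warp_scale = warp_scale,
                 p_shear = p_shear, p_warp = p_warp),
            class = "generator_config")
}
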