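# Crossbridge-centric coordinate system, tail vector extraction, and
# elevation/azimuth/tilt angle measurement with probability densities.

#' Build the crossbridge-centric coordinate frame
#'
#' Constructs the sarcomere-inspired axes from a weakly-bound actomyosin
#' reference geometry: the origin is the center of mass of the actin
#' selection; axis 2 (`e2`) points along the thin filament (the dominant
#' principal axis of the actin coordinates); axis 1 (`e1`) is the unit
#' component, orthogonal to `e2`, of the vector from the origin to the
#' center of mass of the anchor selection (the myosin lever-arm anchor in
#' the reference-aligned pose), i.e. the interfilament direction; axis 3
#' (`e3 = e1 x e2`) is normal to the 1-2 plane, making a right-handed triad.
#'
#' @param reference a [mol_model()] holding the reference complex.
#' @param actin_sel selection spanning the actin filament (>= 3 non-collinear
#'   atoms).
#' @param anchor_sel non-empty selection of the myosin anchor; must not sit
#'   on the `e2` line through the origin.
#' @param e2_direction orientation of `e2` along the filament: `"auto"`
#'   points it from the first to the last selected actin atom; a numeric
#'   3-vector orients `e2` to positive dot product with it. The paper-style
#'   convention (azimuth of the reference pose positive) is a choice the
#'   caller makes here.
#' @return object of class `crossbridge_frame`: `origin`, unit vectors
#'   `e1`, `e2`, `e3`.
#' @export
build_crossbridge_frame <- function(reference, actin_sel, anchor_sel,
                                    e2_direction = "auto") {
  A <- model_coords(reference, actin_sel)
  if (nrow(A) < 3) stop("actin selection must span at least 3 atoms")
  origin <- mass_center(reference, actin_sel)
  Ac <- sweep(A, 2, colMeans(A))
  sv <- svd(Ac, nu = 0)
  if (sv$d[1] < 1e-8) stop("degenerate actin geometry: all atoms coincident")
  if (sv$d[2] < 1e-8) stop("degenerate actin geometry: atoms are collinear")
  e2 <- sv$v[, 1]
  hint <- if (is.numeric(e2_direction)) e2_direction else A[nrow(A), ] - A[1, ]
  if (sum(e2 * hint) < 0) e2 <- -e2
  anchor <- mass_center(reference, anchor_sel)
  r <- anchor - origin
  r_perp <- r - sum(r * e2) * e2
  if (vec_norm(r_perp) < 1e-8)
    stop("anchor lies on the e2 line: interfilament axis undefined")
  e1 <- unit_vec(r_perp)
  e3 <- unit_vec(cross3(e1, e2))
  structure(list(origin = origin, e1 = e1, e2 = e2, e3 = e3),
            class = "crossbridge_frame")
}

#' @export
print.crossbridge_frame <- function(x, ...) {
  cat("<crossbridge_frame>\n")
  cat(sprintf("  origin: %8.3f %8.3f %8.3f\n", x$origin[1], x$origin[2], x$origin[3]))
  for (a in c("e1", "e2", "e3"))
    cat(sprintf("  %s:     %8.4f %8.4f %8.4f\n", a, x[[a]][1], x[[a]][2], x[[a]][3]))
  invisible(x)
}

# center of mass using standard atomic masses; unknown elements fall back
# to carbon
mass_center <- function(model, sel = NULL) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
              P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, FE = 55.845,
              MG = 24.305, ZN = 65.38, `NA` = 22.99, K = 39.098, MN = 54.938)
  xyz <- model_coords(model, sel)
  el <- toupper(model$atoms$elesy)
  if (!is.null(sel)) el <- el[as.integer(sel)]
  w <- unname(masses[el])
  w[is.na(w)] <- 12.011
  colSums(xyz * w) / sum(w)
}

#' Superpose a trajectory into the crossbridge reference frame
#'
#' Aligns every frame on a structural anchor (canonically the helix-loop-helix
#' motif of the lower 50 kDa domain) onto the corresponding atoms of the
#' reference complex, carrying the whole frame along rigidly.
#'
#' @param traj a [mol_traj()].
#' @param hlh_sel selection in the trajectory topology used for the fit.
#' @param reference the reference [mol_model()] (already posed in the frame).
#' @param reference_sel selection in `reference` corresponding atom-for-atom
#'   to `hlh_sel`.
#' @return the transformed trajectory.
#' @export
superpose_to_reference <- function(traj, hlh_sel, reference, reference_sel) {
  if (length(hlh_sel) != length(reference_sel))
    stop("selection length mismatch: ", length(hlh_sel), " vs ", length(reference_sel))
  ref <- model_coords(reference)[as.integer(reference_sel), , drop = FALSE]
  superpose_frames(traj, hlh_sel, ref)
}

#' Tail vector of the lever arm
#'
#' The lever-arm direction is the unit vector from the centroid of the
#' backbone heavy atoms (N, CA, C) of the proximal residue group to the
#' centroid of the same atoms of the distal group. Defaults follow the
#' N-terminal tail segment up to the ELC binding site (residues 769-771 to
#' 784-787).
#'
#' @param xyz N x 3 coordinates of a single frame (full topology).
#' @param topology the [mol_model()] the coordinates belong to.
#' @param proximal,distal residue number vectors for the two endpoint groups.
#' @param chain optional chain to restrict to.
#' @return list with `v` (unit vector), `proximal`, `distal` (centroids).
#' @export
tail_vector <- function(xyz, topology, proximal = 769:771, distal = 784:787,
                        chain = NULL) {
  xyz <- as_xyz_matrix(xyz)
  idx_p <- backbone_idx(topology, proximal, chain)
  idx_d <- backbone_idx(topology, distal, chain)
  p <- colMeans(xyz[idx_p, , drop = FALSE])
  d <- colMeans(xyz[idx_d, , drop = FALSE])
  if (vec_norm(d - p) < 1e-9) stop("tail endpoints coincide: zero-length tail vector")
  list(v = unit_vec(d - p), proximal = p, distal = d)
}

backbone_idx <- function(topology, resnos, chain = NULL) {
  at <- topology$atoms
  keep <- at$resno %in% resnos & at$elety %in% c("N", "CA", "C")
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  idx <- which(keep)
  want <- 3L * length(resnos)
  if (length(idx) != want) {
    have <- paste(at$elety[idx], at$resno[idx], sep = "@")
    missing <- setdiff(paste(rep(c("N", "CA", "C"), length(resnos)),
                             rep(resnos, each = 3), sep = "@"), have)
    stop("missing backbone atoms for tail vector: ",
         paste(missing, collapse = ", "))
  }
  idx
}

#' Tail orientation angles in the crossbridge frame
#'
#' For a unit tail vector `v` and frame axes (`e1`, `e2`, `e3`):
#' * elevation = 90 deg - angle(v, e1): the signed rise of the lever arm
#'   toward +e1 out of the e2-e3 plane, in \[-90, 90\] deg;
#' * azimuth = atan2(v.e3, v.e2): position about axis 1, measured from +e2
#'   toward +e3, in (-180, 180\] deg;
#' * tilt = angle(v, e3), in \[0, 180\] deg.
#'
#' At |elevation| = 90 deg the azimuth is undefined and reported as 0 with
#' the `degenerate` flag set.
#'
#' @param v unit 3-vector (checked to 1e-6).
#' @param frame a [build_crossbridge_frame()] result.
#' @return data.frame with `elevation`, `azimuth`, `tilt` (degrees) and
#'   logical `degenerate`.
#' @export
compute_tail_angles <- function(v, frame) {
  if (vec_norm(v) < 1e-9) stop("zero tail vector")
  v <- v / vec_norm(v)
  c1 <- sum(v * frame$e1); c2 <- sum(v * frame$e2); c3 <- sum(v * frame$e3)
  elevation <- 90 - rad2deg(acos(pmin(1, pmax(-1, c1))))
  degenerate <- abs(abs(elevation) - 90) < 1e-9 ||
    (abs(c2) < 1e-12 && abs(c3) < 1e-12)
  azimuth <- if (degenerate) 0 else rad2deg(atan2(c3, c2))
  tilt <- rad2deg(acos(pmin(1, pmax(-1, c3))))
  data.frame(elevation = elevation, azimuth = azimuth, tilt = tilt,
             degenerate = degenerate)
}

#' Per-frame tail angle series
#'
#' Measures the tail vector and its (elevation, azimuth, tilt) triple for
#' every frame of a trajectory that has already been superposed into the
#' crossbridge frame.
#'
#' @param traj a [mol_traj()], superposed into the frame.
#' @param frame a [build_crossbridge_frame()] result.
#' @inheritParams tail_vector
#' @return data.frame with `frame`, `time_ps`, `elevation`, `azimuth`,
#'   `tilt`, `replicate`, `condition`; per-angle means and standard
#'   deviations in attribute `summary`.
#' @export
angle_timeseries <- function(traj, frame, proximal = 769:771, distal = 784:787,
                             chain = NULL) {
  idx_p <- backbone_idx(traj$topology, proximal, chain)
  idx_d <- backbone_idx(traj$topology, distal, chain)
  nf <- n_frames(traj)
  res <- matrix(NA_real_, nf, 3)
  for (i in seq_len(nf)) {
    m <- frame_coords(traj, i)
    p <- colMeans(m[idx_p, , drop = FALSE]); d <- colMeans(m[idx_d, , drop = FALSE])
    ang <- compute_tail_angles(unit_vec(d - p), frame)
    res[i, ] <- c(ang$elevation, ang$azimuth, ang$tilt)
  }
  out <- data.frame(frame = seq_len(nf), time_ps = (seq_len(nf) - 1) * traj$timestep,
                    elevation = res[, 1], azimuth = res[, 2], tilt = res[, 3],
                    replicate = traj$replicate, condition = traj$condition,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- data.frame(
    angle = c("elevation", "azimuth", "tilt"),
    mean = colMeans(res), sd = apply(res, 2, stats::sd))
  out
}

#' Angle probability density
#'
#' Histogram density over uniform bins: in 1D the per-bin densities satisfy
#' sum(density * binwidth) = 1; in 2D sum(density * area) = 1. Default bin
#' width 2 degrees (and 2 x 2 degrees in 2D).
#'
#' @param samples numeric vector of angles (degrees); for `samples2` given,
#'   a joint 2D density of (samples, samples2) is computed.
#' @param width bin width in degrees (> 0); used for both dimensions in 2D.
#' @param samples2 optional second angle series of equal length.
#' @return list of class `angle_density`: `edges` (bin edges; list of two
#'   for 2D), `density` (vector, or matrix in 2D), `width`, `n`.
#' @export
angle_density <- function(samples, width = 2, samples2 = NULL) {
  if (!length(samples)) stop("no samples")
  if (width <= 0) stop("bin width must be > 0")
  edges1 <- density_edges(samples, width)
  if (is.null(samples2)) {
    cnt <- bin_counts(samples, edges1)
    dens <- cnt / (sum(cnt) * width)
    out <- list(edges = edges1, density = dens, width = width, n = length(samples))
  } else {
    if (length(samples2) != length(samples)) stop("sample series lengths differ")
    edges2 <- density_edges(samples2, width)
    i1 <- bin_index(samples, edges1); i2 <- bin_index(samples2, edges2)
    cnt <- matrix(0, length(edges1) - 1, length(edges2) - 1)
    for (k in seq_along(i1)) cnt[i1[k], i2[k]] <- cnt[i1[k], i2[k]] + 1
    dens <- cnt / (sum(cnt) * width * width)
    out <- list(edges = list(edges1, edges2), density = dens, width = width,
                n = length(samples))
  }
  class(out) <- "angle_density"
  out
}

# uniform-width edges anchored at width * floor(min / width); half-open
# [left, right) bins, so a topmost exact-edge sample gets one extra bin
density_edges <- function(x, width) {
  lo <- width * floor(min(x) / width)
  hi <- width * (floor(max(x) / width) + 1)
  seq(lo, hi, by = width)
}

bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = FALSE, left.open = FALSE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

bin_counts <- function(x, edges) {
  tabulate(bin_index(x, edges), nbins = length(edges) - 1L)
}
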