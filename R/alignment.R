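# Rigid-body superposition, average structures, LOVO least-mobile-subset
# alignment, and RMSD/RMSF with independent align/measure masks.

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `target`. Row-vector convention: the fitted coordinates are
#' `sweep(mobile, 2, cm) %*% R + ct` where `cm`/`ct` are the two centroids.
#'
#' @param mobile,target N x 3 coordinate matrices (or flat xyz vectors) with
#'   corresponding rows; N >= 3 and the point set must not be collinear.
#' @return list with `R` (3 x 3 proper rotation, det +1), `cm`, `ct`
#'   (centroids), and `rmsd` (post-fit, Angstrom).
#' @export
kabsch_superpose <- function(mobile, target) {
  A <- as_xyz_matrix(mobile); B <- as_xyz_matrix(target)
  if (nrow(A) != nrow(B)) stop("point counts differ: ", nrow(A), " vs ", nrow(B))
  if (nrow(A) < 3) stop("need at least 3 points for superposition")
  cm <- colMeans(A); ct <- colMeans(B)
  Ac <- sweep(A, 2, cm); Bc <- sweep(B, 2, ct)
  # rank check: collinear/coincident points have no unique fit
  if (sum(svd(Ac, nu = 0, nv = 0)$d > 1e-8) < 2)
    stop("degenerate (rank-deficient) point configuration")
  M <- crossprod(Ac, Bc)            # 3x3 covariance
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Ac %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Bc)^2)))
  list(R = R, cm = cm, ct = ct, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param xyz N x 3 matrix (or flat vector) to transform.
#' @param fit result of [kabsch_superpose()].
#' @return N x 3 matrix of transformed coordinates.
#' @export
apply_fit <- function(xyz, fit) {
  m <- as_xyz_matrix(xyz)
  sweep(sweep(m, 2, fit$cm) %*% fit$R, 2, fit$ct, "+")
}

rmsd_between <- function(a, b) {
  a <- as_xyz_matrix(a); b <- as_xyz_matrix(b)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Superpose every frame onto a set of reference coordinates
#'
#' Each frame is rigid-body transformed to minimize the RMSD of the atoms in
#' `sel` onto `ref_xyz`; internal frame geometry is unchanged.
#'
#' @param traj a [mol_traj()].
#' @param sel atoms used in the fit.
#' @param ref_xyz reference coordinates for `sel` (N_sel x 3), or a full-model
#'   N x 3 matrix from which `sel` rows are taken.
#' @return the trajectory with transformed frames; per-frame fit RMSDs in
#'   attribute `fit_rmsd`.
#' @export
superpose_frames <- function(traj, sel, ref_xyz) {
  idx <- as.integer(sel)
  ref <- as_xyz_matrix(ref_xyz)
  if (nrow(ref) != length(idx)) ref <- ref[idx, , drop = FALSE]
  out <- traj$xyz
  fr <- numeric(n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, i)
    fit <- kabsch_superpose(m[idx, , drop = FALSE], ref)
    out[i, ] <- xyz_flat(apply_fit(m, fit))
    fr[i] <- fit$rmsd
  }
  traj$xyz <- out
  attr(traj, "fit_rmsd") <- fr
  traj
}

#' Average structure over trajectory frames
#'
#' Per-atom arithmetic mean of coordinates. The caller is responsible for
#' aligning the trajectory first, mirroring the usual order of operations.
#'
#' @param traj a [mol_traj()].
#' @param sel optional selection; the returned model is restricted to it.
#' @return A [mol_model()] with averaged coordinates.
#' @export
average_structure <- function(traj, sel = NULL) {
  if (n_frames(traj) < 1) stop("empty trajectory")
  avg <- matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)
  model <- set_model_coords(traj$topology, avg)
  model$source <- sprintf("average of %d frames (%s/%s)", n_frames(traj),
                          traj$condition, traj$replicate)
  if (!is.null(sel)) {
    model$atoms <- model$atoms[as.integer(sel), , drop = FALSE]
    rownames(model$atoms) <- NULL
  }
  model
}

# per-atom RMS deviation from the average structure, over frames, for the
# atoms in idx (returns one value per atom in idx)
per_atom_rms <- function(xyz, idx) {
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  sub <- xyz[, cols, drop = FALSE]
  avg <- colMeans(sub)
  dev2 <- sweep(sub, 2, avg)^2
  msd <- colMeans(dev2)
  sqrt(msd[seq(1, length(msd), 3)] + msd[seq(2, length(msd), 3)] +
         msd[seq(3, length(msd), 3)])
}

#' LOVO least-mobile-subset trajectory alignment
#'
#' Iterative low-order-value-optimization: starting from all atoms in
#' `calpha_sel`, repeatedly (i) superpose every frame on the current subset
#' to the current average structure, (ii) recompute the average, (iii)
#' compute each atom's time-averaged RMS deviation from the average, and
#' (iv) retain the `round(fraction * N)` least-mobile atoms as the new
#' subset, until subset membership reaches a fixed point (or `max_iter`).
#' Ties at the subset boundary resolve to the lower atom index.
#'
#' @param traj a [mol_traj()].
#' @param fraction fraction phi of atoms to keep, in (0, 1]. The default
#'   0.35 mirrors common practice of aligning on the ~35% least mobile
#'   C-alpha atoms.
#' @param calpha_sel selection of candidate atoms; default: all CA atoms.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param tol average-structure drift (mean per-atom displacement, Angstrom)
#'   below which, together with subset stability, iteration halts.
#' @param stride optional frame stride applied before fitting (the final
#'   transforms are still computed for every retained frame).
#' @return list of class `lovo_fit`: `subset` (atom_sel into the trajectory
#'   topology), `per_atom_rmsd` (over `calpha_sel`, Angstrom),
#'   `subset_rmsd` (per-frame RMSD of subset atoms to the average),
#'   `traj` (aligned trajectory), `fraction`, `iterations`, `converged`.
#' @export
lovo_fit <- function(traj, fraction = 0.35, calpha_sel = NULL,
                     max_iter = 50, tol = 1e-6, stride = 1) {
  if (is.null(calpha_sel)) calpha_sel <- select_atoms(traj$topology, "calpha")
  idx_all <- as.integer(calpha_sel)
  if (!length(idx_all)) stop("no candidate atoms for LOVO fit")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_keep <- round(fraction * length(idx_all))
  if (n_keep < 3) stop("fraction * N must be at least 3 atoms")
  if (stride > 1) traj <- stride_frames(traj, stride)

  subset <- idx_all
  avg_prev <- NULL
  converged <- FALSE
  iters <- 0
  for (it in seq_len(max_iter)) {
    iters <- it
    avg <- matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)
    traj <- superpose_frames(traj, new_atom_sel(subset), avg[subset, , drop = FALSE])
    avg_new <- matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)
    rms <- per_atom_rms(traj$xyz, idx_all)
    # lowest-RMS subset; ties at the boundary go to the lower atom index
    ord <- order(rms, seq_along(rms))
    new_subset <- sort(idx_all[ord[seq_len(n_keep)]])
    drift <- if (is.null(avg_prev)) Inf else mean(sqrt(rowSums((avg_new - avg_prev)^2)))
    avg_prev <- avg_new
    if (identical(new_subset, subset) && drift < tol) {
      converged <- TRUE
      break
    }
    subset <- new_subset
  }
  rms <- per_atom_rms(traj$xyz, idx_all)
  avg <- matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)
  sub_cols <- as.vector(rbind(3 * subset - 2, 3 * subset - 1, 3 * subset))
  subset_rmsd <- sqrt(rowMeans(sweep(traj$xyz[, sub_cols, drop = FALSE], 2,
                                     as.numeric(t(avg[subset, , drop = FALSE])))^2 * 3))
  structure(list(subset = new_atom_sel(subset, sprintf("lovo fraction %.2f", fraction)),
                 per_atom_rmsd = stats::setNames(rms, idx_all),
                 subset_rmsd = subset_rmsd,
                 traj = traj, fraction = fraction,
                 iterations = iters, converged = converged),
            class = "lovo_fit")
}

#' @export
print.lovo_fit <- function(x, ...) {
  cat(sprintf("<lovo_fit> phi = %.2f, subset %d atoms, %d iterations (%s)\n",
              x$fraction, length(x$subset), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  mean subset RMSD to average: %.4f A\n", mean(x$subset_rmsd)))
  invisible(x)
}

#' Per-frame RMSD with independent align and measure masks
#'
#' Each frame is superposed on `align_sel` onto the reference, then the RMSD
#' is evaluated over `measure_sel`; the two masks may differ (e.g. align on a
#' rigid core, measure all C-alpha atoms).
#'
#' @param traj a [mol_traj()].
#' @param align_sel,measure_sel selections valid for both the trajectory
#'   topology and the reference model.
#' @param reference a [mol_model()] supplying reference coordinates.
#' @return numeric vector of per-frame RMSDs (Angstrom), with the
#'   time-average in attribute `mean`.
#' @export
rmsd_series <- function(traj, align_sel, measure_sel, reference) {
  ai <- as.integer(align_sel); mi <- as.integer(measure_sel)
  ref <- model_coords(reference)
  if (max(c(ai, mi)) > nrow(ref) || max(c(ai, mi)) > n_atoms(traj$topology))
    stop("selection out of range for trajectory or reference")
  ref_a <- ref[ai, , drop = FALSE]; ref_m <- ref[mi, , drop = FALSE]
  out <- numeric(n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, i)
    fit <- kabsch_superpose(m[ai, , drop = FALSE], ref_a)
    out[i] <- rmsd_between(apply_fit(m[mi, , drop = FALSE], fit), ref_m)
  }
  attr(out, "mean") <- mean(out)
  out
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its time-average
#' position. The trajectory must already be aligned (typically to a LOVO
#' subset); RMSF is computed in place with no further fitting.
#'
#' @param traj a pre-aligned [mol_traj()].
#' @param sel selection of atoms to profile (default: all CA atoms).
#' @return data.frame with `chain`, `resno`, `insert`, `rmsf` (Angstrom),
#'   `replicate`, `condition`.
#' @export
rmsf_profile <- function(traj, sel = NULL) {
  if (is.null(sel)) sel <- select_atoms(traj$topology, "calpha")
  idx <- as.integer(sel)
  if (n_frames(traj) < 2) warning("single frame: RMSF is identically zero")
  rms <- per_atom_rms(traj$xyz, idx)
  at <- traj$topology$atoms[idx, , drop = FALSE]
  data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
             rmsf = rms, replicate = traj$replicate,
             condition = traj$condition, stringsAsFactors = FALSE)
}
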