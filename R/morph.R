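# Elevation-binned ensemble averaging and interpolated morph trajectories.

#' Bin trajectory frames by elevation angle and average per bin
#'
#' Frames are re-aligned on the motor domain-lever arm junction (so the
#' averages are taken in a common frame), assigned to uniform elevation
#' bins (left-closed, right-open; a frame exactly on an edge goes to the
#' right-hand bin), and per-bin coordinate averages are computed. The bin
#' grid is `n_bins` bins of `width` degrees anchored at
#' `width * floor(min(elevation) / width)`.
#'
#' @param traj a [mol_traj()].
#' @param angles an [angle_timeseries()] data.frame with one row per frame.
#' @param junction_sel selection used for the re-alignment (canonically the
#'   converter-start region, residues 704-723).
#' @param width bin width in degrees (default 5).
#' @param n_bins number of bins (default 20). Frames whose elevation falls
#'   beyond the grid are dropped with a warning.
#' @return object of class `binned_ensemble`: `edges`, `counts`,
#'   `conformers` (list of [mol_model()] averages; NULL for empty bins),
#'   `centers`.
#' @export
bin_by_elevation <- function(traj, angles, junction_sel, width = 5,
                             n_bins = 20) {
  if (nrow(angles) != n_frames(traj))
    stop("angle series length does not match frame count")
  ref <- frame_coords(traj, 1)[as.integer(junction_sel), , drop = FALSE]
  traj <- superpose_frames(traj, junction_sel, ref)
  el <- angles$elevation
  anchor <- width * floor(min(el) / width)
  edges <- anchor + width * (0:n_bins)
  idx <- floor((el - anchor) / width) + 1L
  out_of_grid <- idx > n_bins | idx < 1L
  if (any(out_of_grid)) {
    warning(sum(out_of_grid), " frame(s) beyond the elevation grid dropped")
    idx[out_of_grid] <- NA_integer_
  }
  counts <- tabulate(idx[!is.na(idx)], nbins = n_bins)
  if (sum(counts > 0) == 1) warning("all frames fall in a single elevation bin")
  conformers <- vector("list", n_bins)
  for (b in which(counts > 0)) {
    rows <- which(!is.na(idx) & idx == b)
    avg <- matrix(colMeans(traj$xyz[rows, , drop = FALSE]), ncol = 3, byrow = TRUE)
    m <- set_model_coords(traj$topology, avg)
    m$source <- sprintf("elevation bin [%g, %g) deg, %d frames",
                        edges[b], edges[b + 1], counts[b])
    conformers[[b]] <- m
  }
  structure(list(edges = edges, counts = counts, conformers = conformers,
                 centers = (edges[-1] + edges[-length(edges)]) / 2),
            class = "binned_ensemble")
}

#' @export
print.binned_ensemble <- function(x, ...) {
  cat(sprintf("<binned_ensemble> %d bins of %g deg, %d occupied, %d frames\n",
              length(x$counts), diff(x$edges[1:2]), sum(x$counts > 0),
              sum(x$counts)))
  invisible(x)
}

#' Interpolated morph between bin-averaged conformers
#'
#' Linear per-atom Cartesian interpolation between consecutive occupied bin
#' averages, ordered by bin center, with `steps_per_transition` intermediate
#' frames inserted between each pair; the endpoints equal the bin averages
#' exactly. The result is deliberately nonphysical - it visualises the range
#' of motion, not a dynamical path.
#'
#' @param binned a [bin_by_elevation()] result with >= 2 occupied bins.
#' @param steps_per_transition intermediate frames per transition (0 yields
#'   just the ordered bin averages).
#' @return a [mol_traj()] with `(B - 1) * steps + B` frames for `B` occupied
#'   bins.
#' @export
interpolate_morph <- function(binned, steps_per_transition = 10) {
  occ <- which(binned$counts > 0)
  if (length(occ) < 2) stop("need at least 2 occupied bins to morph")
  confs <- binned$conformers[occ]
  s <- as.integer(steps_per_transition)
  frames <- list(model_coords(confs[[1]]))
  for (i in seq_len(length(confs) - 1)) {
    a <- model_coords(confs[[i]]); b <- model_coords(confs[[i + 1]])
    if (s > 0) {
      for (k in seq_len(s)) {
        w <- k / (s + 1)
        frames[[length(frames) + 1]] <- (1 - w) * a + w * b
      }
    }
    frames[[length(frames) + 1]] <- b
  }
  xyz <- do.call(rbind, lapply(frames, xyz_flat))
  mol_traj(confs[[1]], xyz, timestep = 1, replicate = "morph",
           condition = "other")
}
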