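#' Molecular model container
#'
#' A `mol_model` is the single-structure unit used throughout the package: a
#' table of atoms with chain / residue / atom identity and Cartesian
#' coordinates in Angstrom. Residue identity includes the insertion code and
#' follows the author numbering of the source file (no renumbering).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z`.
#' @param source free-text label recording where the model came from.
#'
#' @return An object of class `mol_model`.
#' @export
mol_model <- function(atoms, source = "") {
  req <- c("chain", "resno", "insert", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms[, req], stringsAsFactors = FALSE)
  atoms$insert[is.na(atoms$insert)] <- ""
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicated (chain, residue, atom name) identity: ",
         key[duplicated(key)][1])
  }
  structure(list(atoms = atoms, source = source), class = "mol_model")
}

#' @export
print.mol_model <- function(x, ...) {
  cat(sprintf("<mol_model> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), length(unique(residue_keys(x))),
              paste(sort(unique(x$atoms$chain)), collapse = " ")))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

n_atoms <- function(model) nrow(model$atoms)

#' Extract model coordinates as an N x 3 matrix
#' @param model a [mol_model()].
#' @param sel optional [select_atoms()] selection.
#' @return numeric matrix with one row per atom.
#' @export
model_coords <- function(model, sel = NULL) {
  m <- as.matrix(model$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  if (!is.null(sel)) m <- m[as.integer(sel), , drop = FALSE]
  m
}

set_model_coords <- function(model, xyz) {
  xyz <- as_xyz_matrix(xyz)
  stopifnot(nrow(xyz) == n_atoms(model))
  model$atoms[, c("x", "y", "z")] <- xyz
  model
}

# one key per atom identifying its residue
residue_keys <- function(model) {
  paste0(model$atoms$chain, ":", model$atoms$resno, model$atoms$insert)
}

#' Trajectory container
#'
#' An ordered stack of coordinate frames over one topology. Frames are stored
#' as an F x 3N matrix (one row per frame, xyz-interleaved), the layout used
#' by bio3d, so bio3d tooling interoperates directly.
#'
#' @param topology a [mol_model()] giving atom identities.
#' @param xyz F x 3N numeric matrix of coordinates in Angstrom.
#' @param timestep time between stored frames, in ps.
#' @param replicate replicate label, e.g. `"run1"`.
#' @param condition one of `"apo"`, `"holo"`, `"other"`.
#'
#' @return An object of class `mol_traj`.
#' @export
mol_traj <- function(topology, xyz, timestep = 10, replicate = "run1",
                     condition = c("other", "apo", "holo")) {
  condition <- match.arg(condition, c("other", "apo", "holo"))
  if (!inherits(topology, "mol_model")) stop("topology must be a mol_model")
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * n_atoms(topology)) {
    stop(sprintf("frame atom count mismatch: expected %d atoms, found %g",
                 n_atoms(topology), ncol(xyz) / 3))
  }
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (!is.numeric(timestep) || timestep <= 0) stop("timestep must be > 0")
  structure(list(topology = topology, xyz = unname(as.matrix(xyz)),
                 timestep = timestep, replicate = replicate,
                 condition = condition),
            class = "mol_traj")
}

#' @export
print.mol_traj <- function(x, ...) {
  cat(sprintf("<mol_traj> %d frames x %d atoms, dt = %g ps, %s/%s\n",
              n_frames(x), n_atoms(x$topology), x$timestep,
              x$condition, x$replicate))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [mol_traj()].
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an N x 3 matrix
#' @param traj a [mol_traj()].
#' @param i frame index (1-based).
#' @param sel optional selection of atoms.
#' @export
frame_coords <- function(traj, i, sel = NULL) {
  m <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
  if (!is.null(sel)) m <- m[as.integer(sel), , drop = FALSE]
  m
}

#' Keep every k-th frame of a trajectory
#'
#' @param traj a [mol_traj()].
#' @param stride keep frames 1, 1+k, 1+2k, ... The stored timestep is scaled
#'   accordingly.
#' @export
stride_frames <- function(traj, stride) {
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1")
  keep <- seq(1L, n_frames(traj), by = stride)
  traj$xyz <- traj$xyz[keep, , drop = FALSE]
  traj$timestep <- traj$timestep * stride
  traj
}

#' Drop an initial equilibration period
#'
#' Removes leading frames covering `discard_ns` nanoseconds, using the
#' trajectory timestep for the conversion.
#'
#' @param traj a [mol_traj()].
#' @param discard_ns equilibration time to drop, in ns.
#' @export
discard_equilibration <- function(traj, discard_ns) {
  n_drop <- floor(discard_ns * 1000 / traj$timestep)
  if (n_drop >= n_frames(traj)) stop("equilibration discard removes every frame")
  if (n_drop > 0) traj$xyz <- traj$xyz[-seq_len(n_drop), , drop = FALSE]
  traj
}
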