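# Structure and trajectory file I/O, built on bio3d. All other modules go
# through mol_model / mol_traj and never touch file formats directly.

#' Read a structure from a PDB file
#'
#' Reads a standard PDB file into a [mol_model()]. Insertion codes are kept
#' as part of residue identity and residue numbers follow the file (no
#' renumbering). When alternate locations are present, the highest-occupancy
#' altloc is kept per atom (ties resolved in favour of altloc `A`).
#'
#' @param path path to a PDB file.
#' @param chains optional character vector of chain identifiers to keep.
#' @param heavy_only drop hydrogens (element `H`)? Elements are taken from
#'   the element column when present, otherwise inferred from the atom name.
#' @return A [mol_model()].
#' @export
read_structure <- function(path, chains = NULL, heavy_only = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  model_from_atom_table(at, source = path, chains = chains,
                        heavy_only = heavy_only)
}

# shared post-processing for bio3d atom tables
model_from_atom_table <- function(at, source, chains = NULL, heavy_only = FALSE) {
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  if (!is.null(chains)) {
    at <- at[at$chain %in% chains, , drop = FALSE]
    if (!nrow(at)) stop("empty selection: no atoms in chain(s) ",
                        paste(chains, collapse = ", "))
  }
  # altloc policy: keep the highest-occupancy altloc; tie -> 'A'
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -at$o, at$alt != "A", at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  elesy <- at$elesy
  bad <- is.na(elesy) | !nzchar(trimws(elesy))
  if (any(bad)) elesy[bad] <- infer_element(at$elety[bad])
  if (heavy_only) {
    at <- at[toupper(trimws(elesy)) != "H", , drop = FALSE]
    elesy <- elesy[toupper(trimws(elesy)) != "H"]
    if (!nrow(at)) stop("empty selection: no heavy atoms left after filtering")
  }
  mol_model(data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                       resid = at$resid, elety = at$elety,
                       elesy = toupper(trimws(elesy)),
                       x = at$x, y = at$y, z = at$z,
                       stringsAsFactors = FALSE),
            source = source)
}

# element from atom name: strip leading digits, take the first letter; names
# like 1HB2 / HD11 are hydrogens
infer_element <- function(elety) {
  nm <- toupper(trimws(elety))
  nm <- sub("^[0-9]+", "", nm)
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el[two %in% c("CL", "BR", "FE", "MG", "ZN", "NA", "MN")] <-
    two[two %in% c("CL", "BR", "FE", "MG", "ZN", "NA", "MN")]
  el
}

# validate fixed-width coordinate records up-front so parse failures name
# the offending line
check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  idx <- which(rec)
  coords <- cbind(substr(lines[idx], 31, 38),
                  substr(lines[idx], 39, 46),
                  substr(lines[idx], 47, 54))
  num <- suppressWarnings(apply(coords, 2, as.numeric))
  bad <- which(!stats::complete.cases(num))
  if (length(bad)) {
    stop(sprintf("unparseable coordinate record at line %d of %s",
                 idx[bad[1]], path))
  }
  invisible(TRUE)
}

#' Read a trajectory from multi-model PDB file(s)
#'
#' Multi-model PDB is the portable trajectory dialect used by this package;
#' frames are returned in stored order. Several files may be given and are
#' concatenated in order.
#'
#' @param paths one or more multi-model PDB files.
#' @param topology a [mol_model()] the frames must match atom-for-atom.
#' @param stride keep every `stride`-th frame (1 keeps everything).
#' @param timestep ps between stored frames (before striding).
#' @param replicate,condition labels stored on the trajectory.
#' @return A [mol_traj()].
#' @export
read_trajectory <- function(paths, topology, stride = 1, timestep = 10,
                            replicate = "run1", condition = "other") {
  xyz <- NULL
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    pdb <- suppressWarnings(bio3d::read.pdb(p, multi = TRUE, rm.alt = FALSE,
                                            verbose = FALSE))
    x <- pdb$xyz
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (ncol(x) != 3L * n_atoms(topology)) {
      stop(sprintf("atom-count mismatch in %s: expected %d atoms, found %g",
                   p, n_atoms(topology), ncol(x) / 3))
    }
    xyz <- rbind(xyz, unname(as.matrix(x)))
  }
  traj <- mol_traj(topology, xyz, timestep = timestep, replicate = replicate,
                   condition = condition)
  if (stride > 1) traj <- stride_frames(traj, stride) else traj
}

#' Write a model to a PDB file
#' @param model a [mol_model()].
#' @param path output path.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = xyz_flat(model_coords(model)),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(nzchar(at$insert), at$insert, ""),
                   elety = at$elety, elesy = at$elesy,
                   eleno = seq_len(nrow(at)))
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#' @param traj a [mol_traj()].
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  at <- traj$topology$atoms
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(nzchar(at$insert), at$insert, ""),
                   elety = at$elety, elesy = at$elesy,
                   eleno = seq_len(nrow(at)))
  invisible(path)
}
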