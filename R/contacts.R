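# Heavy-atom contact detection (5 A criterion), occupancy statistics,
# differential apo/holo contact analysis, and salt-bridge tracking against
# lever-arm orientation.

# Cell-list candidate search: returns unique (i, j) atom-index pairs with
# |xyzA[i,] - xyzB[j,]| <= cutoff. Cost is near-linear in atom count because
# only atoms in neighbouring cells of an axis-aligned grid (cell edge =
# cutoff) are compared. Cell ids are packed into integers (grid span is
# limited to 1024 cells per axis, ample for molecular systems).
grid_close_pairs <- function(xyzA, xyzB, cutoff) {
  cA <- floor(xyzA / cutoff); cB <- floor(xyzB / cutoff)
  o <- pmin(apply(cA, 2, min), apply(cB, 2, min))
  code <- function(cc) {
    (cc[, 1] - o[1] + 1L) + 1024L * ((cc[, 2] - o[2] + 1L) +
                                       1024L * (cc[, 3] - o[3] + 1L))
  }
  codeA <- code(cA); codeB <- code(cB)
  ordA <- order(codeA)
  sortedA <- codeA[ordA]
  uA <- unique(sortedA)
  starts <- match(uA, sortedA)
  ends <- c(starts[-1] - 1L, length(sortedA))
  ai_all <- integer(0); bi_all <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    nb <- codeB + dx + 1024L * (dy + 1024L * dz)
    hit <- match(nb, uA)
    keep <- which(!is.na(hit))
    if (!length(keep)) next
    h <- hit[keep]
    lens <- ends[h] - starts[h] + 1L
    ai_all <- c(ai_all, ordA[sequence(lens, from = starts[h])])
    bi_all <- c(bi_all, rep.int(keep, lens))
  }
  if (!length(ai_all)) return(cbind(i = integer(0), j = integer(0)))
  d2 <- (xyzA[ai_all, 1] - xyzB[bi_all, 1])^2 +
    (xyzA[ai_all, 2] - xyzB[bi_all, 2])^2 +
    (xyzA[ai_all, 3] - xyzB[bi_all, 3])^2
  sel <- d2 <= cutoff^2
  cbind(i = ai_all[sel], j = bi_all[sel])
}

# unique residue-pair codes (lo * 1e6 + hi over residue ranks) for one frame
frame_contact_codes <- function(xyz, ia, ib, rank, cutoff) {
  hits <- grid_close_pairs(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE],
                           cutoff)
  if (!nrow(hits)) return(numeric(0))
  ra <- rank[ia[hits[, 1]]]; rb <- rank[ib[hits[, 2]]]
  keep <- ra != rb
  if (!any(keep)) return(numeric(0))
  lo <- pmin(ra[keep], rb[keep]); hi <- pmax(ra[keep], rb[keep])
  unique(lo * 1e6 + hi)
}

#' Residue contacts in a single frame
#'
#' Two residues are in contact when at least one pair of heavy atoms is
#' within `cutoff` Angstrom (boundary inclusive). Detection uses a spatial
#' grid, so the cost is near-linear in atom count.
#'
#' @param xyz N x 3 coordinates of the frame (full topology).
#' @param topology the [mol_model()] the coordinates belong to.
#' @param groupA,groupB atom selections (heavy atoms) defining the two sides;
#'   for intra-group contacts pass the same selection twice.
#' @param cutoff distance criterion in Angstrom (default 5).
#' @return data.frame of contacting residue pairs: `res_i`, `res_j`
#'   (residue keys `chain:resno`), in canonical order (`res_i` before
#'   `res_j` in topology order; self-pairs removed).
#' @export
frame_contacts <- function(xyz, topology, groupA, groupB, cutoff = 5.0) {
  if (!length(groupA) || !length(groupB)) stop("empty contact group")
  xyz <- as_xyz_matrix(xyz)
  ia <- as.integer(groupA); ib <- as.integer(groupB)
  keys <- residue_keys(topology)
  ukeys <- unique(keys)
  rank <- match(keys, ukeys)   # topology order of residues
  codes <- frame_contact_codes(xyz, ia, ib, rank, cutoff)
  data.frame(res_i = ukeys[codes %/% 1e6], res_j = ukeys[codes %% 1e6],
             stringsAsFactors = FALSE)
}

# default protein heavy-atom selection (standard amino-acid residues only)
protein_heavy_sel <- function(model) {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HID", "HIE", "HIP")
  at <- model$atoms
  new_atom_sel(which(at$resid %in% aa & toupper(at$elesy) != "H"),
               "protein heavy atoms")
}

#' Residue-residue contact occupancy table for one replicate
#'
#' Evaluates residue contacts at a coarser time granularity (default one
#' frame per 100 ps) and tabulates, for every residue pair observed at least
#' once, the fraction of evaluated frames in which it was in contact.
#'
#' @param traj a [mol_traj()] (alignment is irrelevant: contacts are
#'   invariant under rigid motion).
#' @param stride_ps contact analysis granularity in ps; must not exceed the
#'   trajectory duration.
#' @param sel atom selection to analyse (default: all heavy atoms of
#'   standard protein residues, so ligand/solvent are excluded).
#' @param cutoff heavy-atom distance criterion in Angstrom.
#' @return data.frame with `res_i`, `res_j`, `occupancy`, `frames`,
#'   `replicate`, `condition`.
#' @export
residue_contact_tables <- function(traj, stride_ps = 100, sel = NULL,
                                   cutoff = 5.0) {
  if (is.null(sel)) sel <- protein_heavy_sel(traj$topology)
  step <- max(1L, round(stride_ps / traj$timestep))
  if (stride_ps > traj$timestep * n_frames(traj))
    stop("contact stride exceeds trajectory duration")
  frames <- seq(1L, n_frames(traj), by = step)
  keys <- residue_keys(traj$topology)
  ukeys <- unique(keys)
  rank <- match(keys, ukeys)
  ia <- as.integer(sel)
  per_frame <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    per_frame[[k]] <- frame_contact_codes(frame_coords(traj, frames[k]),
                                          ia, ia, rank, cutoff)
  }
  codes <- unlist(per_frame)
  if (!length(codes)) {
    return(data.frame(res_i = character(0), res_j = character(0),
                      occupancy = numeric(0), frames = integer(0),
                      replicate = character(0), condition = character(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(codes)
  code_u <- as.numeric(names(tab))
  out <- data.frame(res_i = ukeys[code_u %/% 1e6], res_j = ukeys[code_u %% 1e6],
                    occupancy = as.integer(tab) / length(frames),
                    frames = length(frames),
                    replicate = traj$replicate, condition = traj$condition,
                    stringsAsFactors = FALSE)
  out <- out[order(code_u), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ligand-protein contact occupancy across replicates
#'
#' Tracks, per protein residue, the fraction of frames in which any ligand
#' heavy atom is within `cutoff` of any residue heavy atom; averages across
#' replicates; drops residues whose averaged occupancy falls below
#' `min_occupancy`; and, when an experimental pose is supplied, classifies
#' MD-only residues as novel contacts and reports the number of replicates
#' in which each contact appears (persistence tiers).
#'
#' @param trajs list of holo [mol_traj()] replicates.
#' @param ligand_sel selection of ligand heavy atoms (in the shared topology).
#' @param min_occupancy exclusion threshold on the replicate-averaged
#'   occupancy (default 0.05, i.e. interactions present for less than 5% of
#'   simulation time are excluded).
#' @param xray optional [mol_model()] of the experimental complex; its
#'   single-pose contact set defines the reference residue list.
#' @param xray_ligand_sel,xray_protein_sel selections in `xray` (defaults:
#'   same provenance as `ligand_sel` / protein heavy atoms).
#' @param protein_sel protein-side selection in the trajectory topology
#'   (default: protein heavy atoms).
#' @param cutoff distance criterion in Angstrom.
#' @param stride_ps analysis granularity in ps (default: every stored frame).
#' @return list with `table` (residue, per-replicate occupancies, `avg`,
#'   `tier` = number of replicates with the contact, `novel`), and
#'   `xray_contacts` (character vector of residue keys, or NULL).
#' @export
ligand_occupancy <- function(trajs, ligand_sel, min_occupancy = 0.05,
                             xray = NULL, xray_ligand_sel = NULL,
                             xray_protein_sel = NULL, protein_sel = NULL,
                             cutoff = 5.0, stride_ps = NULL) {
  if (!length(ligand_sel)) stop("ligand selection is empty")
  if (inherits(trajs, "mol_traj")) trajs <- list(trajs)
  topo <- trajs[[1]]$topology
  if (is.null(protein_sel)) protein_sel <- protein_heavy_sel(topo)
  keys <- residue_keys(topo)
  ukeys <- unique(keys)
  rank <- match(keys, ukeys)
  lig_res <- unique(rank[as.integer(ligand_sel)])
  occ <- list()
  for (r in seq_along(trajs)) {
    tr <- trajs[[r]]
    step <- if (is.null(stride_ps)) 1L else max(1L, round(stride_ps / tr$timestep))
    frames <- seq(1L, n_frames(tr), by = step)
    per_frame <- vector("list", length(frames))
    for (k in seq_along(frames)) {
      codes <- frame_contact_codes(frame_coords(tr, frames[k]),
                                   as.integer(protein_sel),
                                   as.integer(ligand_sel), rank, cutoff)
      res <- unique(c(codes %/% 1e6, codes %% 1e6))
      per_frame[[k]] <- setdiff(res, lig_res)
    }
    cnt <- table(unlist(per_frame))
    occ[[r]] <- stats::setNames(as.integer(cnt) / length(frames),
                                ukeys[as.numeric(names(cnt))])
  }
  all_res <- unique(unlist(lapply(occ, names)))
  if (!length(all_res)) stop("no ligand-protein contacts found in any replicate")
  mat <- sapply(occ, function(o) ifelse(all_res %in% names(o), o[all_res], 0))
  mat <- matrix(mat, nrow = length(all_res),
                dimnames = list(all_res, paste0("rep", seq_along(trajs))))
  avg <- rowMeans(mat)
  xray_contacts <- NULL
  if (!is.null(xray)) {
    if (is.null(xray_protein_sel)) xray_protein_sel <- protein_heavy_sel(xray)
    if (is.null(xray_ligand_sel))
      xray_ligand_sel <- select_atoms(xray, attr(ligand_sel, "provenance"))
    fc <- frame_contacts(model_coords(xray), xray, xray_protein_sel,
                         xray_ligand_sel, cutoff)
    xray_contacts <- setdiff(unique(c(fc$res_i, fc$res_j)),
                             residue_keys(xray)[as.integer(xray_ligand_sel)])
  }
  keep <- avg >= min_occupancy
  tab <- data.frame(residue = all_res[keep], mat[keep, , drop = FALSE],
                    avg = avg[keep],
                    tier = rowSums(mat[keep, , drop = FALSE] > 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(xray_contacts)) tab$novel <- !(tab$residue %in% xray_contacts)
  tab <- tab[order(-tab$avg), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, xray_contacts = xray_contacts)
}

#' Differential apo/holo contacts
#'
#' Unions residue pairs across all replicate occupancy tables (occupancy 0
#' where a pair is absent), tests each pair with a pooled two-tailed
#' Student's t over the per-replicate occupancies, and reports pairs with
#' `p <= alpha` and an absolute occupancy difference of at least
#' `delta_threshold`. Output at threshold 0.20 nests inside 0.10 inside
#' 0.05.
#'
#' @param apo_tables,holo_tables lists of [residue_contact_tables()] outputs
#'   (>= 2 replicates each).
#' @param alpha significance level (default 0.05).
#' @param delta_threshold minimum |mean apo - mean holo| occupancy
#'   difference (default 0.10).
#' @return data.frame of flagged pairs: `res_i`, `res_j`, `occ_apo`,
#'   `occ_holo`, `delta`, `p`, `dominant` (`"apo"` or `"holo"`). The
#'   unfiltered per-pair test table is in attribute `all_pairs`.
#' @export
differential_contacts <- function(apo_tables, holo_tables, alpha = 0.05,
                                  delta_threshold = 0.10) {
  if (length(apo_tables) < 2 || length(holo_tables) < 2)
    stop("need at least 2 replicates per condition")
  pk <- function(tab) paste(tab$res_i, tab$res_j, sep = "|")
  all_pairs <- unique(unlist(c(lapply(apo_tables, pk), lapply(holo_tables, pk))))
  occ_of <- function(tab) {
    v <- stats::setNames(numeric(length(all_pairs)), all_pairs)
    v[pk(tab)] <- tab$occupancy
    v
  }
  amat <- sapply(apo_tables, occ_of)
  hmat <- sapply(holo_tables, occ_of)
  n <- length(all_pairs)
  pv <- numeric(n)
  for (i in seq_len(n)) pv[i] <- students_t_two_tailed(amat[i, ], hmat[i, ])$p
  delta <- rowMeans(amat) - rowMeans(hmat)
  sp <- strsplit(all_pairs, "|", fixed = TRUE)
  full <- data.frame(res_i = vapply(sp, `[`, "", 1), res_j = vapply(sp, `[`, "", 2),
                     occ_apo = rowMeans(amat), occ_holo = rowMeans(hmat),
                     delta = delta, p = pv,
                     dominant = ifelse(delta > 0, "apo", "holo"),
                     stringsAsFactors = FALSE, row.names = NULL)
  out <- full[full$p <= alpha & abs(full$delta) >= delta_threshold, , drop = FALSE]
  out <- out[order(-abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_pairs") <- full
  out
}

#' Salt-bridge occupancy stratified by lever-arm elevation
#'
#' Tracks charged-residue pair contacts (the 5 A heavy-atom criterion
#' restricted to side-chain nitrogen/oxygen atoms) within elevation strata,
#' so bridges that form or break as the lever arm rotates can be summarised.
#' Residues with no side-chain N/O (e.g. reduced synthetic residues) fall
#' back to all their N/O atoms.
#'
#' @param traj a [mol_traj()].
#' @param pairs list of length-2 vectors of residue keys (`"chain:resno"`)
#'   or plain residue numbers (first matching residue used).
#' @param angles an [angle_timeseries()] data.frame for the same frames.
#' @param breaks elevation cut points in degrees defining the strata, e.g.
#'   `c(20, 40)` gives low/mid/high.
#' @param cutoff distance criterion in Angstrom.
#' @return data.frame with `pair`, `stratum`, `occupancy`, `frames`, plus
#'   the unconditional occupancy in rows with stratum `"all"`.
#' @export
saltbridge_series <- function(traj, pairs, angles, breaks = c(20, 40),
                              cutoff = 5.0) {
  if (nrow(angles) != n_frames(traj))
    stop("angle series length does not match frame count")
  topo <- traj$topology
  keys <- residue_keys(topo)
  resolve <- function(r) {
    idx <- if (is.character(r)) which(keys == r) else which(topo$atoms$resno == r)
    if (!length(idx)) stop("unknown residue: ", r)
    at <- topo$atoms[idx, ]
    sc <- idx[at$elesy %in% c("N", "O") & !(at$elety %in% c("N", "O", "C", "CA"))]
    if (!length(sc)) sc <- idx[at$elesy %in% c("N", "O")]
    if (!length(sc)) stop("residue ", r, " has no N/O atoms for the salt-bridge criterion")
    sc
  }
  strata <- cut(angles$elevation, breaks = c(-Inf, breaks, Inf),
                labels = FALSE, right = FALSE)
  labs <- paste0("stratum", seq_len(length(breaks) + 1))
  out <- NULL
  for (p in pairs) {
    ia <- resolve(p[[1]]); ib <- resolve(p[[2]])
    contact <- logical(n_frames(traj))
    for (i in seq_len(n_frames(traj))) {
      m <- frame_coords(traj, i)
      d2 <- outer(seq_along(ia), seq_along(ib), function(u, v)
        rowSums((m[ia[u], , drop = FALSE] - m[ib[v], , drop = FALSE])^2))
      contact[i] <- min(d2) <= cutoff^2
    }
    pname <- paste(p[[1]], p[[2]], sep = "-")
    for (s in seq_len(length(breaks) + 1)) {
      sel <- strata == s
      out <- rbind(out, data.frame(
        pair = pname, stratum = labs[s],
        occupancy = if (any(sel)) mean(contact[sel]) else NA_real_,
        frames = sum(sel), stringsAsFactors = FALSE))
    }
    out <- rbind(out, data.frame(pair = pname, stratum = "all",
                                 occupancy = mean(contact),
                                 frames = length(contact),
                                 stringsAsFactors = FALSE))
  }
  out
}
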