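# Synthetic hinged-domain trajectory generator. Produces a pseudo-myosin
# (rigid motor blob + helical tail on a hinge + pseudo-ELC + multi-moiety
# pseudo-ligand), a pseudo-actin filament for frame construction, and
# replicate trajectories whose tail angles, contact occupancies, RMSF
# inflation, salt-bridge behaviour and ligand poses are planted with known
# ground truth. Geometry and statistics only - no physics.

#' Synthetic trajectory specification
#'
#' Captures the study conditions a generated ensemble should emulate. The
#' apo condition is broad (mean elevation 23 deg) and the holo condition is
#' narrow and more elevated (mean 33 deg), with azimuth means 34/45 deg,
#' mirroring the reported ligand effect. Tilt is not an independent degree
#' of freedom of a tail direction (it is fixed by elevation and azimuth) and
#' is derived, not sampled.
#'
#' @param condition `"apo"` or `"holo"` (the ligand is present only in holo).
#' @param elevation_mean,elevation_sd,azimuth_mean,azimuth_sd Gaussian
#'   parameters in degrees; defaults depend on `condition`.
#' @param noise_sigma isotropic per-atom thermal noise sd in Angstrom.
#' @param n_frames frames per replicate (default 4000, emulating 400 ns at
#'   100 ps granularity).
#' @param n_replicates number of replicates (default 3).
#' @param timestep ps per frame (default 100).
#' @param seed base random seed; each replicate derives its own stream.
#' @param planted_contacts data.frame with columns `pair` (label),
#'   `occupancy` (target contact occupancy in this condition). Defaults: 4
#'   switch pairs at occupancy 0.8 (apo) / 0.3 (holo).
#' @param rmsf_inflate_resno residue numbers given extra mobility.
#' @param rmsf_inflate_sigma extra per-axis noise sd (Angstrom) on those
#'   residues; default 1.2 in apo, 0 in holo (the apo converter is the more
#'   flexible one).
#' @param saltbridge_break_elevation elevation (deg) above which the planted
#'   hinge salt bridge is broken.
#' @param pose_weights mixture weights over the 4-pose ligand library
#'   (holo only); must sum to 1.
#' @param ar1 lag-1 autocorrelation of the angle series (0 = independent
#'   frames; real MD frames are correlated, so an AR(1) option exists for
#'   statistics testing).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(condition = c("apo", "holo"),
                           elevation_mean = NULL, elevation_sd = NULL,
                           azimuth_mean = NULL, azimuth_sd = NULL,
                           noise_sigma = 0.3, n_frames = 4000,
                           n_replicates = 3, timestep = 100, seed = 1,
                           planted_contacts = NULL,
                           rmsf_inflate_resno = 712:766,
                           rmsf_inflate_sigma = NULL,
                           saltbridge_break_elevation = 30,
                           pose_weights = c(0.4, 0.3, 0.2, 0.1),
                           ar1 = 0) {
  condition <- match.arg(condition)
  defaults <- if (condition == "apo") {
    list(el = 23, el_sd = 6, az = 34, az_sd = 8, infl = 1.2, occ = 0.8)
  } else {
    list(el = 33, el_sd = 3, az = 45, az_sd = 4, infl = 0, occ = 0.3)
  }
  if (is.null(elevation_mean)) elevation_mean <- defaults$el
  if (is.null(elevation_sd)) elevation_sd <- defaults$el_sd
  if (is.null(azimuth_mean)) azimuth_mean <- defaults$az
  if (is.null(azimuth_sd)) azimuth_sd <- defaults$az_sd
  if (is.null(rmsf_inflate_sigma)) rmsf_inflate_sigma <- defaults$infl
  if (is.null(planted_contacts)) {
    planted_contacts <- data.frame(pair = paste0("switch", 1:4),
                                   occupancy = defaults$occ)
  }
  if (any(planted_contacts$occupancy < 0 | planted_contacts$occupancy > 1))
    stop("infeasible planted occupancy (must be in [0, 1])")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (abs(sum(pose_weights) - 1) > 1e-9) stop("pose weights must sum to 1")
  structure(list(condition = condition,
                 elevation_mean = elevation_mean, elevation_sd = elevation_sd,
                 azimuth_mean = azimuth_mean, azimuth_sd = azimuth_sd,
                 noise_sigma = noise_sigma, n_frames = n_frames,
                 n_replicates = n_replicates, timestep = timestep, seed = seed,
                 planted_contacts = planted_contacts,
                 rmsf_inflate_resno = rmsf_inflate_resno,
                 rmsf_inflate_sigma = rmsf_inflate_sigma,
                 saltbridge_break_elevation = saltbridge_break_elevation,
                 pose_weights = pose_weights, ar1 = ar1),
            class = "synthetic_spec")
}

# helical backbone segment: N/CA/C on the helix curve, O radial outward.
# u, r1, r2: orthonormal axis frame; returns an atom table.
helix_residues <- function(origin, u, r1, r2, resnos, chain,
                           rise = 1.5, radius = 2.3, twist = 100) {
  rows <- list()
  curve <- function(t) origin + rise * t * u +
    radius * (cos(deg2rad(twist * t)) * r1 + sin(deg2rad(twist * t)) * r2)
  for (k in seq_along(resnos)) {
    t <- k - 1
    ca <- curve(t); nn <- curve(t - 0.35); cc <- curve(t + 0.35)
    rad <- unit_vec(ca - (origin + rise * t * u))
    oo <- cc + 1.2 * rad
    rows[[k]] <- data.frame(
      chain = chain, resno = resnos[k], insert = "", resid = "ALA",
      elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
      x = c(nn[1], ca[1], cc[1], oo[1]),
      y = c(nn[2], ca[2], cc[2], oo[2]),
      z = c(nn[3], ca[3], cc[3], oo[3]), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# compact quasi-uniform blob of backbone pseudo-residues on a Fibonacci
# sphere around `center`
blob_residues <- function(center, resnos, chain, radius = 18) {
  n <- length(resnos)
  k <- seq_len(n)
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * k / phi
  zfrac <- 1 - 2 * (k - 0.5) / n
  r_shell <- radius * (0.4 + 0.6 * (k %% 7) / 6)   # fill the volume, not a shell
  ca <- cbind(r_shell * sqrt(pmax(0, 1 - zfrac^2)) * cos(theta),
              r_shell * sqrt(pmax(0, 1 - zfrac^2)) * sin(theta),
              r_shell * zfrac)
  ca <- sweep(ca, 2, center, "+")
  rows <- lapply(seq_len(n), function(i) {
    p <- ca[i, ]
    data.frame(chain = chain, resno = resnos[i], insert = "", resid = "ALA",
               elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
               x = p[1] + c(-1.2, 0, 1.2, 1.9),
               y = p[2] + c(0.3, 0, 0.4, 1.4),
               z = p[3] + c(0.2, 0, -0.1, -0.2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# 14-atom three-moiety pseudo-ligand: a 6-carbon central ring and two
# 4-atom terminal groups on opposite ring positions; `rot1`/`rot2` are the
# terminal-group dihedral rotations (deg) about their attachment bonds.
ligand_coords <- function(center, rot1 = 0, rot2 = 0) {
  ang <- deg2rad(seq(0, 300, by = 60))
  ring <- cbind(2.5 * cos(ang), 2.5 * sin(ang), 0)
  arm <- function(base_idx, rot) {
    bond <- unit_vec(ring[base_idx, ])           # outward bond direction
    stem <- ring[base_idx, ] + 1.5 * bond
    local <- rbind(c(1.4, 4.0, 0), c(2.6, 0.9, 3.6), c(1.6, -5.0, -2.7))
    perp1 <- unit_vec(cross3(bond, c(0, 0, 1)))
    perp2 <- cross3(bond, perp1)
    pts <- t(apply(local, 1, function(p)
      stem + p[1] * bond + p[2] * perp1 + p[3] * perp2))
    R <- rotation_about_axis(bond, deg2rad(rot))
    pts <- sweep(sweep(pts, 2, ring[base_idx, ]) %*% R, 2, ring[base_idx, ], "+")
    rbind(stem, pts)
  }
  xyz <- rbind(ring, arm(1, rot1), arm(4, rot2))
  sweep(xyz, 2, center, "+")
}

ligand_atom_table <- function(xyz) {
  elety <- c(paste0("C", 1:6), "C7", "N1", "O1", "C8", "C9", "N2", "O2", "C10")
  elesy <- substr(elety, 1, 1)
  data.frame(chain = "L", resno = 1, insert = "", resid = "OMC",
             elety = elety, elesy = elesy,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
}

#' Build the synthetic hinged pseudo-myosin system
#'
#' Deterministically constructs the canonical (zero-elevation-reference)
#' geometry: a rigid motor blob (residues 550-768), a helical tail
#' (residues 769-810) attached at a hinge, a pseudo-ELC (chain E, residues
#' 39-68) riding on the tail, planted contact-switch residue pairs
#' (900-903 vs 910-913), a hinge salt-bridge pair (920-921), an optional
#' 3-moiety pseudo-ligand in the converter pocket (holo only), and a
#' separate pseudo-actin pentamer whose dominant principal axis defines the
#' thin-filament direction. Residue numbering is compatible with the
#' real-system selections (712-766 converter, 769-771/784-787 tail
#' endpoints).
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_system`: `model` (trajectory topology),
#'   `actin`, `reference` (actin + myosin complex for frame construction),
#'   `frame` (the [build_crossbridge_frame()] of the canonical pose),
#'   selection expressions (`hlh`, `junction`, `ligand`, `actin_sel`,
#'   `anchor_sel`), `hinge`, `u0` (canonical measured tail vector),
#'   `mobile_idx` (tail + ELC atom indices), ligand pose library and moiety
#'   indices, and the planted contact-switch bookkeeping.
#' @export
make_hinged_system <- function(spec) {
  motor <- blob_residues(center = c(47, 0, 0), resnos = 550:768, chain = "A")
  hinge <- c(44, 0, 14)
  # canonical tail built along +z with transverse frame (x, y)
  tail <- helix_residues(hinge, u = c(0, 0, 1), r1 = c(1, 0, 0),
                         r2 = c(0, 1, 0), resnos = 769:810, chain = "A")
  elc <- helix_residues(hinge + c(5.5, 0, 22), u = c(0, 0, 1),
                        r1 = c(1, 0, 0), r2 = c(0, 1, 0),
                        resnos = 39:68, chain = "E", radius = 3.5, twist = 97)
  # contact-switch pairs: fixed partners 910-913, mobile switches 900-903
  switch_rows <- list()
  for (k in 0:3) {
    base <- c(75, 22, -20 + 14 * k)
    fixed <- data.frame(chain = "A", resno = 910 + k, insert = "", resid = "GLY",
                        elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
                        x = base[1] + c(-1.2, 0, 1.2, 1.9),
                        y = base[2] + c(0.3, 0, 0.4, 1.4),
                        z = base[3] + c(0.2, 0, -0.1, -0.2), stringsAsFactors = FALSE)
    mob <- fixed
    mob$resno <- 900 + k
    mob$x <- mob$x + 3.8   # contact position; displaced +8 A when "off"
    switch_rows[[k + 1]] <- rbind(mob, fixed)   # 900-block precedes 910-block
  }
  switches <- do.call(rbind, switch_rows)
  # hinge salt bridge: 921 fixed near the hinge, 920 mobile
  sb_fixed <- data.frame(chain = "A", resno = 921, insert = "", resid = "GLU",
                         elety = c("CA", "OE1", "OE2"), elesy = c("C", "O", "O"),
                         x = hinge[1] + c(-8, -7.2, -8.5),
                         y = hinge[2] + c(6, 6.8, 6.9),
                         z = hinge[3] + c(-2, -1.5, -2.6), stringsAsFactors = FALSE)
  sb_mob <- data.frame(chain = "A", resno = 920, insert = "", resid = "LYS",
                       elety = c("CA", "NZ"), elesy = c("C", "N"),
                       x = sb_fixed$x[2] + c(3.6, 2.8),
                       y = sb_fixed$y[2] + c(0.4, 0.2),
                       z = sb_fixed$z[2] + c(0.5, 1.2), stringsAsFactors = FALSE)
  atoms <- rbind(motor, tail, switches, sb_fixed, sb_mob, elc)
  pocket <- c(38, 7, 2)
  pose_rots <- rbind(c(0, 0), c(180, 90), c(90, 270), c(270, 180))
  poses <- lapply(seq_len(nrow(pose_rots)), function(i)
    ligand_coords(pocket, pose_rots[i, 1], pose_rots[i, 2]))
  if (spec$condition == "holo") atoms <- rbind(atoms, ligand_atom_table(poses[[1]]))
  model <- mol_model(atoms, source = sprintf("synthetic %s system", spec$condition))

  # pseudo-actin pentamer along z (well-defined principal axis)
  act <- list()
  for (s in 0:4) {
    for (a in 0:19) {
      th <- 2 * pi * (a / 20) + s * 0.7
      act[[length(act) + 1]] <- data.frame(
        chain = "F", resno = s * 20 + a + 1, insert = "", resid = "ALA",
        elety = "CA", elesy = "C",
        x = 5 * cos(th), y = 5 * sin(th),
        z = (s - 2) * 30 + (a - 9.5) * 1.3, stringsAsFactors = FALSE)
    }
  }
  actin <- mol_model(do.call(rbind, act), source = "synthetic actin pentamer")
  reference <- mol_model(rbind(actin$atoms, model$atoms),
                         source = "synthetic actomyosin reference")
  actin_sel_expr <- "chain F"
  anchor_sel_expr <- "chain A, residues 550-768"
  frame <- build_crossbridge_frame(reference,
                                   select_atoms(reference, actin_sel_expr),
                                   select_atoms(reference, anchor_sel_expr))
  u0 <- tail_vector(model_coords(model), model)$v
  at <- model$atoms
  mobile_idx <- which((at$chain == "A" & at$resno >= 769 & at$resno <= 810) |
                        at$chain == "E")
  structure(list(model = model, actin = actin, reference = reference,
                 frame = frame, hinge = hinge, u0 = u0,
                 mobile_idx = mobile_idx,
                 hlh = "chain A, residues 550-599, atoms CA",
                 junction = "chain A, residues 704-723, atoms CA",
                 ligand = "chain L, heavy",
                 actin_sel = actin_sel_expr, anchor_sel = anchor_sel_expr,
                 poses = poses,
                 moiety_idx = 1:6,
                 ligand_idx = which(at$chain == "L"),
                 switch_info = list(
                   pairs = paste0("A:", 900:903, "|A:", 910:913),
                   mobile_resno = 900:903, off_shift = c(8, 0, 0)),
                 saltbridge = list(pair = c("A:920", "A:921"), mobile_resno = 920,
                                   off_shift = c(9, 0, 0))),
            class = "synthetic_system")
}

#' Simulate replicate trajectories with planted ground truth
#'
#' Per frame, elevation and azimuth are drawn from the specified Gaussians
#' (optionally AR(1)-correlated); the rigid tail + ELC body is rotated about
#' the hinge by the minimal rotation taking the canonical measured tail
#' vector onto the target direction, so the planted angles are realized
#' exactly in the crossbridge frame; planted contact occupancies are
#' realized by Bernoulli gating of the switch residues; the hinge salt
#' bridge is closed only below the break elevation; the ligand pose is drawn
#' from the pose mixture (holo); isotropic Gaussian noise is then added to
#' every atom, with extra noise on the RMSF-inflated residue ranges. All
#' randomness derives from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param system optionally a prebuilt [make_hinged_system()] for this spec.
#' @return list of class `synthetic_sim`: `trajectories` (list of
#'   [mol_traj()]), `truth` (per-replicate data.frames of planted angles,
#'   pose labels and switch states, plus planted-feature metadata),
#'   `system`, `spec`.
#' @export
simulate_trajectories <- function(spec, system = NULL) {
  if (is.null(system)) system <- make_hinged_system(spec)
  model <- system$model
  base <- model_coords(model)
  n_at <- nrow(base)
  fr <- system$frame
  at <- model$atoms
  inflate_idx <- which(at$resno %in% spec$rmsf_inflate_resno & at$chain == "A")
  sw_mob_idx <- lapply(system$switch_info$mobile_resno,
                       function(r) which(at$resno == r & at$chain == "A"))
  sb_idx <- which(at$resno == system$saltbridge$mobile_resno & at$chain == "A")
  n_pairs <- nrow(spec$planted_contacts)
  trajs <- list(); truth_frames <- list()
  for (r in seq_len(spec$n_replicates)) {
    set.seed(spec$seed + 7919L * r)
    nf <- spec$n_frames
    el <- gaussian_series(nf, spec$elevation_mean, spec$elevation_sd, spec$ar1)
    az <- gaussian_series(nf, spec$azimuth_mean, spec$azimuth_sd, spec$ar1)
    sw_state <- matrix(stats::runif(nf * n_pairs) <
                         rep(spec$planted_contacts$occupancy, each = nf), nf, n_pairs)
    pose_id <- if (spec$condition == "holo") {
      sample.int(length(spec$pose_weights), nf, replace = TRUE,
                 prob = spec$pose_weights)
    } else rep(NA_integer_, nf)
    xyz <- matrix(NA_real_, nf, 3 * n_at)
    tilt <- numeric(nf)
    for (i in seq_len(nf)) {
      co <- base
      v <- sin(deg2rad(el[i])) * fr$e1 +
        cos(deg2rad(el[i])) * (cos(deg2rad(az[i])) * fr$e2 +
                                 sin(deg2rad(az[i])) * fr$e3)
      tilt[i] <- rad2deg(acos(pmin(1, pmax(-1, sum(v * fr$e3)))))
      R <- rotation_between(system$u0, v)
      mob <- system$mobile_idx
      co[mob, ] <- sweep(sweep(co[mob, , drop = FALSE], 2, system$hinge) %*% R,
                         2, system$hinge, "+")
      for (k in seq_len(n_pairs)) {
        if (!sw_state[i, k]) {
          co[sw_mob_idx[[k]], ] <- sweep(co[sw_mob_idx[[k]], , drop = FALSE], 2,
                                         system$switch_info$off_shift, "+")
        }
      }
      if (el[i] >= spec$saltbridge_break_elevation) {
        co[sb_idx, ] <- sweep(co[sb_idx, , drop = FALSE], 2,
                              system$saltbridge$off_shift, "+")
      }
      if (!is.na(pose_id[i])) co[system$ligand_idx, ] <- system$poses[[pose_id[i]]]
      if (spec$noise_sigma > 0) {
        co <- co + matrix(stats::rnorm(3 * n_at, sd = spec$noise_sigma), n_at, 3)
      }
      if (spec$rmsf_inflate_sigma > 0 && length(inflate_idx)) {
        co[inflate_idx, ] <- co[inflate_idx, ] +
          matrix(stats::rnorm(3 * length(inflate_idx),
                              sd = spec$rmsf_inflate_sigma),
                 length(inflate_idx), 3)
      }
      xyz[i, ] <- xyz_flat(co)
    }
    trajs[[r]] <- mol_traj(model, xyz, timestep = spec$timestep,
                           replicate = paste0("run", r),
                           condition = spec$condition)
    tf <- data.frame(frame = seq_len(nf), elevation = el, azimuth = az,
                     tilt = tilt, pose = pose_id)
    for (k in seq_len(n_pairs)) tf[[spec$planted_contacts$pair[k]]] <- sw_state[, k]
    truth_frames[[r]] <- tf
  }
  structure(list(trajectories = trajs,
                 truth = list(frames = truth_frames,
                              planted_pairs = system$switch_info$pairs,
                              planted_occupancy = spec$planted_contacts$occupancy,
                              rmsf_inflate_resno = spec$rmsf_inflate_resno,
                              saltbridge = list(
                                pair = system$saltbridge$pair,
                                break_elevation = spec$saltbridge_break_elevation),
                              pose_weights = spec$pose_weights,
                              seed = spec$seed),
                 system = system, spec = spec),
            class = "synthetic_sim")
}

gaussian_series <- function(n, mean, sd, ar1 = 0) {
  if (sd == 0) return(rep(mean, n))
  if (ar1 == 0) return(stats::rnorm(n, mean, sd))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - ar1^2))
  for (i in 2:n) x[i] <- ar1 * x[i - 1] + innov[i - 1]
  mean + x
}

#' Planted-feature accessors for a synthetic simulation
#'
#' Returns the ground-truth record of a [simulate_trajectories()] output,
#' after checking that the outputs belong to the given spec - the oracle
#' for every recovery test.
#'
#' @param spec the [synthetic_spec()] used for the simulation.
#' @param sim the [simulate_trajectories()] result.
#' @return the `truth` list (per-frame angles and switch states per
#'   replicate, planted pairs and occupancies, inflated ranges, salt-bridge
#'   break point, pose weights).
#' @export
synthetic_truth <- function(spec, sim) {
  if (!inherits(sim, "synthetic_sim")) stop("sim must come from simulate_trajectories()")
  if (!identical(sim$spec[names(sim$spec)], spec[names(spec)]))
    stop("spec does not match the one that produced these outputs")
  if (length(sim$trajectories) != spec$n_replicates)
    stop("outputs do not match spec: replicate count differs")
  sim$truth
}
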