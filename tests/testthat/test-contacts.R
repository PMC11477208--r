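# Heavy-atom contact criterion, grid vs brute-force equivalence, occupancy
# tables, differential contacts and salt-bridge stratification.

two_atom_model <- function(gap) {
  toy_model(rbind(c(0, 0, 0), c(gap, 0, 0)), resno = 1:2)
}

test_that("the 5 A criterion is boundary-inclusive", {
  m <- two_atom_model(4.99)
  sel <- select_atoms(m, "calpha")
  expect_equal(nrow(frame_contacts(model_coords(m), m, sel, sel)), 1)
  m2 <- two_atom_model(5.01)
  sel2 <- select_atoms(m2, "calpha")
  expect_equal(nrow(frame_contacts(model_coords(m2), m2, sel2, sel2)), 0)
  m3 <- two_atom_model(5.0)
  sel3 <- select_atoms(m3, "calpha")
  expect_equal(nrow(frame_contacts(model_coords(m3), m3, sel3, sel3)), 1)
  expect_error(frame_contacts(model_coords(m), m, sel[0], sel), "empty")
})

test_that("grid-accelerated detection equals brute force on random configurations", {
  set.seed(17)
  for (i in 1:40) {
    n <- 200
    xyz <- matrix(runif(n * 3, 0, 30), n, 3)
    rank <- sample(1:40, n, replace = TRUE)   # 40 pseudo-residues
    got <- sort(leverarm:::frame_contact_codes(xyz, 1:n, 1:n, rank, 5.0))
    want <- brute_pair_codes(xyz, xyz, rank, rank, 5.0)
    expect_identical(got, want)
  }
})

test_that("occupancy counts frames in contact and respects the stride", {
  # residue pair within cutoff in exactly 40% of frames
  m <- two_atom_model(3)
  base <- model_coords(m)
  xyz <- t(vapply(1:10, function(f) {
    co <- base
    if (f > 4) co[2, 1] <- 20    # break contact in frames 5..10
    leverarm:::xyz_flat(co)
  }, numeric(6)))
  traj <- mol_traj(m, xyz, timestep = 100)
  tab <- residue_contact_tables(traj, stride_ps = 100)
  expect_equal(tab$occupancy, 0.4)
  expect_equal(tab$frames, 10)
  expect_error(residue_contact_tables(traj, stride_ps = 1e6), "stride")
  # permanently close pair has occupancy 1
  static <- mol_traj(m, rbind(leverarm:::xyz_flat(base), leverarm:::xyz_flat(base)),
                     timestep = 100)
  expect_equal(residue_contact_tables(static)$occupancy, 1)
})

test_that("contacts are invariant under global rigid motion of every frame", {
  set.seed(23)
  m <- toy_peptide(1:20)
  base <- model_coords(m)
  R <- leverarm:::rotation_about_axis(rnorm(3), 1.1)
  rot <- base %*% R + matrix(rep(c(10, -4, 2), each = nrow(base)), nrow(base), 3)
  t1 <- mol_traj(m, leverarm:::xyz_flat(base), timestep = 100)
  t2 <- mol_traj(m, leverarm:::xyz_flat(rot), timestep = 100)
  tab1 <- residue_contact_tables(t1)
  tab2 <- residue_contact_tables(t2)
  expect_equal(tab1[, c("res_i", "res_j", "occupancy")],
               tab2[, c("res_i", "res_j", "occupancy")])
  # pair count matches brute-force enumeration on the same frame
  sel <- leverarm:::protein_heavy_sel(m)
  keys <- leverarm:::residue_keys(m)
  rank <- match(keys, unique(keys))
  want <- brute_pair_codes(base[as.integer(sel), ], base[as.integer(sel), ],
                           rank[as.integer(sel)], rank[as.integer(sel)], 5.0)
  expect_equal(nrow(tab1), length(want))
})

test_that("ligand occupancy averages replicates, drops sub-threshold residues", {
  # one ligand residue, two protein residues; contact patterns differ
  at <- rbind(
    data.frame(chain = "A", resno = 1, insert = "", resid = "ALA",
               elety = "CA", elesy = "C", x = 0, y = 0, z = 0),
    data.frame(chain = "A", resno = 2, insert = "", resid = "ALA",
               elety = "CA", elesy = "C", x = 20, y = 0, z = 0),
    data.frame(chain = "L", resno = 9, insert = "", resid = "OMC",
               elety = "C1", elesy = "C", x = 3, y = 0, z = 0))
  m <- mol_model(at)
  lig <- select_atoms(m, "chain L")
  base <- model_coords(m)
  mk <- function(contact_frames, n = 25) {
    xyz <- t(vapply(seq_len(n), function(f) {
      co <- base
      if (!(f %in% contact_frames)) co[3, 1] <- 50
      leverarm:::xyz_flat(co)
    }, numeric(9)))
    mol_traj(m, xyz, timestep = 100, condition = "holo")
  }
  # replicate occupancies 0.2, 0.08, 0.04 -> average > 5% keeps residue 1
  occ <- ligand_occupancy(list(mk(1:5), mk(1:2), mk(1)), lig)
  expect_equal(occ$table$residue, "A:1")
  expect_equal(occ$table$avg, mean(c(0.2, 0.08, 0.04)), tolerance = 1e-12)
  expect_equal(occ$table$tier, 3)
  # all replicates at 4% -> excluded entirely
  expect_error(suppressWarnings(
    ligand_occupancy(list(mk(1), mk(1), mk(1)), lig)), NA)
  low <- ligand_occupancy(list(mk(1), mk(1), mk(1)), lig)
  expect_equal(nrow(low$table), 0)
  expect_error(ligand_occupancy(list(mk(1)), lig[0]), "empty")
})

test_that("novel contacts are classified against the reference pose", {
  sp <- synthetic_spec("holo", n_frames = 40, n_replicates = 2, seed = 41)
  sim <- simulate_trajectories(sp)
  topo <- sim$trajectories[[1]]$topology
  lig <- select_atoms(topo, "chain L, heavy")
  occ <- ligand_occupancy(sim$trajectories, lig, xray = topo,
                          xray_ligand_sel = lig)
  expect_true(!is.null(occ$xray_contacts))
  expect_true(all(c("novel", "tier") %in% names(occ$table)))
  # reference-pose contacts found in MD are not novel
  seen <- occ$table$residue %in% occ$xray_contacts
  expect_false(any(occ$table$novel[seen]))
})

test_that("differential contacts flag planted pairs and nest across thresholds", {
  mk_tab <- function(occ) {
    data.frame(res_i = paste0("A:", seq_along(occ)), res_j = "A:99",
               occupancy = occ, frames = 100, replicate = "r", condition = "c",
               stringsAsFactors = FALSE)
  }
  apo <- lapply(list(c(1, 0.5, 0.3), c(1, 0.52, 0.31), c(1, 0.48, 0.29)), mk_tab)
  holo <- lapply(list(c(0, 0.5, 0.1), c(0, 0.53, 0.11), c(0, 0.47, 0.09)), mk_tab)
  dc <- differential_contacts(apo, holo)
  expect_equal(dc$res_i[dc$delta == 1], "A:1")
  expect_equal(dc$dominant[dc$res_i == "A:1"], "apo")
  expect_false("A:2" %in% dc$res_i)       # identical occupancies: not flagged
  # monotone nesting of thresholds
  key <- function(x) paste(x$res_i, x$res_j)
  d05 <- differential_contacts(apo, holo, delta_threshold = 0.05)
  d10 <- differential_contacts(apo, holo, delta_threshold = 0.10)
  d20 <- differential_contacts(apo, holo, delta_threshold = 0.20)
  expect_true(all(key(d20) %in% key(d10)))
  expect_true(all(key(d10) %in% key(d05)))
})

test_that("generator-planted differential pairs are recovered end to end", {
  spa <- synthetic_spec("apo", n_frames = 100, seed = 11)
  sph <- synthetic_spec("holo", n_frames = 100, seed = 12)
  sa <- simulate_trajectories(spa)
  sh <- simulate_trajectories(sph)
  ta <- lapply(sa$trajectories, residue_contact_tables)
  th <- lapply(sh$trajectories, residue_contact_tables)
  dc <- differential_contacts(ta, th)
  found <- paste(dc$res_i, dc$res_j, sep = "|")
  expect_true(all(sa$truth$planted_pairs %in% found))
  planted <- dc[found %in% sa$truth$planted_pairs, ]
  expect_equal(planted$delta, rep(0.5, 4), tolerance = 0.15)
  expect_equal(planted$dominant, rep("apo", 4))
})

test_that("salt-bridge occupancy stratifies by elevation and recombines", {
  sp <- synthetic_spec("apo", n_frames = 150, n_replicates = 1, seed = 21)
  sim <- simulate_trajectories(sp)
  tr <- sim$trajectories[[1]]
  ats <- angle_timeseries(superpose_to_reference(
    tr, select_atoms(tr$topology, sim$system$hlh),
    sim$system$reference, select_atoms(sim$system$reference, sim$system$hlh)),
    sim$system$frame)
  # measure away from the breakpoint: frames within +-3 degrees of it can be
  # assigned either way through measurement noise, so they get a buffer stratum
  br <- sim$spec$saltbridge_break_elevation
  sb <- saltbridge_series(tr, list(sim$system$saltbridge$pair), ats,
                          breaks = c(br - 3, br + 3))
  below <- sb[sb$stratum == "stratum1", ]
  above <- sb[sb$stratum == "stratum3", ]
  overall <- sb[sb$stratum == "all", ]
  expect_gt(below$occupancy, 0.97)       # closed below the break elevation
  expect_lt(above$occupancy, 0.03)       # open above it
  # law of total probability: strata recombine to the global occupancy
  strata <- sb[sb$stratum != "all", ]
  expect_equal(sum(strata$occupancy * strata$frames) / overall$frames,
               overall$occupancy, tolerance = 1e-12)
  expect_error(saltbridge_series(tr, list(c("A:1", "A:920")), ats), "unknown")
})
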