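# Kabsch superposition against a quaternion oracle, average structures,
# LOVO planted-core recovery, and RMSD/RMSF closed forms.

test_that("kabsch superposition removes exact rigid motions", {
  set.seed(1)
  A <- matrix(rnorm(18), 6, 3)
  f0 <- kabsch_superpose(A, A)
  expect_equal(f0$R, diag(3), tolerance = 1e-12)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  R0 <- leverarm:::rotation_about_axis(c(0, 0, 1), pi / 2)
  B <- A %*% R0 + matrix(rep(c(3, -1, 2), each = 6), 6, 3)
  f <- kabsch_superpose(A, B)
  expect_equal(f$R, R0, tolerance = 1e-9)
  expect_equal(f$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_fit(A, f), B, tolerance = 1e-9)
})

test_that("kabsch RMSD matches the quaternion-eigenvalue oracle on random clouds", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    A <- matrix(rnorm(3 * n, sd = 5), n, 3)
    B <- matrix(rnorm(3 * n, sd = 5), n, 3)
    f <- kabsch_superpose(A, B)
    expect_lt(abs(f$rmsd - quat_rmsd(A, B)), 1e-9)
    expect_equal(det(f$R), 1, tolerance = 1e-9)  # proper rotation, never a reflection
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("average structures are per-atom means and linear", {
  m <- toy_model(cbind(c(-2, 1), 0, 0), resno = 1:2)
  xyz <- rbind(c(-3, 0, 0, 1, 0, 0), c(3, 0, 0, 1, 0, 0))
  traj <- mol_traj(m, xyz, timestep = 1)
  avg <- average_structure(traj)
  expect_equal(model_coords(avg)[1, ], c(0, 0, 0))
  one <- mol_traj(m, xyz[1, , drop = FALSE], timestep = 1)
  expect_equal(model_coords(average_structure(one)),
               leverarm:::as_xyz_matrix(xyz[1, ]))
  scaled <- mol_traj(m, 2.5 * xyz, timestep = 1)
  expect_equal(model_coords(average_structure(scaled)),
               2.5 * model_coords(avg))
})

make_planted_core_traj <- function(n_core = 60, n_noisy = 40, n_frames = 20,
                                   noise_sd = 3, seed = 3) {
  set.seed(seed)
  n <- n_core + n_noisy
  base <- matrix(rnorm(n * 3, sd = 10), n, 3)
  topo <- toy_model(base, resno = seq_len(n))
  xyz <- matrix(NA_real_, n_frames, 3 * n)
  for (f in seq_len(n_frames)) {
    co <- base
    co[(n_core + 1):n, ] <- co[(n_core + 1):n, ] +
      matrix(rnorm(n_noisy * 3, sd = noise_sd), n_noisy, 3)
    R <- leverarm:::rotation_about_axis(rnorm(3), runif(1, 0, pi))
    co <- co %*% R + matrix(rep(rnorm(3, sd = 5), each = n), n, 3)
    xyz[f, ] <- leverarm:::xyz_flat(co)
  }
  list(traj = mol_traj(topo, xyz, timestep = 100), core = seq_len(n_core))
}

test_that("LOVO recovers a planted rigid core exactly", {
  pc <- make_planted_core_traj()
  lv <- lovo_fit(pc$traj, fraction = 0.6)
  expect_true(lv$converged)
  expect_identical(sort(as.integer(lv$subset)), pc$core)
  expect_lt(mean(lv$subset_rmsd), 0.01)
})

test_that("LOVO subset RMSD is non-decreasing in the fraction phi", {
  pc <- make_planted_core_traj(n_frames = 15)
  ms <- vapply(c(0.3, 0.5, 0.6, 0.8, 1.0),
               function(phi) mean(lovo_fit(pc$traj, phi)$subset_rmsd),
               numeric(1))
  expect_true(all(diff(ms) >= -1e-9))
})

test_that("LOVO at phi = 1 reduces to plain iterative align-to-average", {
  pc <- make_planted_core_traj(n_core = 30, n_noisy = 10, n_frames = 10)
  lv <- lovo_fit(pc$traj, fraction = 1.0)
  expect_length(lv$subset, 40)
  # plain iterative align-to-average on all atoms, written out directly
  tr <- pc$traj
  sel <- select_atoms(tr$topology, "calpha")
  avg_prev <- NULL
  for (i in 1:50) {
    avg <- matrix(colMeans(tr$xyz), ncol = 3, byrow = TRUE)
    tr <- superpose_frames(tr, sel, avg)
    avg_new <- matrix(colMeans(tr$xyz), ncol = 3, byrow = TRUE)
    if (!is.null(avg_prev) &&
        mean(sqrt(rowSums((avg_new - avg_prev)^2))) < 1e-6) break
    avg_prev <- avg_new
  }
  avg <- matrix(colMeans(tr$xyz), ncol = 3, byrow = TRUE)
  direct <- mean(sqrt(rowMeans(sweep(tr$xyz, 2, leverarm:::xyz_flat(avg))^2 * 3)))
  expect_equal(mean(lv$subset_rmsd), direct, tolerance = 1e-4)
})

test_that("LOVO beats random subsets of the same size", {
  pc <- make_planted_core_traj(n_frames = 12, seed = 9)
  lv <- lovo_fit(pc$traj, fraction = 0.35)
  k <- length(lv$subset)
  set.seed(11)
  for (i in 1:30) {
    rnd <- sort(sample(100, k))
    tr <- pc$traj
    for (it in 1:3) {
      avg <- matrix(colMeans(tr$xyz), ncol = 3, byrow = TRUE)
      tr <- superpose_frames(tr, leverarm:::new_atom_sel(rnd),
                             avg[rnd, , drop = FALSE])
    }
    avg <- matrix(colMeans(tr$xyz), ncol = 3, byrow = TRUE)
    cols <- as.vector(rbind(3 * rnd - 2, 3 * rnd - 1, 3 * rnd))
    rnd_rmsd <- mean(sqrt(rowMeans(sweep(tr$xyz[, cols], 2,
                                         leverarm:::xyz_flat(avg[rnd, ]))^2 * 3)))
    expect_lte(mean(lv$subset_rmsd), rnd_rmsd + 1e-9)
  }
})

test_that("rmsd_series honours independent align and measure masks", {
  set.seed(5)
  base <- matrix(rnorm(30, sd = 6), 10, 3)
  topo <- toy_model(base, resno = 1:10)
  # frames identical to the reference -> zero for any mask pair
  traj0 <- mol_traj(topo, rbind(leverarm:::xyz_flat(base),
                                leverarm:::xyz_flat(base)), timestep = 1)
  s_all <- select_atoms(topo, "residues 1-10, atoms CA")
  expect_equal(max(rmsd_series(traj0, s_all, s_all, topo)), 0, tolerance = 1e-12)
  # displace one atom by 3 A; align on the others, measure only it
  co <- base; co[10, ] <- co[10, ] + c(3, 0, 0)
  traj1 <- mol_traj(topo, leverarm:::xyz_flat(co), timestep = 1)
  s_align <- select_atoms(topo, "residues 1-9, atoms CA")
  s_meas <- select_atoms(topo, "residues 10, atoms CA")
  expect_equal(as.numeric(rmsd_series(traj1, s_align, s_meas, topo)), 3,
               tolerance = 1e-9)
})

test_that("rmsd_series equals the brute-force superpose-then-measure oracle", {
  set.seed(8)
  base <- matrix(rnorm(24, sd = 5), 8, 3)
  topo <- toy_model(base, resno = 1:8)
  traj <- rigid_traj(topo, 6, noise = 0.8, seed = 13)
  a_idx <- 1:5; m_idx <- c(2, 6, 7, 8)
  sa <- leverarm:::new_atom_sel(a_idx); sm <- leverarm:::new_atom_sel(m_idx)
  got <- rmsd_series(traj, sa, sm, topo)
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    fit <- kabsch_superpose(m[a_idx, ], base[a_idx, ])
    moved <- apply_fit(m, fit)
    want <- sqrt(mean(rowSums((moved[m_idx, ] - base[m_idx, ])^2)))
    expect_equal(got[f], want, tolerance = 1e-9)
  }
  # align == measure reduces to classic aligned RMSD
  classic <- vapply(seq_len(n_frames(traj)), function(f)
    kabsch_superpose(frame_coords(traj, f)[a_idx, ], base[a_idx, ])$rmsd,
    numeric(1))
  expect_equal(as.numeric(rmsd_series(traj, sa, sa, topo)), classic,
               tolerance = 1e-9)
})

test_that("RMSF closed forms hold", {
  m <- toy_model(cbind(0, 0, 0), resno = 1)
  static <- mol_traj(m, matrix(0, 4, 3), timestep = 1)
  expect_equal(rmsf_profile(static)$rmsf, 0)
  # atom alternating between +a and -a along x with equal occupancy -> RMSF a
  a <- 1.7
  alt <- mol_traj(m, rbind(c(a, 0, 0), c(-a, 0, 0), c(a, 0, 0), c(-a, 0, 0)),
                  timestep = 1)
  expect_equal(rmsf_profile(alt)$rmsf, a, tolerance = 1e-12)
  expect_warning(rmsf_profile(mol_traj(m, matrix(0, 1, 3), timestep = 1)),
                 "single frame")
})

test_that("isotropic Gaussian jitter gives RMSF = sigma * sqrt(3)", {
  set.seed(21)
  sigma <- 0.5
  n_frames <- 4000
  m <- toy_model(matrix(rnorm(15), 5, 3), resno = 1:5)
  base <- leverarm:::xyz_flat(model_coords(m))
  xyz <- matrix(rep(base, each = n_frames), n_frames, 15) +
    matrix(rnorm(n_frames * 15, sd = sigma), n_frames, 15)
  prof <- rmsf_profile(mol_traj(m, xyz, timestep = 1))
  expect_equal(mean(prof$rmsf), sigma * sqrt(3), tolerance = 0.03)
})
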