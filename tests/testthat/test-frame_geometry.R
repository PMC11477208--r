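# Crossbridge frame construction, superposition to a reference complex,
# tail vectors, angle conventions and probability densities.

pseudo_actin <- function() {
  # helical pseudo-filament along z; four full turns with no duplicated
  # endpoint, so the centroid lies on the axis to machine precision
  th <- seq(0, 8 * pi, length.out = 61)[-61]
  toy_model(cbind(7 * cos(th), 7 * sin(th), seq(-60, 60, length.out = 60)),
            resno = 1:60, chain = "F")
}

test_that("crossbridge frame axes follow the filament and anchor geometry", {
  act <- pseudo_actin()
  anchor <- toy_model(cbind(40, 0.5, 3), resno = 999, chain = "A")
  ref <- mol_model(rbind(act$atoms, anchor$atoms))
  fr <- build_crossbridge_frame(ref, select_atoms(ref, "chain F"),
                                select_atoms(ref, "chain A"))
  # e2 matches an independent principal-axis computation on the same points
  pc <- prcomp(model_coords(act))$rotation[, 1]
  expect_equal(abs(sum(fr$e2 * pc)), 1, tolerance = 1e-9)
  expect_gt(fr$e2[3], 0.99)        # oriented first -> last actin atom (+z)
  expect_gt(sum(fr$e1 * c(1, 0, 0)), 0.99)
  # orthonormal right-handed triad
  G <- cbind(fr$e1, fr$e2, fr$e3)
  expect_equal(crossprod(G), diag(3), tolerance = 1e-9)
  expect_equal(det(G), 1, tolerance = 1e-9)
})

test_that("degenerate actin or anchor geometry is rejected", {
  same <- toy_model(matrix(1, 4, 3), resno = 1:4, chain = "F")
  anchor <- toy_model(cbind(40, 0, 0), resno = 9, chain = "A")
  ref <- mol_model(rbind(same$atoms, anchor$atoms))
  expect_error(build_crossbridge_frame(ref, select_atoms(ref, "chain F"),
                                       select_atoms(ref, "chain A")),
               "degenerate")
  # anchor exactly on the e2 line through the origin
  act <- pseudo_actin()
  probe <- toy_model(cbind(40, 0, 0), resno = 9, chain = "A")
  ref_ok <- mol_model(rbind(act$atoms, probe$atoms))
  fr_ok <- build_crossbridge_frame(ref_ok, select_atoms(ref_ok, "chain F"),
                                   select_atoms(ref_ok, "chain A"))
  on_axis_pt <- fr_ok$origin + 50 * fr_ok$e2
  on_axis <- toy_model(matrix(on_axis_pt, 1, 3), resno = 9, chain = "A")
  ref2 <- mol_model(rbind(act$atoms, on_axis$atoms))
  expect_error(build_crossbridge_frame(ref2, select_atoms(ref2, "chain F"),
                                       select_atoms(ref2, "chain A")),
               "anchor")
})

test_that("superpose_to_reference removes rigid motions and preserves geometry", {
  m <- toy_peptide(1:12)
  sel <- select_atoms(m, "residues 1-6, atoms CA")
  base <- model_coords(m)
  R <- leverarm:::rotation_about_axis(c(0, 0, 1), pi / 2)
  moved <- base %*% R + matrix(rep(c(5, -2, 1), each = nrow(base)), nrow(base), 3)
  traj <- mol_traj(m, rbind(leverarm:::xyz_flat(base), leverarm:::xyz_flat(moved)),
                   timestep = 1)
  out <- superpose_to_reference(traj, sel, m, sel)
  expect_equal(attr(out, "fit_rmsd"), c(0, 0), tolerance = 1e-9)
  # internal geometry unchanged: all pairwise distances preserved
  d_before <- dist(moved)
  d_after <- dist(frame_coords(out, 2))
  expect_equal(as.numeric(d_after), as.numeric(d_before), tolerance = 1e-9)
  expect_error(superpose_to_reference(traj, sel, m,
                                      select_atoms(m, "residues 1-3, atoms CA")),
               "length mismatch")
})

test_that("tail vector is the unit centroid-to-centroid direction", {
  m <- toy_peptide(c(769:771, 784:787))
  co <- model_coords(m)
  at <- m$atoms
  prox <- at$resno %in% 769:771 & at$elety %in% c("N", "CA", "C")
  dist_g <- at$resno %in% 784:787 & at$elety %in% c("N", "CA", "C")
  p0 <- colMeans(co[prox, ])
  # distal backbone centroid exactly 10 A above the proximal centroid
  nk <- sum(dist_g)
  ring <- 0.5 * cbind(cos(2 * pi * seq_len(nk) / nk),
                      sin(2 * pi * seq_len(nk) / nk), 0)
  co[dist_g, ] <- matrix(rep(p0 + c(0, 0, 10), each = nk), nk, 3) + ring
  tv <- tail_vector(co, m)
  expect_equal(tv$v, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(tv$proximal, p0, tolerance = 1e-12)
  # missing atoms are named
  m2 <- toy_peptide(c(769:771, 784:786))
  expect_error(tail_vector(model_coords(m2), m2), "787")
  # coincident endpoints
  co2 <- model_coords(m)
  co2[dist_g, ] <- matrix(rep(p0, each = nk), nk, 3)
  expect_error(tail_vector(co2, m), "zero-length")
})

test_that("angle conventions match the axis-aligned cases", {
  fr <- random_frame(4)
  a1 <- compute_tail_angles(fr$e1, fr)
  expect_equal(a1$elevation, 90, tolerance = 1e-9)
  expect_equal(a1$tilt, 90, tolerance = 1e-6)
  expect_equal(a1$azimuth, 0)       # degenerate convention
  expect_true(a1$degenerate)
  a2 <- compute_tail_angles(fr$e2, fr)
  expect_equal(c(a2$elevation, a2$azimuth, a2$tilt), c(0, 0, 90), tolerance = 1e-6)
  a3 <- compute_tail_angles(-fr$e3, fr)
  expect_equal(c(a3$elevation, a3$azimuth, a3$tilt), c(0, -90, 180), tolerance = 1e-6)
  expect_error(compute_tail_angles(c(0, 0, 0), fr), "zero")
})

test_that("angles are invariant under a global rigid transform of frame and vector", {
  fr <- random_frame(7)
  set.seed(7)
  for (i in 1:20) {
    v <- leverarm:::unit_vec(rnorm(3))
    a <- compute_tail_angles(v, fr)
    R <- leverarm:::rotation_about_axis(rnorm(3), runif(1, 0, 2 * pi))
    fr2 <- fr
    fr2$e1 <- as.numeric(fr$e1 %*% R); fr2$e2 <- as.numeric(fr$e2 %*% R)
    fr2$e3 <- as.numeric(fr$e3 %*% R)
    b <- compute_tail_angles(as.numeric(v %*% R), fr2)
    expect_equal(unlist(a[1:3]), unlist(b[1:3]), tolerance = 1e-8)
    # reflection through the e2-e3 plane negates the elevation
    v_ref <- v - 2 * sum(v * fr$e1) * fr$e1
    expect_equal(compute_tail_angles(v_ref, fr)$elevation, -a$elevation,
                 tolerance = 1e-8)
    # antipodal tilt sums to 180
    expect_equal(a$tilt + compute_tail_angles(-v, fr)$tilt, 180, tolerance = 1e-8)
  }
})

test_that("angle densities are normalised histograms", {
  d <- angle_density(rep(35.0, 100), width = 2)
  expect_equal(sum(d$density > 0), 1)
  expect_equal(max(d$density), 0.5)   # one occupied 2-degree bin
  expect_equal(sum(d$density * d$width), 1, tolerance = 1e-9)
  set.seed(2)
  u <- runif(50000, 0, 10)
  du <- angle_density(u, width = 2)
  expect_equal(length(du$density), 5)
  expect_equal(du$density, rep(0.1, 5), tolerance = 0.01)
  expect_equal(sum(du$density * du$width), 1, tolerance = 1e-9)
  # 2D density integrates to one
  d2 <- angle_density(rnorm(2000, 30, 5), width = 2, samples2 = rnorm(2000, 45, 4))
  expect_equal(sum(d2$density) * 4, 1, tolerance = 1e-9)
  expect_true(all(d2$density >= 0))
  expect_error(angle_density(numeric(0)), "no samples")
  expect_error(angle_density(1:3, width = 0), "width")
})

test_that("angle series moments are order-invariant and exact at zero noise", {
  sp <- synthetic_spec("holo", elevation_sd = 0, azimuth_sd = 0,
                       noise_sigma = 0, n_frames = 5, n_replicates = 1,
                       rmsf_inflate_sigma = 0)
  sim <- simulate_trajectories(sp)
  tr <- sim$trajectories[[1]]
  ats <- angle_timeseries(tr, sim$system$frame)
  expect_equal(ats$elevation, rep(33, 5), tolerance = 1e-9)
  expect_equal(ats$azimuth, rep(45, 5), tolerance = 1e-9)
  expect_equal(sd(ats$elevation), 0, tolerance = 1e-9)
  rev_tr <- tr
  rev_tr$xyz <- tr$xyz[5:1, , drop = FALSE]
  rats <- angle_timeseries(rev_tr, sim$system$frame)
  s1 <- attr(ats, "summary"); s2 <- attr(rats, "summary")
  expect_equal(s1$mean, s2$mean, tolerance = 1e-12)
  expect_equal(s1$sd, s2$sd, tolerance = 1e-12)
})
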