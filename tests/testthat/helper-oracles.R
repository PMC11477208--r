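# Independent oracles and small fixture builders used across the suite.
# Every oracle here is implemented from first principles, independently of
# the package's own code paths.

# --- quaternion (Horn) superposition oracle ---------------------------
# Minimal RMSD of A onto B via the eigenvalue of the 4x4 quaternion matrix;
# no rotation matrix construction, fully independent of the SVD route.
quat_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# --- brute-force close-pair oracle ------------------------------------
# all-pairs atom distances; returns sorted unique residue-pair codes
brute_pair_codes <- function(xyzA, xyzB, rankA, rankB, cutoff) {
  codes <- numeric(0)
  for (i in seq_len(nrow(xyzA))) {
    d2 <- (xyzB[, 1] - xyzA[i, 1])^2 + (xyzB[, 2] - xyzA[i, 2])^2 +
      (xyzB[, 3] - xyzA[i, 3])^2
    js <- which(d2 <= cutoff^2)
    if (length(js)) {
      ra <- rankA[i]; rb <- rankB[js]
      keep <- rb != ra
      if (any(keep)) {
        lo <- pmin(ra, rb[keep]); hi <- pmax(ra, rb[keep])
        codes <- c(codes, lo * 1e6 + hi)
      }
    }
  }
  sort(unique(codes))
}

# --- textbook average-linkage + exhaustive KGS penalty ----------------
# Merge sequence by direct Lance-Williams average linkage on the matrix;
# returns the list of partitions (one per number of clusters n-1 .. 1).
avg_linkage_partitions <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  dm <- d
  diag(dm) <- Inf
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  assign_of <- function() {
    cl <- integer(n)
    g <- 0
    for (k in which(active)) { g <- g + 1; cl[members[[k]]] <- g }
    cl
  }
  parts <- list()
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); bd <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && dm[a, b] < bd) { bd <- dm[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (k in idx) {
      if (k != a && k != b) {
        dm[a, k] <- dm[k, a] <-
          (sizes[a] * dm[a, k] + sizes[b] * dm[b, k]) / (sizes[a] + sizes[b])
      }
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
    dm[b, ] <- Inf; dm[, b] <- Inf
    parts[[step]] <- assign_of()
  }
  parts
}

# KGS penalty evaluated from scratch for an arbitrary list of partitions
kgs_best_partition <- function(d, parts) {
  n <- nrow(d)
  spread_of <- function(cl) {
    gs <- unique(cl)
    sps <- c()
    for (g in gs) {
      idx <- which(cl == g)
      if (length(idx) > 1) {
        sps <- c(sps, mean(d[idx, idx][upper.tri(diag(length(idx)))]))
      }
    }
    if (!length(sps)) NA_real_ else mean(sps)
  }
  sp <- vapply(parts, spread_of, numeric(1))
  ks <- vapply(parts, function(cl) length(unique(cl)), numeric(1))
  ok <- !is.na(sp)
  rng <- range(sp[ok])
  norm <- rep(1, length(sp))
  if (diff(rng) > 0) norm[ok] <- 1 + (n - 2) * (sp[ok] - rng[1]) / diff(rng)
  pen <- norm + ks
  best <- which(pen == min(pen))
  best <- best[which.min(ks[best])]
  parts[[best]]
}

# partitions agree up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# --- small fixture builders -------------------------------------------
toy_model <- function(coords, resno = seq_len(nrow(coords)), chain = "A",
                      elety = "CA", elesy = "C", resid = "ALA") {
  mol_model(data.frame(chain = chain, resno = resno, insert = "",
                       resid = resid, elety = elety, elesy = elesy,
                       x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       stringsAsFactors = FALSE))
}

# a complete pseudo-peptide with N/CA/C/O for the given residue numbers
toy_peptide <- function(resnos, chain = "A", spacing = 3.8) {
  rows <- lapply(seq_along(resnos), function(i) {
    p <- c(spacing * i, 0.5 * (i %% 3), 0.3 * (i %% 5))
    data.frame(chain = chain, resno = resnos[i], insert = "", resid = "ALA",
               elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
               x = p[1] + c(-1.1, 0, 1.1, 1.8), y = p[2] + c(0.2, 0, 0.3, 1.2),
               z = p[3] + c(0.1, 0, -0.1, -0.3), stringsAsFactors = FALSE)
  })
  mol_model(do.call(rbind, rows))
}

# trajectory of rigid-motion copies of a model plus optional per-atom noise
rigid_traj <- function(model, n_frames, noise = 0, seed = 1) {
  set.seed(seed)
  base <- model_coords(model)
  n <- nrow(base)
  xyz <- matrix(NA_real_, n_frames, 3 * n)
  for (f in seq_len(n_frames)) {
    R <- leverarm:::rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, pi))
    co <- base %*% R + matrix(rep(stats::rnorm(3, sd = 4), each = n), n, 3)
    if (noise > 0) co <- co + matrix(stats::rnorm(3 * n, sd = noise), n, 3)
    xyz[f, ] <- leverarm:::xyz_flat(co)
  }
  mol_traj(model, xyz, timestep = 100)
}

# orthonormal right-handed random frame for angle-convention tests
random_frame <- function(seed = 1) {
  set.seed(seed)
  e1 <- leverarm:::unit_vec(stats::rnorm(3))
  tmp <- stats::rnorm(3)
  e2 <- leverarm:::unit_vec(tmp - sum(tmp * e1) * e1)
  e3 <- leverarm:::cross3(e1, e2)
  structure(list(origin = c(0, 0, 0), e1 = e1, e2 = e2, e3 = e3),
            class = "crossbridge_frame")
}
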