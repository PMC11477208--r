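# Ligand conformer clustering: pose RMSD after central-moiety alignment,
# average-linkage agglomeration, and the Kelley-Gardner-Sutcliffe penalty
# cut for picking the number of clusters.

#' Pairwise pose RMSD matrix after central-moiety alignment
#'
#' Each pose is superposed onto the reference pose using only the atoms of
#' the conformationally homogeneous central moiety; the all-atom RMSD
#' between every pair of moiety-aligned poses is then computed (no further
#' fitting), so the matrix reflects the motion of the terminal groups
#' relative to the fixed core.
#'
#' @param poses list of N x 3 coordinate matrices (one per pose, common atom
#'   order), or an F x 3N xyz matrix.
#' @param moiety_idx indices (into pose atoms) of the central moiety;
#'   at least 3 atoms.
#' @param reference index of the pose all others are aligned to (default 1).
#' @return symmetric matrix of RMSDs (Angstrom) with zero diagonal.
#' @export
pose_rmsd_matrix <- function(poses, moiety_idx, reference = 1) {
  if (is.matrix(poses) && ncol(poses) %% 3 == 0 && !is.list(poses))
    poses <- lapply(seq_len(nrow(poses)), function(i)
      matrix(poses[i, ], ncol = 3, byrow = TRUE))
  n <- length(poses)
  if (n < 2) stop("need at least 2 poses")
  moiety_idx <- as.integer(moiety_idx)
  if (length(moiety_idx) < 3) stop("central moiety must have at least 3 atoms")
  ref <- as_xyz_matrix(poses[[reference]])
  aligned <- lapply(poses, function(p) {
    p <- as_xyz_matrix(p)
    fit <- kabsch_superpose(p[moiety_idx, , drop = FALSE],
                            ref[moiety_idx, , drop = FALSE])
    apply_fit(p, fit)
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- rmsd_between(aligned[[i]], aligned[[j]])
    }
  }
  d
}

#' Penalty-cut average-linkage conformer clustering
#'
#' Agglomerative average-linkage clustering of a pose distance matrix with
#' the cut level chosen by the Kelley-Gardner-Sutcliffe penalty: at each
#' merge level the average intra-cluster spread (mean pairwise distance of
#' clusters with more than one member) is normalised across levels onto
#' \[1, N-1\] and added to the number of clusters; the partition minimising
#' this penalty is returned. The procedure is deterministic given the
#' matrix and invariant under uniform scaling of the distances.
#'
#' @param dist symmetric non-negative distance matrix (or `dist` object).
#' @return object of class `conformer_clusters`: `assignment` (cluster id
#'   per conformer, ids ranked 1 = most populous), `representatives`
#'   (medoid conformer index per cluster), `populations` (fractions summing
#'   to 1), `penalty` (data.frame of level, n_clusters, spread, normalised
#'   spread, penalty), `n_clusters`.
#' @export
nmrclust <- function(dist) {
  d <- if (inherits(dist, "dist")) as.matrix(dist) else as.matrix(dist)
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) || any(d < 0))
    stop("distance matrix must be symmetric and non-negative")
  if (n < 2) {
    warning("fewer than 2 conformers: trivial single cluster")
    return(structure(list(assignment = rep(1L, n), representatives = seq_len(n),
                          populations = rep(1, n), penalty = NULL,
                          n_clusters = n),
                     class = "conformer_clusters"))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # candidate partitions: after merge s there are n - s clusters (s = 1..n-1)
  ks <- (n - 1):1
  spread <- numeric(length(ks))
  parts <- vector("list", length(ks))
  for (s in seq_along(ks)) {
    cl <- stats::cutree(hc, k = ks[s])
    parts[[s]] <- cl
    sizes <- table(cl)
    multi <- as.integer(names(sizes)[sizes > 1])
    if (!length(multi)) { spread[s] <- NA_real_; next }
    sps <- vapply(multi, function(g) {
      idx <- which(cl == g)
      mean(d[idx, idx][upper.tri(diag(length(idx)))])
    }, numeric(1))
    spread[s] <- mean(sps)
  }
  ok <- !is.na(spread)
  rng <- range(spread[ok])
  norm <- rep(1, length(ks))
  if (diff(rng) > 0)
    norm[ok] <- 1 + (n - 2) * (spread[ok] - rng[1]) / diff(rng)
  penalty <- norm + ks
  penalty[!ok] <- norm[!ok] + ks[!ok]   # all-singleton levels: spread treated as minimal
  best <- which(penalty == min(penalty))
  best <- best[which.min(ks[best])]     # tie -> fewer clusters
  cl <- parts[[best]]
  # rank cluster ids by population (ties: lower original id first)
  sizes <- table(cl)
  rank_map <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                              names(sizes))
  assignment <- as.integer(rank_map[as.character(cl)])
  reps <- vapply(seq_len(max(assignment)), function(g) {
    idx <- which(assignment == g)
    if (length(idx) == 1) return(idx)
    idx[which.min(rowMeans(d[idx, idx, drop = FALSE]))]
  }, integer(1))
  structure(list(assignment = assignment,
                 representatives = reps,
                 populations = as.numeric(table(assignment)) / n,
                 penalty = data.frame(n_clusters = ks, spread = spread,
                                      normalised = norm, penalty = penalty),
                 n_clusters = max(assignment)),
            class = "conformer_clusters")
}

#' @export
print.conformer_clusters <- function(x, ...) {
  cat(sprintf("<conformer_clusters> %d conformers in %d clusters\n",
              length(x$assignment), x$n_clusters))
  cat("  populations:", paste(sprintf("%.2f", x$populations), collapse = " "), "\n")
  invisible(x)
}

#' Ranked cluster report
#'
#' Clusters ranked by population with the cumulative population fraction of
#' the top `k` reported (the share of all conformers they account for).
#'
#' @param result a [nmrclust()] result.
#' @param top_k number of leading clusters to report (clamped, with a
#'   warning, to the number of clusters).
#' @return list with `table` (cluster, population count, fraction,
#'   cumulative fraction, representative) and `cumulative_top_k`.
#' @export
cluster_report <- function(result, top_k = 4) {
  k <- result$n_clusters
  if (top_k > k) {
    warning("top_k exceeds number of clusters; clamping to ", k)
    top_k <- k
  }
  counts <- as.integer(table(result$assignment))
  tab <- data.frame(cluster = seq_len(k), count = counts,
                    fraction = result$populations,
                    cumulative = cumsum(result$populations),
                    representative = result$representatives)
  list(table = tab, cumulative_top_k = tab$cumulative[top_k])
}
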