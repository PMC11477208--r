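# Replicate-level statistics: pooled two-tailed Student's t-tests, RMSD
# summary tables over align/measure mask modes, and per-residue RMSF
# difference maps with significance flags.

#' Pooled two-tailed Student's t-test
#'
#' Classic pooled-variance Student's t with `df = nA + nB - 2` and a
#' two-tailed p-value from the t distribution. Replicate time-averages are
#' the intended observations, so groups are small; Welch's correction is
#' deliberately not applied. Degenerate convention: zero pooled variance
#' gives p = 1 when the means are equal and p = 0 otherwise.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return list with `t`, `p`, `df`.
#' @export
students_t_two_tailed <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (abs(dm) < .Machine$double.eps^0.5) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(dm) * Inf, p = 0, df = df))
  }
  tstat <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df), df = df)
}

#' RMSD summary table over mask modes
#'
#' Builds the replicate-as-observation summary: one row per align/measure
#' mask mode, per-replicate time-averaged RMSDs, condition averages, and a
#' pooled two-tailed Student's t p-value comparing the apo and holo
#' replicate averages.
#'
#' @param apo,holo named lists, one element per mask mode; each element is a
#'   numeric vector of per-replicate time-averaged RMSDs (Angstrom). The two
#'   lists must share mode names, with >= 2 replicates per condition.
#' @return data.frame with one row per mode: replicate columns, `apo_avg`,
#'   `holo_avg`, `p`.
#' @export
rmsd_summary_table <- function(apo, holo) {
  modes <- names(apo)
  if (!identical(sort(modes), sort(names(holo))))
    stop("apo and holo mode sets differ")
  rows <- lapply(modes, function(m) {
    a <- apo[[m]]; h <- holo[[m]]
    if (length(a) < 2 || length(h) < 2) stop("missing replicate in mode ", m)
    tt <- students_t_two_tailed(a, h)
    cbind(data.frame(mode = m),
          stats::setNames(as.data.frame(t(a)), paste0("apo_", seq_along(a))),
          data.frame(apo_avg = mean(a)),
          stats::setNames(as.data.frame(t(h)), paste0("holo_", seq_along(h))),
          data.frame(holo_avg = mean(h), p = tt$p))
  })
  do.call(rbind, rows)
}

#' Per-residue RMSF difference map
#'
#' Compares apo and holo per-residue C-alpha RMSF profiles across replicates.
#' For each residue, Delta = mean(apo) - mean(holo) (positive = more flexible
#' without ligand) and a pooled two-tailed Student's t-test over the
#' per-replicate RMSF values; residues with p < alpha are flagged. An
#' optional Benjamini-Hochberg correction across residues can be switched on
#' (off by default: raw per-residue p-values are the reported convention).
#'
#' @param apo,holo lists of [rmsf_profile()] data.frames (one per replicate
#'   and at least 2 each) sharing a common residue set.
#' @param alpha significance level for the flag.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `chain`, `resno`, `insert`, `rmsf_apo`, `rmsf_holo`,
#'   `delta`, `p`, `significant`.
#' @export
rmsf_difference_map <- function(apo, holo, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(apo) < 2 || length(holo) < 2)
    stop("need at least 2 replicates per condition")
  key_of <- function(p) paste0(p$chain, ":", p$resno, p$insert)
  keys <- key_of(apo[[1]])
  for (p in c(apo, holo)) {
    if (!identical(key_of(p), keys)) {
      sym <- c(setdiff(key_of(p), keys), setdiff(keys, key_of(p)))
      stop("residue sets differ between profiles: ",
           paste(utils::head(sym, 10), collapse = ", "))
    }
  }
  amat <- sapply(apo, `[[`, "rmsf")   # residues x replicates
  hmat <- sapply(holo, `[[`, "rmsf")
  n <- nrow(amat)
  pv <- numeric(n); tv <- numeric(n)
  for (i in seq_len(n)) {
    tt <- students_t_two_tailed(amat[i, ], hmat[i, ])
    pv[i] <- tt$p; tv[i] <- tt$t
  }
  p_use <- if (adjust == "BH") stats::p.adjust(pv, "BH") else pv
  out <- data.frame(chain = apo[[1]]$chain, resno = apo[[1]]$resno,
                    insert = apo[[1]]$insert,
                    rmsf_apo = rowMeans(amat), rmsf_holo = rowMeans(hmat),
                    delta = rowMeans(amat) - rowMeans(hmat),
                    p = p_use, significant = p_use < alpha,
                    stringsAsFactors = FALSE)
  out
}
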