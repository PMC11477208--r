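# Orchestration: one configuration object and one driver that runs the
# full stage sequence (equilibration discard -> LOVO -> RMSD table -> RMSF
# difference map -> crossbridge frame + angles + densities -> contacts +
# differentials -> ligand occupancy + clustering -> morph) and writes
# CSV/JSON/PDB outputs plus a reproducibility manifest.

#' Analysis run configuration
#'
#' Collects every tunable of the pipeline with defaults matching the
#' canonical protocol: discard 100 ns of equilibration, analyse at 10 ps
#' granularity, contacts at 100 ps, LOVO fraction 0.35, 5 A contact cutoff,
#' alpha 0.05, 10% occupancy difference threshold, 2 deg angle bins, and
#' twenty 5 deg morph bins.
#'
#' @param output_dir directory for outputs (created if missing).
#' @param seed integer seed for every stochastic stage.
#' @param mode `"synthetic"` (generate the shipped scenario) or `"files"`
#'   (read trajectories from `inputs`).
#' @param inputs for `mode = "files"`: list with `topology_apo`,
#'   `topology_holo`, `reference`, `apo`, `holo` (character vectors of
#'   multi-model PDB paths, one per replicate), `timestep_ps`.
#' @param discard_ns equilibration discard (ns); applied in `"files"` mode.
#' @param analysis_stride_ps,contact_stride_ps analysis granularities (ps).
#' @param lovo_fraction LOVO subset fraction phi.
#' @param cutoff contact distance criterion (Angstrom).
#' @param alpha significance level.
#' @param delta_threshold differential-contact occupancy difference.
#' @param angle_bin_width 1D/2D angle bin width (degrees).
#' @param morph_bin_width,morph_bins elevation binning for morphs.
#' @param morph_steps interpolation steps per transition.
#' @param hlh,junction,ligand,tail_proximal,tail_distal,actin,anchor
#'   selection expressions / residue vectors; defaults follow the synthetic
#'   system and the canonical residue numbering.
#' @param n_frames,n_replicates synthetic-scenario size overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("leverarm_run_"), seed = 1,
                       mode = c("synthetic", "files"), inputs = NULL,
                       discard_ns = 100, analysis_stride_ps = 10,
                       contact_stride_ps = 100, lovo_fraction = 0.35,
                       cutoff = 5.0, alpha = 0.05, delta_threshold = 0.10,
                       angle_bin_width = 2, morph_bin_width = 5,
                       morph_bins = 20, morph_steps = 5,
                       hlh = "chain A, residues 550-599, atoms CA",
                       junction = "chain A, residues 704-723, atoms CA",
                       ligand = "chain L, heavy",
                       tail_proximal = 769:771, tail_distal = 784:787,
                       actin = "chain F", anchor = "chain A, residues 550-768",
                       n_frames = 400, n_replicates = 3) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(inputs))
    stop("mode 'files' requires an inputs list")
  structure(as.list(environment()), class = "run_config")
}

load_condition <- function(config, condition) {
  if (config$mode == "synthetic") {
    spec <- synthetic_spec(condition, n_frames = config$n_frames,
                           n_replicates = config$n_replicates,
                           seed = config$seed + if (condition == "holo") 5000L else 0L)
    simulate_trajectories(spec)
  } else {
    topo_path <- config$inputs[[paste0("topology_", condition)]]
    topo <- read_structure(topo_path, heavy_only = FALSE)
    paths <- config$inputs[[condition]]
    trajs <- lapply(seq_along(paths), function(r) {
      tr <- read_trajectory(paths[r], topo,
                            timestep = config$inputs$timestep_ps,
                            replicate = paste0("run", r), condition = condition)
      discard_equilibration(tr, config$discard_ns)
    })
    list(trajectories = trajs, system = NULL, spec = NULL, truth = NULL)
  }
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage against the configured inputs and writes a report
#' bundle: RMSD summary table, RMSF profiles and difference map, tail-angle
#' series and densities, contact occupancy tables and differential
#' contacts, ligand occupancy and conformer clusters (holo), an elevation
#' morph trajectory, and a JSON manifest. A stage failure aborts with the
#' stage name; partial outputs are kept next to a `FAILED` marker.
#'
#' @param config a [run_config()].
#' @return invisible list with the in-memory stage results and the manifest.
#' @export
run_full_analysis <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outdir <- config$output_dir
  stage <- "preflight"
  manifest <- list(seed = config$seed, mode = config$mode,
                   package_version = as.character(utils::packageVersion("leverarm")),
                   outputs = character(0))
  result <- list()
  on_fail <- function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    apo <- load_condition(config, "apo")
    holo <- load_condition(config, "holo")
    topo_apo <- apo$trajectories[[1]]$topology
    # pre-flight: every selection must resolve before any stage runs
    for (expr in c(config$hlh, config$junction)) {
      s <- select_atoms(topo_apo, expr)
      if (!length(s)) stop("unresolvable selection: ", expr)
    }
    lig_sel <- select_atoms(holo$trajectories[[1]]$topology, config$ligand)
    if (!length(lig_sel)) stop("unresolvable selection: ", config$ligand)

    stage <- "lovo"
    ca_apo <- select_atoms(topo_apo, "calpha")
    lv <- lapply(c(apo$trajectories, holo$trajectories), function(tr)
      lovo_fit(tr, fraction = config$lovo_fraction, calpha_sel = ca_apo))
    result$lovo <- lv
    subset_sel <- lv[[1]]$subset

    stage <- "rmsd_table"
    ref_apo <- set_model_coords(topo_apo, frame_coords(apo$trajectories[[1]], 1))
    mean_rmsd <- function(trs, align, measure) vapply(trs, function(tr)
      attr(rmsd_series(tr, align, measure, ref_apo), "mean"), numeric(1))
    modes_a <- list(all_ca = mean_rmsd(apo$trajectories, ca_apo, ca_apo),
                    lovo_subset = mean_rmsd(apo$trajectories, subset_sel, subset_sel),
                    lovo_all = mean_rmsd(apo$trajectories, subset_sel, ca_apo))
    modes_h <- list(all_ca = mean_rmsd(holo$trajectories, ca_apo, ca_apo),
                    lovo_subset = mean_rmsd(holo$trajectories, subset_sel, subset_sel),
                    lovo_all = mean_rmsd(holo$trajectories, subset_sel, ca_apo))
    result$rmsd_table <- rmsd_summary_table(modes_a, modes_h)
    manifest$outputs <- c(manifest$outputs,
                          write_stage_csv(result$rmsd_table, outdir, "rmsd_table.csv"))

    stage <- "rmsf"
    prof <- function(lvfit) rmsf_profile(lvfit$traj)
    apo_prof <- lapply(lv[seq_along(apo$trajectories)], prof)
    holo_prof <- lapply(lv[length(apo$trajectories) + seq_along(holo$trajectories)], prof)
    result$rmsf_map <- rmsf_difference_map(apo_prof, holo_prof, alpha = config$alpha)
    manifest$outputs <- c(manifest$outputs,
                          write_stage_csv(result$rmsf_map, outdir, "rmsf_difference.csv"))

    stage <- "angles"
    ref_complex <- if (config$mode == "synthetic") apo$system$reference else
      read_structure(config$inputs$reference)
    frame <- build_crossbridge_frame(ref_complex,
                                     select_atoms(ref_complex, config$actin),
                                     select_atoms(ref_complex, config$anchor))
    ref_sel <- select_atoms(ref_complex, config$hlh)
    angle_tabs <- lapply(c(apo$trajectories, holo$trajectories), function(tr) {
      tr2 <- superpose_to_reference(tr, select_atoms(tr$topology, config$hlh),
                                    ref_complex, ref_sel)
      angle_timeseries(tr2, frame, proximal = config$tail_proximal,
                       distal = config$tail_distal)
    })
    result$angles <- do.call(rbind, angle_tabs)
    manifest$outputs <- c(manifest$outputs,
                          write_stage_csv(result$angles, outdir, "tail_angles.csv"))
    for (cond in c("apo", "holo")) {
      el <- result$angles$elevation[result$angles$condition == cond]
      dens <- angle_density(el, width = config$angle_bin_width)
      df <- data.frame(left_edge = dens$edges[-length(dens$edges)],
                       density = dens$density)
      manifest$outputs <- c(manifest$outputs,
                            write_stage_csv(df, outdir,
                                            paste0("elevation_density_", cond, ".csv")))
    }

    stage <- "contacts"
    ct <- function(trs) lapply(trs, residue_contact_tables,
                               stride_ps = config$contact_stride_ps,
                               cutoff = config$cutoff)
    apo_tabs <- ct(apo$trajectories); holo_tabs <- ct(holo$trajectories)
    result$differential <- differential_contacts(apo_tabs, holo_tabs,
                                                 alpha = config$alpha,
                                                 delta_threshold = config$delta_threshold)
    manifest$outputs <- c(manifest$outputs,
                          write_stage_csv(result$differential, outdir,
                                          "differential_contacts.csv"))

    stage <- "ligand"
    occ <- ligand_occupancy(holo$trajectories, lig_sel, cutoff = config$cutoff)
    result$ligand_occupancy <- occ$table
    manifest$outputs <- c(manifest$outputs,
                          write_stage_csv(occ$table, outdir, "ligand_occupancy.csv"))

    stage <- "cluster"
    tr1 <- holo$trajectories[[1]]
    take <- seq(1, n_frames(tr1), length.out = min(100, n_frames(tr1)))
    poses <- lapply(unique(round(take)), function(i)
      frame_coords(tr1, i)[as.integer(lig_sel), , drop = FALSE])
    moiety <- seq_len(6)  # central ring atoms lead the ligand selection
    dmat <- pose_rmsd_matrix(poses, moiety)
    result$clusters <- nmrclust(dmat)
    rep_tab <- cluster_report(result$clusters,
                              top_k = min(4, result$clusters$n_clusters))
    manifest$outputs <- c(manifest$outputs,
                          write_stage_csv(rep_tab$table, outdir, "ligand_clusters.csv"))

    stage <- "morph"
    apo_angles1 <- angle_tabs[[1]]
    binned <- bin_by_elevation(apo$trajectories[[1]], apo_angles1,
                               select_atoms(topo_apo, config$junction),
                               width = config$morph_bin_width,
                               n_bins = config$morph_bins)
    if (sum(binned$counts > 0) >= 2) {
      morph <- interpolate_morph(binned, config$morph_steps)
      mp <- file.path(outdir, "elevation_morph.pdb")
      write_trajectory(morph, mp)
      manifest$outputs <- c(manifest$outputs, mp)
      result$morph_frames <- n_frames(morph)
    }

    stage <- "manifest"
    cfg <- config
    cfg$inputs <- NULL
    manifest$config <- cfg[setdiff(names(cfg), c("output_dir"))]
    if (config$mode == "synthetic") {
      jsonlite::write_json(apo$truth[c("planted_pairs", "planted_occupancy",
                                       "rmsf_inflate_resno")],
                           file.path(outdir, "truth.json"), auto_unbox = TRUE)
      manifest$outputs <- c(manifest$outputs, file.path(outdir, "truth.json"))
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }, error = on_fail)
  invisible(result)
}
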