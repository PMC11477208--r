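Package: leverarm
Title: Crossbridge-Centric Analysis of Myosin Lever-Arm Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lever-arm orientation dynamics of beta-cardiac myosin
    from molecular dynamics trajectories and the effects of the myotrope
    omecamtiv mecarbil. Builds a crossbridge-centric coordinate system from a
    weakly-bound actomyosin reference geometry and measures tail
    elevation/azimuth/tilt angles and their probability densities; performs
    rigid-body (Kabsch) superposition, iterative least-mobile-subset (LOVO)
    trajectory alignment, and RMSD/RMSF computation with independent
    align/measure masks; computes replicate-wise fluctuation statistics with
    two-tailed Student's t-tests; detects heavy-atom residue-residue and
    ligand-protein contacts with occupancy and differential apo/holo
    comparison; clusters ligand conformers with an average-linkage
    penalty-cut (NMRclust-style) procedure; and generates synthetic
    hinged-domain trajectories with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
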