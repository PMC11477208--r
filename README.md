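# leverarm

Crossbridge-centric analysis of myosin lever-arm orientation dynamics from
molecular dynamics trajectories.

## The problem

In the pre-powerstroke (M.ADP.Pi) state of β-cardiac myosin, the lever arm
(tail) is "primed": its orientation relative to the motor domain sets both
the geometry of the eventual powerstroke and the disposition of heads in
the sarcomere. Myosin-targeted small molecules such as omecamtiv mecarbil
(OM) bind a pocket at the converter/N-terminal-domain junction and
modulate these dynamics. Quantifying that modulation from MD requires
more than global RMSD: it needs a physically meaningful angular coordinate
system, an alignment strategy that is not frustrated by the swinging tail,
and replicate-aware statistics for fluctuations and contacts.

`leverarm` implements that tool chain for structural biologists working
with trajectories of myosin–ELC (essential light chain) constructs:

* **Crossbridge frame** — axes built from a weakly-bound actomyosin
  reference: the origin at the actin-pentamer center of mass, axis 2
  (`e2`) along the thin filament (dominant principal axis of the actin
  coordinates), axis 1 (`e1`) the interfilament direction, and
  `e3 = e1 × e2`. The tail direction **v** (centroid-to-centroid vector of
  the backbone N/CA/C atoms of residues 769–771 → 784–787) is summarised
  by the triple
  * elevation = 90° − ∠(v, e1),
  * azimuth = atan2(v·e3, v·e2),
  * tilt = ∠(v, e3),

  with probability densities on 2° (and 2°×2°) bins.
* **LOVO alignment** — iterative low-order-value optimisation that finds
  the fraction φ (default 0.35) of Cα atoms with the smallest time-averaged
  deviation from the evolving average structure, separating the rigid core
  from mobile subdomains; RMSD series support independent align/measure
  masks and RMSF profiles are computed per replicate.
* **Replicate statistics** — pooled two-tailed Student's t-tests with
  replicate time-averages as the observations, per-residue RMSF difference
  maps, and Table-style RMSD summaries.
* **Contacts** — the 5 Å heavy-atom criterion on residue–residue and
  ligand–residue pairs (grid-accelerated, exactly equal to brute force),
  occupancy tables at 100 ps granularity, differential apo/holo contacts
  (p ≤ 0.05 and ≥ 10% occupancy difference by default), and salt-bridge
  occupancy stratified by lever-arm elevation.
* **Conformer clustering** — ligand poses aligned on the central moiety
  and clustered by average linkage with the Kelley–Gardner–Sutcliffe
  penalty cut (NMRclust-style).
* **Morphs** — elevation-binned coordinate averages (twenty 5° bins) and
  linear morphs between them, written as multi-model PDB.
* **Synthetic generator** — a hinged pseudo-myosin system with planted
  ground truth (tail angle distributions, differential contacts, RMSF
  inflation, a breaking salt bridge, a multi-moiety ligand pose mixture)
  so every stage is testable without archived trajectories.

All I/O is standard PDB / multi-model PDB (via bio3d) plus CSV/JSON
exports.

## Worked example

```r
library(leverarm)

# simulate three apo and three holo replicates of the hinged test system
apo  <- simulate_trajectories(synthetic_spec("apo",  n_frames = 300, seed = 1))
holo <- simulate_trajectories(synthetic_spec("holo", n_frames = 300, seed = 2))

# measure tail angles in the crossbridge frame
frame <- apo$system$frame
angles <- function(sim) do.call(rbind, lapply(sim$trajectories,
  angle_timeseries, frame = frame))
a <- angles(apo); h <- angles(holo)
cat(sprintf("mean elevation: apo %.1f deg (sd %.1f), holo %.1f deg (sd %.1f)\n",
            mean(a$elevation), sd(a$elevation),
            mean(h$elevation), sd(h$elevation)))
#> mean elevation: apo 23.1 deg (sd 5.8), holo 32.9 deg (sd 3.1)

# differential residue-residue contacts (5 A, p <= 0.05, |delta| >= 10%)
dc <- differential_contacts(
  lapply(apo$trajectories,  residue_contact_tables),
  lapply(holo$trajectories, residue_contact_tables))
head(dc[dc$res_i %in% paste0("A:", 900:903), ], 4)
#>    res_i res_j   occ_apo  occ_holo     delta            p dominant
#> 38 A:900 A:910 0.8088889 0.3044444 0.5044444 1.108979e-04      apo
#> 39 A:901 A:911 0.8011111 0.2977778 0.5033333 1.535887e-06      apo
#> 46 A:902 A:912 0.7855556 0.2966667 0.4888889 3.488622e-06      apo
#> 54 A:903 A:913 0.7933333 0.3233333 0.4700000 2.357065e-05      apo
```

The ligand narrows and raises the lever-arm elevation distribution
(holo 33° vs apo 23°, with roughly half the spread), and the four contact
pairs planted at an occupancy difference of 0.5 are recovered with the
correct sign and magnitude. `run_full_analysis(run_config(...))` chains
every stage (LOVO fit → RMSD table → RMSF difference map → angles and
densities → contacts and differentials → ligand occupancy and clustering →
morph) and writes CSV/JSON/PDB outputs plus a manifest.

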