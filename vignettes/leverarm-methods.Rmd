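---
title: "Methods: crossbridge-centric lever-arm analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossbridge-centric lever-arm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leverarm)
```

This vignette records the models, conventions and numerical choices behind
`leverarm`, in the spirit of a lab notebook for the package's maintainers
and reviewers.

## The coordinate system and angle conventions

The orientation of the myosin lever arm is measured in a *crossbridge
frame* anchored to a weakly-bound actomyosin reference geometry rather
than to the myosin motor itself, because sarcomere-level questions (where
does the head point relative to the filaments?) are about the crossbridge,
not the motor's internal axes.

Construction (`build_crossbridge_frame()`):

* **origin** — mass-weighted center of the actin selection (standard
  atomic masses; unknown elements fall back to carbon, which only matters
  for exotic atoms and shifts centers negligibly);
* **e2** — dominant principal axis of the actin coordinates (left singular
  direction of the centered coordinate matrix). A principal axis has no
  intrinsic sign, so `e2` is oriented from the first to the last selected
  actin atom by default (`e2_direction` accepts an explicit hint vector);
  which end of the filament counts as "up" is a convention the caller
  fixes once per study;
* **e1** — the component of (anchor center − origin) orthogonal to `e2`,
  normalized. The anchor is the myosin body in the reference-aligned pose,
  making `e1` the interfilament direction;
* **e3 = e1 × e2**, which yields a right-handed triad
  (`det[e1 e2 e3] = +1`).

The tail direction `v` is the unit vector between backbone (N, CA, C)
centroids of a proximal (default residues 769–771) and a distal (default
784–787) residue group — a deliberate simplification of "a line through
the tail": a two-centroid vector is exactly rigid-motion covariant and
needs no least-squares line fit. Only the N-terminal tail segment up to
the ELC binding site is used because the more distal tail can curve.

Angles (`compute_tail_angles()`):

* elevation `= 90° − ∠(v, e1)` ∈ [−90°, 90°]: signed rise out of the
  `e2`–`e3` plane toward `+e1`;
* azimuth `= atan2(v·e3, v·e2)` ∈ (−180°, 180°]: position about `e1`
  measured from `+e2` toward `+e3`;
* tilt `= ∠(v, e3)` ∈ [0°, 180°].

Two consequences of defining all three angles from the *same* unit vector
deserve emphasis:

1. **Tilt is not an independent degree of freedom.** A unit vector has two
   degrees of freedom, so `cos(tilt) = cos(elevation)·sin(azimuth)`
   identically. Angle triples whose tilt violates this identity cannot be
   realized by any tail vector; reported tilt values from other tools that
   do not satisfy it must be using a second, roll-like direction that a
   single tail vector cannot carry. The synthetic generator therefore
   samples elevation and azimuth and *derives* tilt; its truth record
   stores the derived value.
2. **Degeneracy at |elevation| = 90°**: the azimuth is undefined when `v`
   is parallel to `e1`; it is reported as 0 with a `degenerate` flag.

Angle statistics use ordinary (non-circular) means and standard
deviations. Observed lever-arm ranges sit tens of degrees away from the
±180° wrap, where circular and linear moments agree to well below the
reported precision; this is a documented limitation, not an oversight.

Probability densities (`angle_density()`) are normalized histograms:
`sum(density × binwidth) = 1` (and `× area` in 2D), with 2° bins by
default and edges anchored at `width · floor(min/width)`. Bins are
left-closed, right-open.

## Superposition and LOVO alignment

`kabsch_superpose()` is the standard SVD solution of the orthogonal
Procrustes problem with the determinant correction that forbids
reflections. It is validated in the test suite against an independent
quaternion-eigenvalue implementation (agreement ≤ 1e−9 Å on 1000 random
instances), keeping the two routes fully separate.

`lovo_fit()` implements low-order-value optimisation for trajectory
alignment: starting from all Cα atoms, iterate (align every frame on the
current subset to the current average structure) → (recompute the
average) → (rank atoms by time-averaged RMS deviation) → (keep the
`round(φN)` least mobile). Numerical choices:

* **initial subset** — all Cα atoms; the initial reference is the plain
  coordinate average of the unaligned frames;
* **convergence** — subset membership fixed point *and* average-structure
  drift below `tol` (default 1e−6 Å mean per-atom displacement). Requiring
  both makes the φ = 1 case identical to classic iterative
  align-to-average rather than stopping after one pass;
* **tie-break** at the subset boundary: lower atom index wins
  (deterministic);
* **non-convergence** at `max_iter` is flagged on the result, not an
  error, since a useful alignment usually exists anyway;
* the default fraction φ = 0.35 reflects the common practice of aligning
  on roughly the least-mobile third of Cα atoms; the subset found is a
  local optimum (each iteration is a descent step), which is what the
  planted-core recovery tests exercise.

`rmsd_series()` separates the align mask from the measure mask because
the scientifically interesting question is often "how much does X move
when aligned on Y". `rmsf_profile()` computes
`sqrt(mean_t |r_i(t) − ⟨r_i⟩|²)` on a pre-aligned trajectory and does not
re-fit, so the caller controls the alignment that defines "fluctuation".

## Replicate statistics

Replicate time-averages — not per-frame values — are the statistical
units everywhere: frames within a replicate are strongly autocorrelated,
while replicates are independent. Tests are pooled-variance two-tailed
Student's t (`students_t_two_tailed()`), not Welch, matching the
convention for n = 3 replicate designs; with two groups of three, the
pooled test is also the more powerful and the variances are generated by
the same protocol. Degenerate inputs follow a documented convention:
zero pooled variance yields p = 1 for equal means and p = 0 otherwise.

No multiple-testing correction is applied across residues or contact
pairs by default — the reported quantities are raw p < α counts, mirroring
the descriptive use of such maps — but `rmsf_difference_map()` exposes a
Benjamini–Hochberg switch. With tight replicate spreads the per-residue
test will flag tiny systematic differences; the RMSF difference *map*
(Δ values) is therefore the interpretable object, with the flags as a
screen.

## Contacts

Two residues are in contact when any heavy-atom pair is within 5.0 Å,
boundary inclusive ("within 5 Å" is read as ≤). Detection uses an
axis-aligned cell list with cell edge = cutoff, compared atom pairs only
from the 27 neighbouring cells; this is exact (no cutoff approximation)
and the suite verifies equality with brute force on hundreds of random
configurations. Sequence-adjacent pairs are *not* excluded: the criterion
is purely geometric and any exclusion would be a modelling decision the
caller can make downstream. Solvent and ions are excluded by the default
protein selection.

Ligand occupancy uses the same criterion between ligand heavy atoms and
residue heavy atoms; interactions below 5% replicate-averaged occupancy
are dropped; contacts absent from a supplied experimental pose are
classified "novel", and each contact's persistence tier counts the
replicates in which it appears. Differential contacts union the pair sets
across replicates (absent = occupancy 0), test 3-vs-3 occupancies, and
report pairs passing both p ≤ α and |Δ| ≥ the occupancy-difference
threshold (0.05/0.10/0.20 supported; the outputs nest monotonically).
Salt bridges are the same distance criterion restricted to side-chain N/O
atoms of the partner residues (falling back to all N/O atoms for reduced
synthetic residues), stratified over user-defined elevation bands.

## Conformer clustering

Ligand poses are superposed on the conformationally homogeneous central
moiety of a reference pose and compared by all-heavy-atom RMSD without
re-fitting, so the matrix measures terminal-group rearrangement relative
to a fixed core. All-heavy-atom (rather than ring-only) RMSD is used
because it weights every moiety's motion and requires no per-ligand
annotation. The merge sequence is average-linkage agglomeration
(delegated to `stats::hclust`; tie handling therefore follows `hclust`,
which is immaterial on continuous RMSD matrices), and the cut level
minimises the Kelley–Gardner–Sutcliffe penalty: the average intra-cluster
spread (mean pairwise distance over clusters with ≥ 2 members),
normalised across cut levels onto [1, N−1], plus the number of clusters.
Penalty ties resolve toward fewer clusters. When every spread is equal
the normalisation is degenerate and defined as 1, which collapses
uniformly tiny matrices into a single cluster — the intuitive answer.
Representatives are medoids (minimal mean distance to co-members);
"population share" of a cluster is its fraction of poses, the only
variance-like quantity computable from a partition alone.

## Elevation binning and morphs

Frames are re-aligned on the motor-domain–lever-arm junction (default
residues 704–723; a required, configurable input) before per-bin
averaging so that bin averages live in a common frame. The grid is twenty
5° bins anchored at `5°·floor(min/5°)` — anchoring to the observed range
(rather than a fixed absolute window) keeps the twenty bins informative
for any ensemble; frames beyond the grid are dropped with a warning.
Morphs are linear per-atom Cartesian interpolations between consecutive
occupied bin averages. They are deliberately nonphysical visualisation
aids; endpoints equal the bin averages exactly and every interpolated
coordinate lies on the segment between its endpoints.

## The synthetic generator: what it emulates, what it does not

`make_hinged_system()` / `simulate_trajectories()` produce a geometric
stand-in for a myosin–ELC trajectory set: a rigid motor blob
(219 pseudo-residues, 550–768, full N/CA/C/O backbones), a helical tail
(769–810) on a hinge, a pseudo-ELC riding the tail, a pseudo-actin
pentamer with a dominant principal axis for frame construction, a
three-moiety 14-atom pseudo-ligand with two rotatable terminal groups,
four contact-switch residue pairs (900–903 vs 910–913), and a hinge salt
bridge (920–921) that opens above a set elevation. Residue numbering is
deliberately compatible with the real-system selections (converter
712–766, tail endpoints 769–771/784–787).

Per frame, elevation and azimuth are drawn from condition-specific
Gaussians; the rigid tail+ELC body is rotated about the hinge by the
minimal rotation mapping the *measured* canonical tail vector onto the
target direction, so planted angles are realized exactly (machine
precision at zero noise — the identity property the suite asserts);
switch contacts are Bernoulli-gated to their target occupancies; the
ligand pose is drawn from a mixture over the pose library; isotropic
Gaussian noise (default σ = 0.3 Å) is added to every atom, with extra
noise (default 1.2 Å, apo only) on the RMSF-inflated converter range.

Default condition parameters, chosen once as a plausible emulation of an
activator that raises and narrows the primed orientation: apo elevation
23° ± 6°, azimuth 34° ± 8°; holo elevation 33° ± 3°, azimuth 45° ± 4°;
planted differential occupancies 0.8 (apo) vs 0.3 (holo); salt-bridge
break at 30° elevation; pose weights (0.4, 0.3, 0.2, 0.1). The default
scenario is 3 replicates × 4000 frames at 100 ps per condition.

What the generator does *not* emulate: physical forces, internal
flexibility of the domains (each body is rigid plus isotropic noise),
solvent, frame-to-frame autocorrelation (an AR(1) option exists and is
off by default — real MD frames are correlated, which matters when
testing statistics at per-frame resolution), and any coupling between
angle, contact and pose channels beyond the planted salt bridge. Passing
tests on generated data therefore demonstrates correctness of the
measurement and statistics machinery, not fidelity of any MD force field.

Two generator-design notes. The pseudo-ELC is kept small (30 residues)
so that the rigid tail+ELC unit is smaller than any LOVO subset at the
default φ — otherwise the internally-rigid swinging unit is itself a
legitimate "least-mobile subset" basin, and the fit can converge to it
(a real ambiguity of LOVO on systems whose mobile part is large and
internally rigid). The ligand's central ring is given a 2.5 Å radius: the
moiety is the alignment anchor, and a small anchor amplifies fit noise
into spurious terminal-group spread (a lever effect) that can over-split
clusters.

## Problem sizes and runtime

The shipped tests run the generator at 100–400 frames and 1–3 replicates
per condition, the property suites at 200–1000 random instances, and the
acceptance script at 3 × 1000 frames for angle statistics and 3 × 100
frames for contact recovery; these sizes were chosen so the whole suite
completes in a few minutes on one CPU while leaving the statistical
assertions comfortable margins. All random draws derive from explicit
seeds.

## Known limitations

* The crossbridge frame's `e2` sign and the azimuth convention are fixed
  by explicit choices (filament atom order, `+e2` toward `+e3`); measuring
  structures in another deposition's frame requires checking both.
* Tilt carries no information beyond elevation and azimuth (see above);
  it is reported for continuity with the field's three-angle summaries.
* Non-circular angle statistics; unsafe if an ensemble straddles ±180°.
* The helix-loop-helix alignment range and the junction range are
  required inputs with documented defaults, not derived from structure.
* `nmrclust()` inherits `stats::hclust` tie-breaking on exactly tied
  linkage values.
* Contact analysis treats residues as atom sets; no hydrogen-bond
  geometry (donor–H–acceptor angles) is evaluated anywhere.
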