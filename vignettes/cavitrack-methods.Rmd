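---
title: "Methods: tracking ligand entry into buried binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking ligand entry into buried binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavitrack)
```

## The problem

Many receptors bind their ligand in a cavity that is closed in every
experimental structure: the ligand must reach it through a transient
channel that only opens dynamically. Insect odorant-receptor
co-receptors (Orco) are the motivating case — a homotetrameric cation
channel whose synthetic agonists bind deep in the transmembrane bundle
— but the analysis questions are generic. Given trajectories of a
ligand diffusing around such a receptor: which trajectories reach the
buried site, through which metastable intermediates, shedding how much
of their hydration shell, touching which residues, and how does the
target cavity compare across homologs in volume, polarity and sequence
conservation?

`cavitrack` implements that analysis chain end to end, plus a synthetic
data generator that plants each signal with exact ground truth. The
generator is not a toy afterthought: because no public trajectory data
accompany the motivating studies, it is the package's reference input,
and every analysis stage is validated against geometry recomputed from
the coordinates it emits.

## The site point and distance series

The buried site is defined operationally, not structurally: the center
of mass of a reference ligand bound in a homolog structure, mapped into
the target frame. `map_reference_site()` superposes Cα anchors of the
reference complex onto paired target residues with the Kabsch algorithm
(SVD of the weighted covariance; the reflection branch is corrected so
the rotation determinant is always +1) and transforms the reference
ligand COM. The pairing is user-supplied: automatic structure alignment
is deliberately out of scope, keeping the mapping deterministic and its
failure mode (unpaired residues) explicit.

`distance_series()` then measures `d_t = ||COM(ligand) − site||`
per frame. COM weighting is by standard atomic mass by default, with an
unweighted option; on the synthetic ligand (equal masses) the two
coincide. With `align_each_frame = TRUE` each frame's receptor
selection is first superposed onto the topology's reference
coordinates, so a site expressed in the reference frame stays valid
when the receptor drifts; the identity
`series(rotated system) == series(original)` holds to 1e-6 Å and is
tested. Coordinates are assumed imaged/whole: there is no
periodic-boundary handling anywhere, which is stated rather than
silently "fixed" because re-imaging is a modelling decision upstream of
analysis.

## Four states, two segmentation methods

The ingress narrative divides the distance curve into *contact*,
*entry*, *vestibule* and *binding*. The literature divides such curves
visually; nothing numeric exists to inherit. The package therefore
offers two explicit methods:

* **changepoint** (default for describing a single trajectory): a
  piecewise-constant mean with `n_states − 1` breakpoints fitted by
  least-squares binary segmentation (each split maximises the SSE
  reduction, minimum segment length `min_dwell`). Segments are labelled
  by mean-distance rank along the state ladder, so the outermost
  plateau gets the outermost label. On planted plateaus with 0.5 Å
  Gaussian noise and 100-frame states, recovered boundaries sit within
  ±3 frames of the planted switches (tested over 10 seeds).
* **threshold** (default for event counting): distance bands under a
  `state_thresholds()` object, smoothed with a hysteresis of
  `min_dwell` frames — a label switches only at the start of a run of
  `min_dwell` identical band labels, so single-frame spikes never
  create states.

The default thresholds (`d_contact = 25`, `d_entry = 15`,
`d_vestibule = 9`, `d_binding = 4` Å, `min_dwell = 5`) are calibration
choices on the synthetic receptor family, exposed as arguments and
recorded in every output header; they are not literature values,
because none exist. Bands are open below (`d < d_binding` is binding),
which makes `segment_states(threshold)` and `detect_entry_events()`
provably consistent: any vestibule-labelled segment of length
`min_dwell` implies `entered_vestibule`.

Event detection is deliberately simpler than segmentation: a trajectory
entered the vestibule iff its distance stays below `d_vestibule` for
`min_dwell` consecutive frames, and bound iff below `d_binding` that
long. This is monotone in the thresholds (raising `d_vestibule` can
only add entries), which is tested as a property.

## Representative frames

Within each state, frames are clustered by k-means (`stats::kmeans`,
10 random restarts under a fixed seed) on either the flattened ligand
coordinates or a per-residue contact fingerprint — both offered because
the choice is a genuine open question in this analysis style. The
representative is the frame nearest the centroid of the most populated
cluster (medoid rule), ties to the lowest frame index. k-means++
initialisation was considered and dropped: `stats::kmeans` does not
provide it, and 10 seeded random restarts give the same determinism and
robustness on desk-scale state populations without re-implementing an
initialiser.

## Solvation

The first solvation shell is counted per water *residue*: a water is in
the shell when any of its atoms lies within the cutoff (default 3.0 Å,
inclusive) of any ligand heavy atom. The inclusive boundary matches the
package-wide neighbor convention — exact planted-count tests require a
fixed convention, and the difference is measure-zero for continuous
coordinates. The cutoff is a knob because hydration-shell tools differ
(3.0 vs 3.4 Å lower shell); 3.0 Å is the default here.

Normalisation divides per-frame counts by a bulk mean from either a
dedicated ligand-in-water box or the pre-contact frames of the main
trajectory; the two agree within sampling error on synthetic data and
that agreement is tested. Fractions may exceed 1 under fluctuation and
are never clipped: the quantity is a ratio of counts, not a
probability.

One statistical note: per-frame shell counts are Poisson-like. Around a
33-heavy-atom ligand at liquid-water density the mean count is ~10, so
per-frame counts fluctuate with CV ≈ 30% no matter how long the
trajectory; what stabilises is the *mean*, whose relative standard
error over 50 frames is ~4%. Tests assert stability of the mean, which
is the quantity the normalisation actually uses.

## Contacts

A residue contacts the ligand when any heavy atom is within 4.0 Å
(inclusive) of a ligand heavy atom. Interaction-type-specific criteria
(hydrogen bond, π-stacking geometries) are out of scope: a single
distance criterion is transparent, testable and standard, and the
cutoff is exposed. Frequencies are row means of the residue × frame
contact matrix over a window that by default starts at the first frame
with any contact — bulk-diffusion frames before first touch would
dilute frequencies arbitrarily with trajectory length — and can be set
explicitly for the whole-trajectory convention. Cohort frequencies are
unweighted means over entry trajectories only, outer-joining residue
universes with zero fill.

## Pocket detection

The detector replaces alpha-sphere/Voronoi pocket finders with a grid
method chosen for verifiability: a regular grid (default 1 Å) over the
padded bounding box; points within vdW + probe (probe 1.4 Å) of any
atom are occupied; empty points are *buried* when at least 9 of 14
fixed ray directions (6 axial + 8 cube diagonals) hit occupancy within
12 Å, sampled at grid resolution; 26-connected components of at least
30 points are pockets. Volume is `n_points × spacing³`, which makes the
estimator directly checkable against an analytic sphere: the planted
5 Å cavity (523.6 Å³) is recovered within 15% at 1 Å spacing, within
10% of itself when the spacing is halved, and within 5% under rigid
rotation (the grid is re-derived from the rotated bounding box). There
is no randomness anywhere in the pipeline.

Lining residues are those with a heavy atom within 4.5 Å of any pocket
grid point. Pocket polarity is the mean lining hydrophilicity under a
chosen scale; both bundled scales are oriented so higher = more polar
(Kyte–Doolittle hydropathy sign-flipped; Wimley–White water→interface
transfer energies, whose native orientation already points that way).
Two scales are bundled because the appropriate scale is genuinely
ambiguous in this literature; the choice is recorded in outputs. The
manual "pocket of interest" selection step is automated as
`nearest_to_point` with a guide coordinate (typically the mapped site
point), falling back to the largest pocket.

## Complementarity scores

The hydrophobic and electrostatic pose scores are defined from first
principles as *correlates* of proprietary tools, never replicas — the
acceptance surface is sign and ordering behaviour on constructed cases,
not absolute values. Both are evaluated on the ligand's
solvent-accessible surface, sampled as a Fibonacci lattice on each
atom's probe-expanded sphere with buried points removed
(deterministic; a point on exactly coincident spheres is kept once).

* hydrophobic: `Pearson(MHP_lig, MHP_env)` with
  `MHP(p) = Σᵢ fᵢ exp(−d(p,i)/L)`, decay length L = 2 Å, atomic
  constants from a bundled element table (carbon positive, N/O
  negative) overridable per atom;
* electrostatic: `−Pearson(φ_lig, φ_env)` with `φ = Σᵢ qᵢ/dᵢ` (the
  dielectric folds out of a correlation), so +1 is ideal
  complementarity and the score is exactly antisymmetric under charge
  conjugation of either side.

Two numerical caveats are documented rather than hidden. First, the
surface lattice is laid in fixed coordinate axes, so rigid rotation of
a complex re-samples the smooth fields at slightly shifted points:
scores are rotation-stable to ~1e-3 at 1 point/Å² (tighter at higher
density), not to machine precision; a fully molecule-fixed sampling
frame is ill-defined for degenerate shapes (e.g. a 2-atom ligand).
Second, because Coulomb potentials are long-range, both surface fields
are smooth and effectively low-rank: under completely random charges
the null correlation has a standard deviation near 0.3 regardless of
atom count. Null tests therefore bound the *center* of the null
distribution and the separation from designed cases, not individual
draws.

## The synthetic generator

The generator emulates, with exact bookkeeping, the features the
pipeline must detect:

* **Receptor**: a pseudo-atom shell (one carbon per residue, layered
  Fibonacci spheres with 0.08 Å jitter) whose innermost layer sits at
  `cavity_radius + probe + vdW`, so the planted cavity is exactly the
  stated sphere at grid resolution; a cylindrical channel (default bore
  3.6 Å) connects it to the exterior.
* **Trajectories**: the ligand (default 33 heavy atoms, the size of a
  drug-like agonist, filling a 14 × 6 × 5 Å ellipsoid) is translated
  along the channel axis so its COM distance is
  `planted_distance[state] + N(0, noise_sd)` per frame, dwelling a set
  number of frames per state. Default planted distances
  (40/20/12/6.5/2 Å) sit mid-band between the default thresholds;
  default noise 0.5 Å keeps plateau separations above 4 noise SDs, the
  regime where cohort recovery is exact.
* **Waters**: single-oxygen pseudo-atoms (hydrogens add nothing to a
  distance count) in a 20 Å box moving with the ligand at 0.0334
  waters/Å³ — liquid-water density. In states with a planted
  shell-retention fraction (contact 0.7, entry 0.5, vestibule 0.2,
  binding 0.2 — the canonical desolvation profile of this analysis
  style), the generator places exactly
  `round(retention × expected bulk shell)` waters in the shell and
  forces the rest out; the expected bulk count is a seeded Monte-Carlo
  volume estimate, so the planted fraction is constructive.
* **Cohorts**: exactly `n_entering` of `n_traj` trajectories reach the
  vestibule and `n_binding` of those bind, by truncating the state
  schedule; the study-scale design (88/19/7, 200 frames) runs in
  seconds.
* **Alignments**: pairwise identity/similarity over designated columns
  is *constructed* (matched, same-group, different-group residues), so
  planted percentages like 73/82 or 50/62.5 are exact by arithmetic,
  with infeasible plans (non-integer counts) rejected.
* **Complementarity cases**: a ±1 dipole ligand inside a charge- or
  hydrophobicity-patterned cage whose score sign is known from the
  construction.

Ground truth (distances, contact schedules, shell counts) is recomputed
from the emitted coordinates by brute-force passes independent of the
analysis code paths, so tests compare against geometry, not against the
generator's intent.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: conformational flexibility of ligand and
receptor (both are rigid), explicit hydrogens and water orientation,
membrane and ions, realistic kinetics (states are planted, not
sampled from a free-energy surface), force-field physics of any kind,
and gapped/phylogenetically structured alignments. The package's claims
on real trajectories are therefore about the *estimators* (distances,
counts, segmentations, volumes, correlations), not about reproducing
any particular receptor's biology.

## Numerical conventions and degenerate inputs

All cutoff comparisons are inclusive (`≤`), fixed package-wide so
planted-count tests are exact. PDB coordinates round-trip at 3 decimals
(the format's precision). Ties are deterministic: k-means ties to the
lowest frame index, consensus ties alphabetical, pocket lists sorted by
volume. Degenerate inputs degrade loudly: empty selections error,
empty water selections warn and return 0, an all-gap column is flagged,
a model without a pocket gets an NA row, fewer frames than clusters
reduces k with a message, and a missing bulk mean skips the solvation
stage with a warning while the other stages complete.

## Problem sizes

The shipped tests and the acceptance script run the full study design
where it is cheap (88-trajectory cohorts at 200 frames, 176-sequence
alignments) and desk-scale versions elsewhere (receptors of 300–1500
pseudo-atoms, 20–60 water frames, 1 Å pocket grids). These sizes are
the package's reference conditions: they were chosen once, produce
stable estimates at the tested tolerances, and are stated in each test
file rather than tuned per run.
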