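# cavitrack

Tools for characterising how a small-molecule ligand reaches a **buried
receptor binding site** in molecular dynamics trajectories. The package
was built around the analysis style used for insect odorant-receptor
co-receptor (Orco) channels, where an agonist must travel from solvent
through a transient channel in the transmembrane helix bundle to a
cavity that is closed in every experimental structure — but every stage
is generic: any receptor with a buried site, any ligand, any
trajectory that fits in memory.

## What it computes

**Reference-site mapping.** The buried site is defined by superposing a
ligand-bound reference complex onto the target receptor (Kabsch, Cα
anchors over a user-supplied residue pairing) and mapping the reference
ligand's center of mass: the site point *s*.

**Distance series and state segmentation.** For each frame *t* the
ligand-to-site distance is `d_t = ||COM(ligand_t) − s||` (mass-weighted
COM by default). The ingress is segmented into the four classic
metastable states — *contact*, *entry*, *vestibule*, *binding* — either
by least-squares changepoint fitting (binary segmentation of a
piecewise-constant mean) or by distance thresholds with a dwell-time
hysteresis. Entry events are counted per trajectory:
`entered_vestibule` iff `d_t < d_vestibule` for at least `min_dwell`
consecutive frames, `fully_bound` analogously with `d_binding`, and
cohorts are tallied with `summarize_cohort()`.

**Desolvation.** The first solvation shell is the set of water residues
with an atom within 3 Å (inclusive) of any ligand heavy atom; per-frame
counts normalised by a bulk reference (a dedicated ligand-in-water box,
or the pre-contact frames) give the solvation fraction.

**Contacts.** A residue is in contact when any heavy atom lies within
4 Å of a ligand heavy atom; per-residue contact frequencies are row
means over an ingress window, and cohort frequencies average over
entry trajectories only.

**Pockets.** A deterministic grid detector: grid points farther than
vdW + probe from every atom are empty; empty points that see protein in
≥ 9 of 14 fixed ray directions within 12 Å are buried; 26-connected
components are pockets with volume `n_points × spacing³`, lining
residues, and a polarity score (mean lining hydrophilicity under a
bundled scale — Kyte–Doolittle sign-flipped, or Wimley–White interface).

**Complementarity.** Pose scores on the ligand's solvent-accessible
surface (Fibonacci lattice): the hydrophobic score is the Pearson
correlation between ligand-sourced and environment-sourced molecular
hydrophobicity potentials `Σᵢ fᵢ·exp(−d/L)`; the electrostatic score is
`−Pearson(φ_lig, φ_env)` with `φ = Σᵢ qᵢ/dᵢ`, so +1 means perfectly
anticorrelated potentials. A 180° `flip_pose()` utility supports
"reverted pose" comparisons.

**Conservation.** Per-column alignment statistics, consensus-logo
matrices (probability or information-content bits), and pocket
identity/similarity percentages between sequence pairs under
configurable similarity groups.

**Synthetic data.** `make_toy_receptor()`, `make_translocation_trajectory()`,
`make_cohort()`, `make_bulk_water_system()`, `make_alignment()`,
`make_complementarity_case()` and `make_contact_trajectory()` plant all
of these signals with exact machine-readable ground truth recomputed
from the emitted coordinates, so the whole pipeline is testable without
running a nanosecond of MD.

## Worked example

```r
library(cavitrack)

receptor <- make_toy_receptor(seed = 7)                 # buried 5 A cavity
site     <- site_point(attr(receptor, "cavity_center"))
tr   <- make_translocation_trajectory(receptor, n_waters = 267, seed = 42)
topo <- tr$trajectory$topology
lig  <- atom_select(topo, chain = "L")

ds <- distance_series(tr$trajectory, lig, site = site)
ds
#> DistanceSeries: 200 frames, 0.7-41.4 A

seg <- segment_states(ds, method = "threshold")
seg
#> StateSegmentation (threshold): bulk[40] > contact[40] > entry[40] > vestibule[40] > binding[40]

detect_entry_events(ds)
#> EntryEvents: vestibule=TRUE (frame 121), bound=TRUE (frame 161)

wat <- atom_select(topo, water = TRUE)
bm  <- bulk_reference(tr$trajectory, lig, wat,
                      frames = which(seg$labels == "bulk"))
sf  <- solvation_fraction(tr$trajectory, lig, wat, bm)
round(tapply(sf$fraction, factor(seg$labels, levels = unique(seg$labels)), mean), 2)
#>      bulk   contact     entry vestibule   binding
#>      1.00      0.74      0.47      0.19      0.19

detect_pockets(receptor)[[1]]
#> Pocket: 565 grid points (1.0 A spacing), volume 565.0 A^3, 332 lining residues, polarity -1.80
```

Reading the numbers: the ligand dwells at the five planted distances
(the series spans 41 Å in bulk down to 0.7 Å in the cavity), the
threshold segmentation recovers all five 40-frame states, vestibule
entry and full binding are detected at the planted switch frames, the
solvation fraction falls from 1.0 in bulk to ~0.2 in the binding pose
(the planted desolvation profile), and the grid detector finds the
single planted cavity at 565 Å³ — within 8% of the analytic
4/3·π·5³ = 523.6 Å³ for a 1 Å grid.

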