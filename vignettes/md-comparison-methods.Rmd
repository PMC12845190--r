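---
title: "Methods: comparative MD descriptors and interaction fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative MD descriptors and interaction fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdligand)
```

## Scope and model

`mdligand` implements the post-simulation analysis layer for comparing two
protein–ligand complexes: trajectory descriptors, residue flexibility
statistics, geometric interaction fingerprints, and binding free-energy
component bookkeeping, plus the upstream combinatorial library and
drug-likeness filtering stage. Docking and force-field MD are explicitly out
of scope; a synthetic-data module stands in for them so every stage can be
exercised against planted ground truth at desk scale.

All internal geometry is in Å (the native unit of the PDB format used for
I/O); the reporting layer converts to nm where the field conventionally
prints nm (RMSD, RMSF, Rg summaries, H-bond mean-distance tables). This
avoids unit churn at I/O while matching both the Å-scale superposition
reports and the nm-scale trajectory summaries such analyses print.

## Superposition and pruned-pair RMSD

`kabsch_fit()` minimises the weighted sum of squared pair distances via the
SVD of the pair covariance matrix, with the reflection corrected by a sign
flip of the smallest singular direction so the result is always a proper
rotation. Collinear point sets leave the rotation underdetermined and are
rejected. Weights default to uniform — the convention for backbone
least-squares fitting — with mass weighting available as an option.

`pruned_superpose()` mirrors the matchmaker convention used by common
visualisation tools: fit on the retained pairs, drop *all* pairs whose
post-fit distance exceeds the cutoff (default 2.0 Å), refit, and stop when
the retained set is stable or would fall below `max(3, 0.3 · n)` pairs, in
which case the last valid set is kept. Both the pruned and the all-pair RMSD
are reported under the final transform, so `rmsd_pruned ≤ rmsd_all` always
holds. The retained-pair counts are data-dependent; they are diagnostics,
not targets.

## Trajectory descriptors

* **RMSD series**: each frame is fitted on the fit selection (default
  protein backbone) to a reference frame — the *initial* conformation, the
  standard convention for stability plots — and RMSD is measured on the
  measure selection. Ligand RMSD is measured after fitting on the protein
  backbone, so it reflects pocket-relative motion; fitting on the ligand
  itself is available by flag since published workflows rarely state which
  convention they used.
* **RMSF profile**: frames are fitted to the time-average structure,
  computed by an initial fit to frame 1 followed by one refinement pass
  (refit to the provisional mean, recompute the mean). The per-residue basis
  is the Cα atom — the convention behind residue-level flexibility plots —
  with a heavy-atom-mean option.
* **Rg**: mass-weighted RMS distance from the centre of mass, per frame.

Summaries are mean ± sample SD (n − 1) over frames.

## Flexibility classes and the differential detector

Residues are classed low (< 0.1 nm), medium (0.1–0.3 nm) or high
(> 0.3 nm). Because the class definitions are stated as open inequalities
on both ends, both boundary values (exactly 0.1 or 0.3 nm) fall to medium.
Percentages are rounded half-up to two decimals, matching printed tables
(base R's round-half-even would give 36.45 where such tables print 36.46).

The differential detector slides a 5-residue window (stride 1) over the
residues shared by both profiles and scores each window by the difference
of windowed *maxima*, `d = max_w(A) − max_w(B)`; windows with
`|d| ≥ 0.2 nm` are flagged. Overlapping flagged windows of the same sign
merge into one segment. A design point that the underlying convention
leaves open is what residue span a merged segment reports. We index a
window by its start residue and report first-to-last flagged start: with a
bump at residues 10–14 in a 20-residue profile, every window touching the
bump flags (starts 6–14) and the segment is 6–14. This is the minimal rule
that turns windows into the residue-span segments such analyses report, and
it is antisymmetric under swapping the two systems. Window size, threshold
and the merge rule are all exposed as arguments.

## Interaction fingerprints

Detector thresholds are geometric, inclusive, and deliberately
conservative-permissive so that every contact class the field reports as
bonded passes:

| interaction | criteria (defaults) |
|---|---|
| hydrogen bond | H–A ≤ 3.0 Å, D–A ≤ 4.0 Å, D–H–A ≥ 120° |
| salt bridge | min cation/anion group atom distance ≤ 5.5 Å |
| π-stacking | centroid ≤ 5.5 Å, lateral offset ≤ 2.0 Å, normals ≤ 35° |
| hydrophobic | apolar–apolar pair ≤ 4.5 Å (one event per residue) |

The H-bond cutoffs accommodate reported bonded geometries up to
H–A 2.96 Å / D–A 3.94 Å; the salt-bridge cutoff of 5.5 Å admits contacts
described as "salt-bridge-type" at 5.26 Å. π-stacking is detected as a
single face-to-face class (the lateral-offset rule excludes T-shaped
geometries), because trajectory fingerprints in this setting record
face-to-face stacking as the π-interaction of interest. Cation–π and
halogen-bond detectors are intentionally absent. Every emitted event stores
its geometry and asserts its own thresholds.

Persistence of a (residue, type) key is the exact fraction of frames in
which it occurs. The mean donor–acceptor distance tables average over *all*
frames, bonded or not — the only convention consistent with published
tables whose means reach 1.06 nm, far beyond any bonding cutoff.

The contact class map colours residues by minimum heavy-atom distance to
the ligand: green below 4 Å, yellow from 4 to 6 Å. The upper yellow bound
is a package choice — an open-ended "> 4 Å" class would make every residue
an interacting residue — and is configurable.

## Energy bookkeeping

`GGAS = VDWAALS + EEL` and `GSOLV = EPB + ENPOLAR` are computed per frame
and then summarised, so the mean-level identities hold exactly and the
reported SDs are sample SDs of the per-frame derived series, not quadrature
sums. Printed ± values in the literature cannot disambiguate this
convention; computing on per-frame series is the choice that keeps all
identities exact. Solvation components are inputs produced by an external
MM/PBSA engine; entropy corrections are out of scope.

## Library and drug-likeness filtering

The combinatorial library is enumerated r2-major over head groups
(R2 = 1..15) and tail groups (R1 = 1..12), named `"{r2}.{r1}"`. The five
rule sets use the numeric thresholds of the standard ADME filter
definitions (Lipinski MW ≤ 500, logP ≤ 4.15, HBD ≤ 5, HBA ≤ 10; Ghose,
Veber, Egan, Muegge analogously); the thresholds live in
`inst/extdata/druglikeness_rules.json`, not in code. A rule missing its
descriptor is *not evaluable* and reported as such — never silently zero
violations. The CNS window retains consensus logP in [2.0, 3.5]; a record
with zero rule violations but logP outside the window fails the filter and
is flagged rather than passed, even though published compound tables
occasionally list such compounds as retained. Descriptors are consumed as
data behind a provider interface (TSV reader); recomputing logP or TPSA
from structures is out of scope.

## The synthetic world

`make_toy_complex()` lays a backbone along a helical curve with simplified
residue geometry from standard templates: planar aromatic rings (the
fused 5+6 indole is built exactly), carboxylate and guanidinium groups,
amide hydrogens. The ligand sits at a configurable clearance (default 6 Å)
from the protein, far enough that the *default* complex has no
protein–ligand contacts: interactions exist only where planted, which is
what makes exact-count assertions meaningful.

`make_fluctuation_trajectory()` displaces whole residues rigidly by
isotropic per-axis Gaussian noise of SD σ_r (nm). Rigid per-residue motion
(rather than per-atom noise) makes the expected Cα RMSF exactly σ_r·√3
without intra-residue averaging effects. Noise is uncorrelated across
frames and residues — no principal-component-like collective motion — so a
green RMSF test establishes estimator correctness, not realism of the
dynamics. Two estimator artefacts bound what "recovery" can mean: the
least-squares fit absorbs 6 rigid degrees of freedom, biasing RMSF low by
a factor ≈ √(1 − 6/(3·n_fit_atoms)) (≈ 0.4 % for a 120-residue backbone
fit), and a single residue's RMSF at T frames carries ≈ 1/√(2T) relative
sampling error (≈ 1 % at T = 5000). The 2 % recovery criterion is
therefore asserted on the profile mean over residues, with a 5 %
per-residue bound.

`plant_interaction_snapshot()` builds each requested interaction as an
isolated, widely separated "station": a minimal protein residue carrying
the stated residue id and name, plus matching ligand atoms, positioned so
the requested geometry holds exactly (verified post-construction by direct
measurement, to 0.01 Å, independent of the detector code). Two bridges
from one guanidine to two carboxylates are realised as two separate
stations — a synthetic stand-in that preserves event counts and geometries
while keeping each distance exactly controllable. Stations are spaced 25 Å
apart, so detectors find exactly the planted events.

`make_energy_series()` draws independent Gaussian per-frame components;
`make_rmsf_pair()` plants a differential bump over a stated residue range
with off-bump jitter bounded below a quarter of the detection threshold.
All generators are bit-reproducible under a fixed seed.

## Numerical choices and degenerate inputs

* Rotation fits reject < 3 pairs and collinear sets; rank is judged
  against the largest singular value at 1e−10 relative.
* Ring normals come from the SVD of the centered ring atoms; collinear
  rings are a geometry error. Normal orientation is folded to ≤ 90° before
  the planarity test.
* Classification ties (exactly 0.1 / 0.3 nm) go to medium; extrema ties go
  to the lowest residue id.
* Sample SD is undefined for a single frame and reported as NA, never 0.
* Table renderers use fixed-width decimal formatting (RMSF 4 dp, distances
  and energies 2 dp, percentages 2 dp), making repeat runs byte-identical.

## Known limitations

* Pairing for superposition is positional; there is no sequence alignment.
* The PDB reader handles the fixed-column multi-model dialect only: no
  mmCIF, no binary trajectory formats, no insertion codes, no altLoc
  handling beyond passing the column through.
* The synthetic generator has no physics: no sterics beyond a clash check
  in planted snapshots, no solvent, no correlated motion.
* Trajectory-average quantities from the original 200 ns simulations this
  analysis style is built for are not reproducible from the package alone —
  those trajectories are not public — so tests target self-contained
  arithmetic, planted geometries and closed-form statistics instead.
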