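# mdligand

Comparative trajectory descriptors and interaction fingerprints for
protein–ligand complexes.

`mdligand` is a desk-scale R re-implementation of the analysis layer used to
compare two protein–ligand systems after molecular dynamics — for example a
designed aspartic-protease inhibitor against a clinical reference compound
bound to the same enzyme. It covers everything *after* docking and the MD
engine: the engines themselves are replaced by a seeded synthetic-data module,
so the whole pipeline runs in seconds and every stage is testable against
planted ground truth.

## What it computes

* **Superposition** — Kabsch least-squares fitting (SVD with reflection
  correction), plain RMSD, and Chimera-matchmaker-style *pruned-pair* RMSD:
  iteratively refit on retained atom pairs and drop pairs beyond a cutoff
  (default 2.0 Å), reporting both the pruned and the all-pair RMSD.
* **Trajectory descriptors** — per-frame RMSD against the initial
  conformation after backbone fitting; per-residue RMSF about the
  time-average structure, `RMSF_r = sqrt(mean_t |x_rt − x̄_r|²)` on Cα atoms;
  mass-weighted radius of gyration
  `Rg = sqrt(Σ m_i |r_i − r_com|² / Σ m_i)`. Reported in nm, mean ± sample SD.
* **Flexibility analysis** — three-class residue taxonomy (low < 0.1 nm,
  medium 0.1–0.3 nm, high > 0.3 nm) with count/percentage tables, extrema
  reporting, and a sliding-window differential detector: windows of 5
  residues are scored by `d = max_w(RMSF_A) − max_w(RMSF_B)` and windows with
  `|d| ≥ 0.2 nm` merge into directional segments.
* **Interaction fingerprints** — geometric per-frame detectors for hydrogen
  bonds (H–A ≤ 3.0 Å, D–A ≤ 4.0 Å, D–H–A ≥ 120°), salt bridges (minimum
  cation/anion group distance ≤ 5.5 Å), face-to-face π-stacking (centroid
  ≤ 5.5 Å, lateral offset ≤ 2.0 Å, ring-normal angle ≤ 35°) and hydrophobic
  contacts (apolar pair ≤ 4.5 Å); frames × (residue, type) fingerprint
  matrices with exact persistence; donor–acceptor mean-distance tables; a
  green/yellow (< 4 Å / 4–6 Å) per-residue contact class map.
* **Energy bookkeeping** — MM/PBSA component aggregation:
  `GGAS = VDWAALS + EEL`, `GSOLV = EPB + ENPOLAR`, `TOTAL = GGAS + GSOLV`,
  summarised per frame with exact additivity, plus ligand-vs-ligand deltas.
* **Library design / ADME filtering** — `(R2.R1)`-named combinatorial
  enumeration (12 tails × 15 heads = 180 compounds) and the filtering
  cascade: Lipinski, Ghose, Veber, Egan and Muegge violation counts, a
  consensus-logP CNS window of 2.0–3.5, and optional P-gp/CYP flag screens.

## Worked example

```r
library(mdligand)

# two synthetic systems sharing a topology but with different dynamics
cx <- make_toy_complex(25, seed = 110)
sys_a <- make_fluctuation_trajectory(cx, 0.05, 6, seed = 111)
sys_b <- make_fluctuation_trajectory(cx, 0.08, 6, seed = 112)

rs <- rmsd_series(sys_a)
round(unlist(rs$summary[c("mean", "sd")]), 3)
#>  mean    sd
#> 0.097 0.048

prof <- classify_flexibility(rmsf_profile(sys_b))
flexibility_summary(prof)
#>    class count percentage
#> 1    low     8         32
#> 2 medium    17         68
#> 3   high     0          0

# a planted final-snapshot fixture with three H-bonds, two salt bridges
# and one pi-stack at exact geometries
snap <- plant_interaction_snapshot(cx, list(
  list(type = "hbond", resid = 74, resname = "GLY", donor = "protein",
       ha = 2.96, da = 3.94, lig_atom = "N24"),
  list(type = "salt_bridge", resid = 32, resname = "ASP", dist = 4.19),
  list(type = "pi_stacking", resid = 115, resname = "TRP",
       centroid = 5.37, offset = 0.63)))
detect_hbonds_frame(snap)[, c("resid", "resname", "ha_dist", "da_dist")]
#>   resid resname ha_dist da_dist
#> 1    74     GLY    2.96    3.94
```

The numbers mean: system A's backbone deviates on average 0.097 ± 0.048 nm
from its starting conformation; in system B 17 of 25 residues fall in the
medium-flexibility band; and the planted Gly74 hydrogen bond is re-detected
at exactly its requested geometry (H–acceptor 2.96 Å, donor–acceptor
3.94 Å).

An end-to-end comparison with report tables:

```r
rep <- run_compare(sys_a, sys_b, seed = 1)
render_tables(rep, "run")   # TSV tables + report.json + manifest.json
```

A command-line front end with `synth`, `compare`, `libgen` and
`adme-filter` subcommands is installed at
`system.file("cli", "mdligand.R", package = "mdligand")`.

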