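---
title: "Methods: geometry, statistics and design choices behind the triage funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, statistics and design choices behind the triage funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppitriage)
```

`ppitriage` post-processes docking campaigns against protein–protein
interfaces in which the candidate ligands are themselves short peptides or
peptidomimetics. This vignette records the model behind each stage, the
parameters that matter, and the choices made where the underlying procedure
is conventionally under-specified. Nothing here asserts an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Structures, ensembles and poses

Atom records live in a plain data.frame (`Structure`); an `Ensemble` is an
ordered list of coordinate frames over one topology, with frame *k* at time
*k·Δt* — the initial configuration is not stored as a frame. That timing
convention is load-bearing: it is the only one under which sampling a
100 ps run every 4 ps yields exactly 25 conformers and 25 combined 2-ns
runs sampled at 4 ps yield exactly 12,500 frames, the two bookkeeping
identities the acceptance suite checks.

PDB reading resolves alternate locations to the highest-occupancy copy
(ties: first encountered), a standard convention. Hydrogens are read and
kept, but contacts, clashes and RMSD use heavy atoms only by default;
SASA includes hydrogens when present. Van der Waals radii come from a
bundled Bondi-style element table (`default_vdw_radii()`), overridable per
call. Polar atoms are N, O, S in thiols and hydrogens bonded to N/O
(bond inferred by a 1.25 Å distance rule) — a TPSA-style convention chosen
because the permeability literature never defines "polar" operationally.

Docking pose sets are multi-model PDB with one `REMARK VINA RESULT:` score
line per model (a configurable regex, since no standard exists); poses are
stably sorted by ascending score so equal scores keep file order.

## Geometry kernels

Dihedrals use the standard signed atan2 formulation (IUPAC: cis = 0°,
trans = 180°, range (−180°, 180°]); collinear triples raise an error rather
than silently returning 0. ω(i) is assigned to the bond joining residue
*i* to *i+1*. Superposition is closed-form Kabsch via SVD with a
determinant correction so the rotation is always proper; `rmsd(fit = TRUE)`
reports the post-fit value and is never larger than the unfitted value (a
property test exercises 200 seeded instances).

## Contact conservation

A receptor–partner residue pair is in contact when its minimum heavy-atom
distance is ≤ 4.0 Å, *inclusive* — "a distance of 4.0 Å" is read as the
standard minimum-heavy-atom criterion. Conservation across a panel of
complexes is recurrence of the same receptor residue (matched by residue
number; receptor numbering must be shared) in at least a fraction of the
complexes; the default fraction is 0.75, operationalising "virtually all"
while acknowledging that published conservation tables contain blank cells,
so 100% is demonstrably not required. Partner-side sequence-alignment
pooling is deliberately out of scope: partners are reported per complex.

## Pose-filter cascade

Only the top 20 poses per compound are examined (configurable). The three
geometric filters and the energy cut are independent predicates, and the
survivor set is their intersection — a property the tests verify against
single-filter runs and against generator labels.

**Ramachandran.** No canonical reference distribution exists for
peptidomimetics, so the bundled map is a deliberately coarse 10°-bin mask
rasterised from rectangular allowed regions (α, β/PPII, α_L for the general
class; broadened and mirrored for glycine; φ-restricted for proline) stored
as a TSV so stricter masks can be substituted. Residues lacking a Cβ are
treated as glycine-like; unknown residue classes fall back to general.
A residue fails only when both φ and ψ are defined and the bin is
disallowed; chain termini therefore never fail.

**Peptide bonds.** |ω| ≥ 150° is trans, |ω| ≤ 30° is cis, anything between
is non-planar; cis and non-planar both fail. The windows are conventional
and configurable; bonds with missing defining atoms are skipped rather than
failed.

**Clashes.** "Intramolecular contacts" is read as steric clashes: two heavy
atoms at least 4 covalent bonds apart closer than r_i + r_j − 0.4 Å. A
literal any-contact rule would reject every folded conformation. The
covalent graph uses template connectivity on standard peptide atom names
with a distance fallback (0.8–1.8 Å) only for atoms the template does not
cover — pure distance inference would classify a deliberately planted
1.0 Å overlap as a covalent bond and hide it from the check.

**Energy.** "Docking energy lower than −8 kcal/mol" is directionally
ambiguous; the only reading consistent with published selections whose
weakest retained score is exactly −8.0 is: discard scores numerically
greater than −8.0, keep ≤ −8.0 inclusive. The merged ranking breaks ties
deterministically by score, then compound id, then rank.

## Binding stability

The reference for ligand RMSD is the *docked pose*, not the first
trajectory frame: the quantity measures retention of the predicted binding
mode. Each frame is first superposed on the reference using receptor heavy
atoms; the ligand RMSD is then computed *without* fitting the ligand, so
drift out of the site counts while receptor tumbling does not. The verdict
averages the trailing window — default the trailing 50% of frames,
generalising "the last 1.5 ns of a 3 ns run", with an absolute `window_ps`
alternative — and declares a stable binder on a strict `< 3.0 Å`
comparison (a mean of exactly 3.0 Å is not stable).

## Polar surface area and permeability

SASA is Shrake–Rupley with a deterministic golden-spiral lattice
(default 960 points, probe 1.4 Å), chosen over random sampling so results
are bit-for-bit reproducible at fixed point count; the acceptance suite
bounds its error at ≤ 0.5% against the isolated-sphere closed form and
≤ 2% against a 10⁵-sample Monte-Carlo surface integration on random
clusters. Per-atom area is 4π(r+probe)² × (accessible points / points).
The polar restriction sums per-atom areas over the polar flags;
polar + apolar = total exactly by construction.

The screening threshold (150 Å²) and the stricter synthesis cut (130 Å²)
are two thresholds on the same ensemble-averaged quantity, both strict
inequalities. Conformer ensembles are produced by `extract_snapshots()`
(every 4 ps by default) and `combine_ensembles()`.

## Probe-occupancy hotspots

Each probe molecule contributes its heavy-atom geometric centre (per-atom
binning would overweight larger probes) to one voxel per frame over the
trailing window (default 50%, mirroring analysis of the last half of a
mixed-solvent run). Counts are conserved exactly: every probe lands in one
voxel or the out-of-grid sentinel. Grid spacing defaults to 1.0 Å — the
occupancy grid is not the docking grid, whose finer spacing serves a
different purpose. Occupancy fractions are normalised per probe type by
(windowed frames × probes of that type) so thresholds compare across
types. Hotspots are 6-connected components of voxels above `min_fraction`,
ranked by peak fraction, reporting residues within `report_radius`
(default 6 Å) of the peak, distance-sorted.

`min_fraction` has no canonical value (published contour levels go
unreported); the tests use 0.005 with 20 probes × 100 windowed frames,
chosen *a priori* as roughly ten times the uniform-background per-voxel
fraction (≈ 5×10⁻⁴ at that sampling depth) and comfortably below the
expected peak fraction (≈ 0.017) of a σ = 1 Å planted Gaussian visited 30%
of the time. It was not adjusted after seeing results.

## What the synthetic generators do and do not establish

`build_peptide()` places N/CA/C/O/Cβ atoms by internal-coordinate (NeRF)
chaining from fixed ideal bond lengths and angles; the tests assert
self-consistency (measured torsions reproduce requested ones to 10⁻³°),
not the constants themselves. `make_pose_library()` samples clean poses
from interior points of the allowed torsion regions and *rejects* clean
conformations that clash (ideal geometry at allowed torsions can still
produce borderline O···O contacts in 3–4-mers), then injects labelled
defects: an off-map (φ, ψ) = (75°, −60°) at an internal residue, an ω of
0° or 100°, or a Cβ displaced to 1.0 Å from a non-bonded carbon.

One defect can have physical side effects — a cis rebuild may also create
a clash — so the label contract is: every labelled defect trips its own
filter, defect-free poses pass all filters, and the survivor set equals
the label-predicted intersection. The generators emulate geometry and
bookkeeping, not chemistry: no sidechain rotamers beyond Cβ, no realistic
score–geometry correlation, single-site probes, rigid receptors. A green
suite therefore establishes algorithmic correctness against ground truth,
not predictive validity on real docking output.

Gaussian-noise trajectories noise the ligand with the receptor rigid when
testing the RMSD statistic, because the expectation being checked
(mean RMSD ≈ σ√3 for iid per-coordinate noise) concerns the measurement,
not superposition fit error; noising the receptor too inflates the aligned
statistic by a few percent of fit leakage.

## Numerical conventions

Angles in degrees in (−180°, 180°]; coordinates in Å; residue numbering
follows the input file. Collinearity tolerance for dihedrals: cross-product
norm < 10⁻⁹ Å². Rotation matrices are validated to det = +1 within 10⁻⁶.
All boundary comparisons at published thresholds are strict (<) except the
energy cut, which is inclusive (≤ −8.0) per the published selection.
All generators take a mandatory seed and are pure functions of
(parameters, seed).

## Known limitations

- Cross-complex correspondence is by receptor residue number only; a
  mapping table, not sequence alignment, is the escape hatch.
- The Ramachandran mask is coarse by design; it separates clearly allowed
  from clearly disallowed and is not a statistical potential.
- `filter_clashes` template connectivity covers standard backbone + Cβ
  names; exotic atom nomenclature falls back to distance inference.
- Occupancy accumulation is plain R loops — adequate for fixture-scale
  grids, not for 50 ns production trajectories.
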