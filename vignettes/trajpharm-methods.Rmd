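---
title: "Dynamic pharmacophores from MD interaction profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic pharmacophores from MD interaction profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajpharm)
```

## The problem

A crystal structure shows a single ligand pose; a molecular dynamics
trajectory shows which of its noncovalent contacts persist. `trajpharm`
implements the full desk workflow around that observation: detect
contacts frame by frame, summarize them as per-residue occurrence
profiles, promote persistent contacts to a 3D pharmacophore, and screen
conformer libraries against that model. It also covers the two
supporting analyses such a study needs: consensus clustering of docking
poses (to pick a binding mode before any MD is run) and standard
trajectory metrics (backbone RMSD, Cα RMSF, salt-bridge prevalence).

Docking engines, MD codes and chemistry toolkits are deliberately out of
scope: the package consumes their outputs (multi-model PDB trajectories,
SDF pose sets and conformer libraries) and owns everything downstream.

## Interaction detection

Five detectors operate on one frame at a time. All criteria are
configurable through `interaction_criteria()`; the defaults mirror the
published defaults of the PLIP profiler, which is the de facto standard
for this kind of MD interaction fingerprinting.

| interaction | criterion (defaults) |
|---|---|
| hydrogen bond | donor–acceptor < 4.1 Å; if explicit H present, D–H···A angle at H ≥ 100° |
| hydrophobic | apolar C···C < 4.0 Å, collapsed to the closest pair per residue |
| π-stacking | ring centroids < 5.5 Å, interplanar angle within 30° of 0° or 90°, in-plane offset ≤ 2.0 Å |
| salt bridge | opposite-charge group centroids < 5.5 Å |
| cation–π | cation centroid to ring centroid < 6.0 Å (opt-in) |

Boundary conventions are fixed so tests are exact: strict `<` for every
distance cutoff, `≥` for angle minima, `≤` for angle-deviation windows
and the stacking offset. The cation–π detector exists and is exported,
but `detect_frame()` excludes it by default so the frame union is
exactly the four types the occurrence profiles report; pass
`include_pication = TRUE` to add it.

**Atom typing.** Protein atoms are typed from residue-name templates for
the twenty standard amino acids (backbone N donor, backbone O acceptor,
a side-chain donor/acceptor/apolar/ring/charge table), because real PDB
input usually carries neither hydrogens nor reliable CONECT records.
Ligand atoms are typed from their bond graph: N/O with an explicit H
donate; all O and non-quaternary N accept; carbons bonded only to C/H
are apolar; 5- and 6-cycles planar within 0.3 Å RMS of their best-fit
plane are aromatic. When a ligand carries no hydrogens at all,
under-valent N/O are treated as implicit-H donors, and hydrogen bonds
fall back to the heavy-atom distance criterion alone — this is what lets
minimal fixtures omit hydrogens without changing the code path for real
input. Ring membership is a topology-level property; planarity is
assessed on the reference coordinates, not re-judged every frame.

## Occurrence profiles

`profile_trajectory()` counts, for each (residue, interaction type)
pair, the number of frames with **at least one** qualifying event;
multiplicity within a frame is deliberately ignored because occurrence
is defined over conformations, not atom pairs. Percentages are computed
as `100·count/total` and rounded **half away from zero** to two
decimals. This convention reproduces the reference worked examples
(14998/15000 → 99.99, 3239/15000 → 21.59, 4713/15000 → 31.42,
7421/15000 → 49.47). One published value disagrees: 13204/15000 =
88.0267% is printed as 88.02 in the reference tables, which is
truncation, not rounding; the majority convention wins and the package
returns 88.03.

`relevant_interactions()` applies the relevance rule — occurrence
**strictly greater than** 20% of simulation time — so a cell at exactly
20.00% is excluded. The threshold is a parameter everywhere it appears.

## Pharmacophore generation

`build_features()` maps each relevant cell to a typed feature:

* hydrogen bonds split by the ligand's role, each role thresholded on
  its own occurrence: ligand-acceptor events yield an HBA, ligand-donor
  events an HBD (one residue can legitimately yield both — a hinge
  backbone donates and accepts simultaneously);
* π-stacking yields an Aro at the mean ligand ring centroid;
* hydrophobic contacts yield Hyd features at the mean closest apolar
  carbon; features whose anchors lie within a 1.5 Å merge radius
  collapse into one, single linkage, with an occurrence-weighted
  centroid — this is how contacts of several pocket residues with one
  ligand region become a single element;
* salt bridges and cation–π have no feature type in the HBA/HBD/Aro/Hyd
  vocabulary and are skipped.

Feature centers are centroids over qualifying frames of the ligand-side
anchor, radii default to 1.0 Å (the Pharmit default; per-feature
configurable), and every feature records its provenance
(`chain:resnum resname itype`). Co-located duals (`add_colocated()`)
share one center and one co-location group: a conformer may satisfy
either member, and the group counts **once** toward the match minimum —
counting both would double-weight one position.

The packaged reference model (`ck1e_reference_model()`) reproduces the
published eight-element composition for the CK1ε catalytic site — HBA,
HBD1, HBD2, Aro1+Hyd1 co-located, Hyd2+Aro2 co-located, Hyd3; 6 distinct
positions; minimum match 6. Its **coordinates are synthetic**: the
original geometry is not published, so the packaged file
(`ck1e_elements_synthetic.json`, named accordingly) lays the elements
out on the described triangular hinge/buried/phosphate arrangement.
Tests assert composition, never absolute geometry.

## Matching and screening

`match_pharmacophore()` searches injective assignments of positionally
distinct elements to conformer feature points of compatible kind. Each
candidate assignment is evaluated by a least-squares rigid fit
(Kabsch/SVD) of the assigned pairs; it is accepted when every fitted
deviation is within that element's radius, and the best assignment
maximizes matched count with ties broken by lowest total deviation. The
search is exact, not heuristic: a branch-and-bound over elements with a
pairwise pruning rule (two points can serve two elements only if their
separation matches the element separation within the radius sum — a
necessary condition under any rigid transform, by the triangle
inequality). The unit tests hold it to exact agreement with an
unpruned exhaustive search.

`screen_library()` applies the filters in the published order and with
the published boundary conventions: molecular volume **strictly
greater** than 270 Å³ eliminates before matching (the cheaper filter
runs first); at least 6 matched elements makes a conformer a hit; any
hit conformer makes its compound a hit. `pose_agreement()` compares the
pharmacophore-placed conformer with a docked pose by heavy-atom RMSD
without refitting and selects **strictly below** 1.5 Å.

Molecular volume is a voxel count: centers of an absolute-lattice grid
(spacing 0.2 Å by default) falling inside any Bondi van der Waals
sphere. Anchoring voxel centers at integer multiples of the spacing
cancels most surface bias (a single carbon evaluates within 1% of the
analytic sphere; halving the spacing moves fixture volumes by < 0.5%).

Whether the "at least six elements" rule should apply to the full
model, a reduced submodel, or both is a genuinely open choice;
`min_match` is therefore
an explicit parameter of the model, `match_pharmacophore()` and
`screen_library()`, with 6 as the default everywhere.

## Consensus pose clustering

`pose_rmsd()` is computed in the common receptor frame **without**
re-superposition — docked poses are already placed — over heavy atoms
in identical order (no symmetry-equivalent atom remapping; poses come
from one engine run on one input molecule). `hierarchical_cluster()` is
a hand-rolled complete-linkage agglomeration that merges while the
smallest complete-linkage distance is **strictly below** the cutoff
(default 2.0 Å). Complete linkage is the only standard linkage under
which "all subcluster members are mutually within the cutoff" is a
theorem rather than a hope, and owning the ~30-line agglomeration is
the only way to make the strict boundary exact — `stats::hclust` +
`cutree` would include merges at exactly the cutoff height. `hclust`
remains in the test suite as the independent cross-check on randomized
matrices.

The representative is the **medoid** (minimum mean RMSD to the other
members), with ties broken by better docking score, then lowest index.
Scores are treated as energy-like: lower is better, matching the
conventions of the docking engines this workflow consumes. The
consensus binding mode is the largest subcluster (ties: better mean
score, then lowest member index); supplying a reference pose reports
the representative-vs-reference RMSD, the number a redocking validation
quotes.

## Trajectory metrics

Backbone RMSD superposes each frame on the reference frame (default:
the first production frame — no standard exists, so this is a
documented, configurable default) over N/CA/C/O by the Kabsch
algorithm, then reports the RMSD over those atoms. RMSF superposes all
frames on the time-average structure — two refinement passes: align to
frame 1, average, re-align to the average, re-average — and reports the
per-residue Cα fluctuation about its mean position. An independent
quaternion (Horn) superposition serves as the numerical oracle in the
tests (agreement to 1e-6 Å). Salt-bridge prevalence is the
occurrence-percent of frames in which two named residues' charged-group
centroids sit within the salt-bridge cutoff.

## The synthetic world

The generators state one fixed world; their defaults were chosen once
from reported conditions for kinase-inhibitor MD studies, and the tests
measure the package against that world rather than tuning it.

* `make_pocket()` builds a minimal catalytic site: one residue per
  planted interaction (hinge-like leucine accepting the ligand amine's
  hydrogen bond at 2.9 Å, a serine backbone donating to the ligand
  carbonyl at 2.9 Å, a phenylalanine stacked parallel at 4.3 Å — rotated
  30° so no carbon pair slips inside the hydrophobic cutoff, a leucine
  side chain at 3.5 Å from the ligand methyl, and a lysine/glutamate
  pair giving ligand and protein–protein salt bridges at 3.0/3.2 Å).
* `make_trajectory()` switches each planted interaction on with its
  per-frame probability and otherwise displaces the partner residue two
  Ångström beyond the relevant cutoff, then adds 0.05 Å Gaussian
  jitter. The off-displacement margin means thermal jitter can never
  flip a planted state: detected counts equal the Bernoulli draws
  exactly, which the tests verify by replaying the RNG stream. Default
  probabilities (0.99, 0.88, 0.31, 0.63, 0.80) restate reported
  occurrence levels for kinase-inhibitor complexes: a near-permanent
  hinge bond, the low end of the hinge range, stacking near 31%, a
  frequent hydrophobic contact, a frequent salt bridge. The default 200 frames is a test-scale stand-in
  for the 15,000-frame production analyses (the arithmetic of which is
  tested directly); recovery tests use 2,000 frames.
* `make_pose_set()` plants 96 poses (12 scoring/search combos × 8
  ranks, labels like `pO-1`) around two modes 10 Å apart — dominant
  mode two thirds of poses with better scores, rigid jitter 0.3 Å — so
  subcluster sizes, mode recovery and tie-breaking are all checkable
  against ground truth.
* `make_conformer_library()` plants hits whose feature points sit
  within a quarter radius of the model centers (a bound under which the
  global rigid fit provably cannot push any deviation past the radius)
  and decoys that keep at most `min_match − 1` correct positions while
  scattering the rest beyond the model's footprint plus 3 Å — far
  enough that no rigid fit can recruit a sixth element. Hits and decoys
  are recorded in the names, so screens are graded exactly.

All generators run under one seeded Mersenne-Twister stream and restore
the caller's RNG state; fixtures are bit-reproducible per seed.

What a green test does **not** establish: the pocket has no force
field, no sterics, no chemistry beyond the typing rules; decoys are
geometric, not chemically plausible; the synthetic trajectories have no
correlated motions, so RMSD/RMSF numbers describe the planted
displacements, not protein dynamics. The suite demonstrates that the
*measurement machinery* is exact — detectors against brute-force
oracles, clustering against `hclust`, the matcher against exhaustive
search, recovery of planted probabilities within binomial error — not
that any biological conclusion follows.

## Numerical and design choices

* Indices are 1-based internally (R convention); conversion to PDB
  serials and SDF atom numbering happens only at the I/O boundary.
* Coordinates are Ångström throughout.
* PDB writes 3 decimals; round-trip tests assert at format precision.
* SDF bond blocks are authoritative; distance-based bond inference
  (1.3 × covalent radii sum) runs only on request. Pre-annotated
  feature points survive SDF round-trips as a JSON-encoded data field.
* Rounding of percentages is half-away-from-zero (see above); R's
  `round()` (half-to-even) would print 21.58 where 21.59 is expected.
* Degenerate inputs: empty relevant set → empty feature list, not an
  error; an empty model or a model smaller than `min_match` never
  matches; singleton clusters are their own medoid; zero-frame
  trajectories and zero-atom structures are rejected at construction.
* The CLI (`run_cli()`, thin wrapper in `inst/cli/trajpharm`) writes a
  `manifest.json` per run with every parameter including defaults;
  reruns with the same inputs and seed are byte-identical.

## Known limitations

Halogen bonds, water bridges and metal coordination are not detected
(the profiles this package reproduces never report them). Binary
trajectory formats (XTC/DCD) are not read; convert to multi-model PDB
upstream. No symmetry-aware pose RMSD. Protein typing covers the twenty
standard residues; nonstandard residues are silently untyped rather
than guessed. MM-PBSA energetics, structure repair, protonation-state
enumeration and docking itself are out of scope by design.
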