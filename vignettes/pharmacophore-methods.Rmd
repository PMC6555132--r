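---
title: "Pharmacophore models, geometric matching and screening statistics in sigmaphore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore models, geometric matching and screening statistics in sigmaphore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmaphore)
```

## The model

A pharmacophore here is the classic Catalyst-style object: a named set of
typed chemical features, each a sphere in a model-local Angstrom frame,
plus a set of excluded-volume spheres encoding the receptor wall. The
feature vocabulary is PI (positive ionizable), HBA/HBD (hydrogen-bond
acceptor/donor, optionally with a projected point marking the partner
position), HYD (hydrophobe), HYD_AR (hydrophobe that also accepts
aromatic rings) and AR (aromatic ring with a normal projection). A ligand
conformer *matches* a model when an injective, kind-compatible assignment
of its perceived features to the model features exists such that, after
least-squares superposition, every mapped feature lies inside its
tolerance sphere, every constrained projection lies inside its projection
sphere, and no heavy atom enters an excluded volume.

The package encodes a library of sigma-1 receptor (σ1R) models around
this machinery: a structure-derived model (`5HK1-Ph.A`: one PI, a
proximal HYD at 3.7 Å with 0.8 Å tolerance, two distal HYDs at 7–13 Å,
21 excluded volumes), its curated derivative (`5HK1-Ph.B`: the two
distal HYDs averaged into one feature with tolerance 3.0 Å, the
proximal tolerance widened to 2.2 Å, excluded volumes unchanged, and
non-basic amidines/guanidines excluded from the PI mapping), four
reproduced literature models (`Langer-Ph`, `Gund-up/down-Ph`,
`Zampieri-Ph`, `Banister-Ph`) and the distance-only `Glennon-Ph`
(PI–HYD at 2.5–3.9 Å and 6–10 Å, no angle constraint).

### Coordinate provenance

The source descriptions of these models print distances, feature counts,
tolerances and edit operations, but not full coordinate sets. The
shipped geometries are therefore *constructed embeddings*: coordinates
chosen in a model-local right-handed frame to satisfy every printed
distance and count simultaneously. Because ligands are always aligned
into the model frame, any consistent embedding of the same distance
facts produces the same qualification decisions up to the unprinted
degrees of freedom. Each model records this in its `provenance` field,
and all screening code is config-driven (`load_model()`/`save_model()`,
the versioned `pharmjson/1` dialect), so refined coordinates can be
dropped in without code changes. The 21 excluded volumes of the
structure-derived model are likewise a constructed pocket wall: rings of
1.2 Å spheres around the feature axis at a clearance consistent with
ligands that fit the features, plus a cap beyond the proximal
hydrophobe.

## Feature perception

Feature definitions are explicit and versioned, not proprietary: each
kind carries include and exclude patterns in a documented subset of the
SMARTS language, matched by the package's own backtracking subgraph
matcher (no installed R package exposes substructure matches with atom
indices). Defaults:

* **PI** — protonated or protonatable amines (`[N+]`, aliphatic `[NX3]`
  with amide/sulfonamide/aniline exclusions), amidines and guanidines
  placed at the group centroid. `nonbasic_amidine_patterns()` removes
  aryl-conjugated and acylated amidines/guanidines, the customization
  carried by `5HK1-Ph.B`.
* **HBA/HBD** — N/O acceptors with a lone pair and N/O–H donors. A 3.0 Å
  projected point is placed along the idealized partner direction
  (opposite the mean bonded-neighbor direction). A linear environment
  (e.g. a symmetric ether) has no preferred direction and carries no
  projection; this keeps perception exactly equivariant under rigid
  motion.
* **HYD** — contiguous groups of two or more apolar heavy atoms
  (carbons without N/O/P neighbors, thioether sulfur, halogens on
  aromatics) merged into one centroid feature per group, mirroring the
  one-feature-per-hydrophobe convention that keeps assignment
  enumeration tractable.
* **AR** — aromatic rings of size 5–7 (Hückel-style perception on the
  Kekulé connection table), centroid plus a 3.0 Å normal projection.
  Ring normals are direction-free: the matcher tries both orientations.

Kinds are deliberately not disjoint — an aromatic ring is both AR and
HYD, as in standard pharmacophore practice.

## Matching

`enumerate_hypotheses()` generates injective kind-compatible assignments
with pairwise-distance pruning: a pair of mapped features survives only
if the model and ligand inter-feature distances agree within the sum of
the two tolerances. This bound is conservative (by the triangle
inequality a violating pair can never both land inside their spheres),
so pruning never removes a qualifying pose. `align_and_score()` then
superposes the mapped ligand points (plus constrained projection points)
onto the model by the Kabsch algorithm and scores

> FitValue = Σ over mapped features of w · max(0, 1 − (d/t)²),

maximal (the weight sum) when every feature is centered and zero at the
sphere boundary. The exact commercial FitValue function is unpublished;
this form reproduces the behavior screening relies on — a smooth,
weight-linear ranking of geometric fit quality — and is stated here as
the package's definition. Omitted features contribute zero and their
spheres are ignored. Ties between equally scoring poses break by smaller
maximum displacement, then lexicographically smallest assignment, making
`screen_library()` fully deterministic.

Degenerate hypotheses (one mapped point: pure translation; collinear
point sets: the SVD minimizer with proper-rotation correction) follow a
documented convention rather than erroring. Exclusion tests use atom
centers against sphere radii; the shipped radii are calibrated for
center tests, not van der Waals surfaces.

The conventional virtual-screening protocol is the default: omission of
features is not allowed (`max_omitted = 0`), each conformer is mapped
separately, and only the best-scoring qualifying conformer represents a
compound. Two published protocol variants are first-class operations:
`gund_dual_direction_screen()` screens with the "up" aromatic
projection and re-tests every passing pose *in place* (no re-fitting)
against the inverted projection, and `langer_affinity_mode()` screens
with all-but-one omission allowed so every compound mapping at least one
feature receives a weighted score (a ranking, not a Ki estimate; the
original per-feature weights were published separately, so configs
accept user-supplied weights and default to 1).

### Flexible fit

"Slight conformational modification" is made testable by a hard cap:
torsion-space coordinate descent (rotatable single bonds, re-aligning
rigidly after each trial move) may improve the fit as long as the
heavy-atom RMSD from the input conformer stays within 0.5 Å. The
descent maximizes qualification first (total tolerance excess, with
clash penalties) and FitValue second, and always returns an iterate at
least as good as the rigid start, so flexible scores dominate rigid
scores compound-by-compound.

## Screening statistics

`enrichment_factor()` implements the standard early-recognition ratio
EF = (Actives_sel/N_sel)/(Actives_total/N_total); the selection size is
x% of the database rounded half away from zero with a floor of one
compound (rounding at the cut is not specified in the source
descriptions; this choice is documented and fixed). Pharmacophore
rankings are tie-heavy — non-hits carry no score at all — so tied
groups straddling the cut contribute *expected* counts, which makes EF,
TPR and TNR independent of any arbitrary ordering within a tie group.
`roc_auc()` is the rank-based (Mann–Whitney) AUC with average ranks for
ties; the whole non-hit mass shares one bottom tie. Whether the original
whole-database ROC ranked non-fitting compounds this way or dropped them
was not stated; tying them is the deterministic, order-free choice and
is used throughout. The hit rate is HR = 100·EF/EF_ideal with
EF_ideal = min(Actives_total, N_sel)/N_sel ÷ (Actives_total/N_total),
an exact identity that also holds for the printed values of the
reference study within rounding (the last-digit pattern of those tables
suggests they were computed from unrounded EFs, which is what the
package does).

`sigma1_affinity_distribution()` ships the printed affinity-bin
composition of the 25,676-compound reference dataset (4,766 actives at
Ki ≤ 1 µM, 18.6%); the activity rule itself is
`classify_activity()`: active iff Ki ≤ 1000 nM, inactive above or when
only an inhibition below 50% at 1 µM was measured, unknown otherwise.

## Diversity descriptors

`fingerprint()` provides extended-connectivity-style circular
fingerprints implemented directly on the connection table: atom
environments of bond diameter 4 or 6, keyed either on
element/degree/H-count/charge/aromaticity/ring membership
(`circular_atom_type`) or on pharmacophoric classes
(`circular_functional_class`). Environment identifiers are canonical
strings rather than folded hash bits, so the diameter-6 feature set
contains the diameter-4 set by construction and Tanimoto arithmetic is
collision-free. MACCS-type public structural keys are computed through
OpenBabel. `pairwise_diversity()` reports mean, median and mode of all
pairwise Tanimoto distances; the mode uses 0.01-wide bins reported at
the bin center with ties broken toward the lower bin (bin width and
tie-break are unstated in the source and fixed here).

## Synthetic benchmark data

The reference screening library is proprietary, so every end-to-end
claim is exercised on constructed data with known ground truth.
`generate_ligand_library()` builds actives fragment-on-scaffold: a
charged amine posed at the PI center, C₂/C₃ alkyl groups at hydrophobe
centers, benzene rings at aromatic features (normals oriented to any
constrained projection), imine or ether termini for acceptors — each
jittered by an isotropic Gaussian (default σ = 0.4 Å, chosen so that
features stress but essentially never leave 1.6 Å-class tolerance
spheres) and joined through ether-oxygen bridges so hydrophobe
perception keeps the groups distinct. Decoys violate the model by
construction (`missing_feature`, `shuffled_geometry` — distances
rescaled beyond every pruning bound — or `clashing`, an atom inside an
excluded volume) and each decoy is *verified* non-matching before it is
accepted. `generate_ranking()` draws scores from two unit-variance
Gaussians at the separation solving the binormal relation
AUC = Φ(δ/√2), with the reference composition (18.6% actives of 25,676)
as the default shape. Everything is bit-reproducible from the seed.

What these generators deliberately do not emulate: force-field-quality
geometry (bond lengths across bridges are unphysical; the matcher
consumes geometry only), conformational ensembles of real drug-like
molecules, and the label noise of experimental Ki values. Passing the
end-to-end suites therefore demonstrates the correctness of perception,
matching, ranking and statistics — not prospective screening performance
on a real vendor library.

## Structure-derived model generation

`derive_pharmacophore()` follows the receptor–ligand recipe: perceive
all ligand features on the bound conformer, keep a feature only when an
interaction rule fires (ionic contact ≤ 4.0 Å between PI and a
deprotonated acidic receptor atom; ≥ 3 apolar receptor atoms within
4.5 Å of a hydrophobe; hydrogen bonds at ≤ 3.5 Å with ≥ 120° approach;
ring-centroid stacking ≤ 5.0 Å), then place 1.2 Å exclusion spheres on
all receptor heavy atoms within 5.0 Å of the ligand that are not
partners of a kept interaction. All cutoffs are standard literature
values and overridable via `interaction_rules()`. Toy complexes with
designed ground truth (`generate_toy_complex()`) pin each rule down in
tests; `read_pdb_atoms()` (bio3d) feeds real structures in.

## Conformers and ionization

`generate_conformers()` implements the systematic fallback protocol:
torsion driving at 60° increments for sp³–sp³/sp³–sp² bonds and 180°
for sp²–sp², followed by de-duplication at 0.3 Å best-fit heavy-atom
RMSD (the threshold is the package's choice; it prevents grid blow-up).
The force-field minimization that a modeling suite would append is
intentionally omitted: the matcher never consumes energies, only
geometries, and the embedded base geometry (OpenBabel distance-geometry
3D generation) is already strain-relaxed. Racemic or grouped stereo
markers pool both mirror-image conformer sets under one compound
identifier; for molecules with several racemic centers this enumerates
the two global mirror forms, not every diastereomeric combination — a
documented simplification. `enumerate_ionization_states()` applies the
threshold-5 rule — protonate bases with pKa above 5, deprotonate acids
below 5, successively on the previous state, pooling every intermediate
and dropping duplicates — with pKa values from a small substructure rule
table (amine ≈ 10.5, amidine ≈ 11.1, aniline ≈ 4.6, carboxylic acid
≈ 4.2, phenol ≈ 10, tetrazole ≈ 4.9) standing in for a commercial
predictor; per-atom user overrides take precedence.

## Problem sizes used in the shipped checks

The validation suite runs at desk scale: matcher–oracle equivalence on
100 random instances of up to 4 model features; metric calibration on
200 label permutations (EF and AUC) and 1,000 random rankings (HR
identity); end-to-end enrichment on five seeded libraries of 50 actives
and 200 decoys against `5HK1-Ph.B`; flexible-versus-rigid dominance on
a 30-compound library. These sizes give stable statistics (the
permutation means are quoted with ±0.02–0.05 bands) while keeping the
whole suite fast enough to run routinely.

## Known limitations

* Printed distances under-determine the reproduced models; screening
  results depend on the unprinted degrees of freedom of any embedding.
* The SMARTS subset omits recursive patterns; the shipped definitions
  are written within the subset, but arbitrary user SMARTS may not be.
* Aromaticity perception is Hückel-lite on Kekulé input; exotic
  ring systems (fused charged heteroaromatics, 7-membered aromatics)
  may be missed.
* The flexible fit is a local coordinate descent under an RMSD cap, not
  a global conformational search; it can miss rescues requiring
  correlated torsion moves.
* Synthetic actives are geometric idealizations; no claim is made about
  synthesizability or real-library screening performance.
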