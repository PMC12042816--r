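---
title: "Interaction fields for weak hydrogen bonds: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction fields for weak hydrogen bonds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifkit)
```

# The problem

CH/π and CH/N interactions are weak hydrogen bonds (roughly 0.5–3
kcal/mol) that fine-tune how nitrogen-containing heterocyclic ligands sit
in protein binding sites. Their 3-D preferences — where around a pyridine
or indazole a methyl or aryl C–H donor likes to be — are not captured by
classical force-field terms, and the dimer energies that do capture them
require dispersion-corrected DFT on thousands of configurations. `mifkit`
implements the surrounding pipeline: the scan geometry, probe placement
and normalization; the contraction of a scanned field into a closed-form
Gaussian expansion; contact-density maps from crystal-structure scatter;
and the projection of fitted fields into protein/ligand complexes. The
quantum engine itself is deliberately out of scope: the scan talks to any
energy backend satisfying a small contract, a classical Lennard-Jones +
Coulomb backend is included for desk-scale work, and counterpoise dimer
inputs can be emitted for an external program.

# Molecular frame and scan grid

The frame (*o-uvw*) puts the origin at the centroid of a user-chosen ring
atom set. *w* is the least-squares normal of the ring plane (SVD of the
centred ring coordinates); for planar rings this equals the exact plane,
and for puckered rings it is the natural generalization — the package
always fits rather than picking three atoms, so frames vary continuously
with geometry. *u* points from the origin toward a designated heavy atom,
projected into the plane orthogonal to *w* so that orthogonality is exact
even when that atom is slightly out of plane, and *v* = *w* × *u*
completes a right-handed triad.

The sign of a plane normal is geometrically ambiguous. We fix it by
requiring the largest-magnitude component of *w* to be positive, which
makes the output deterministic. Under an arbitrary rigid rotation of the
molecule the recovered *w* may therefore be minus the rotated original
(with *v* flipping accordingly); for the symmetric aromatic targets this
toolkit addresses, the field is mirror-symmetric about the ring plane and
the choice is physically immaterial.

Grid points live on spherical shells: radii 2–7 Å in 0.2 Å steps, polar
angle 0–180° from +*w* and azimuth 0–360° from +*u* toward +*v*, both in
10° steps by default. Coincident points are merged — azimuth 360° is
identified with 0°, and each pole contributes a single point per radius
(the azimuth-0 representative) — giving the closed-form count
r·((p−2)·a + 2): 26·(17·36 + 2) = 15,964 for the default spec. Ordering
is radius-major, then polar, then azimuth, and a pairwise-distance
deduplication tolerance of 1e-8 Å is asserted in tests.

# Probe placement and the energy backend

Each probe is a rigid monomer at a standard experimental geometry
(methane r(CH) = 1.087 Å tetrahedral; ethylene r(CC) = 1.339 Å,
r(CH) = 1.086 Å, ∠HCC = 121.3°; benzene r(CC) = 1.397 Å,
r(CH) = 1.084 Å; acetylene r(CC) = 1.203 Å, r(CH) = 1.063 Å). The donor
vector **M** runs from a donor carbon along one C–H bond; the particular
C–H is immaterial by symmetry, and the donor carbon — not the hydrogen —
is placed exactly at the grid point, so grid positions correspond to
donor-carbon positions, the same convention density maps use when they
select carbon atoms.

**G**ₙ points from the grid point to the nearest target site, where sites
are the real atoms plus one dummy at the centroid of every flagged
aromatic ring (fused bicyclics get one per ring). Ties resolve to the
lowest site index, dummies ordered after atoms. The probe is rotated
about its donor carbon by the minimal rotation taking **M** onto **G**ₙ;
the antiparallel case rotates 180° about the normalized **M** × **e**,
with **e** the lab axis least aligned with **M**.

One degree of freedom remains: the torsion about the aligned axis. No
published convention pins it down, so the package fixes it
deterministically by rotating the probe's secondary reference vector (its
second C–H for methane, the C=C direction for ethylene, the next ring
carbon for benzene) as close as possible to the frame's *w* axis; linear
probes skip the step. This is a documented convention, not a
reconstruction of any particular prior choice — for high-symmetry probes
at typical distances the energy dependence on this torsion is small.

A backend is any function `(target_elements, target_coords,
probe_elements, probe_coords) -> kcal/mol` that is deterministic and
returns negative values for attraction. Backend errors and non-finite
returns become failure markers; the scan never aborts. Normalization maps
raw energies to [0, 1] on the most stable value: Eₙ/min(E) for attractive
points, 0 for repulsive or failed points, so 1.0 always marks the global
minimum Δ*E*max (undefined when nothing is attractive). The classical
backend uses 12-6 Lennard-Jones with Lorentz–Berthelot mixing plus
Coulomb terms (k = 332.0636 kcal·Å/mol·e²); default partial charges are
zero for every element, so electrostatics are opt-in — the defaults are
meant to exercise the geometry and normalization machinery, not to
approximate DFT energetics.

# Contraction into Cartesian Gaussians

The expansion uses g(u,v,w) = uᵏvˡwᵐ·exp(−α(u²+v²+w²)) with
k+l+m = n ≤ 7 (types s through j). Along its optimal direction a CGF of
order n ≥ 1 behaves as rⁿ·exp(−αr²), which peaks at √(n/2α); we therefore
set α = n/(2·r²max) so each term's maximum sits at a chosen interaction
distance r_max. s-type terms have no radial maximum, so they reuse the
n = 1 rule and share the p-type decay scale — users who prefer another
convention can construct bases directly. Defaults r_max ∈ {2.4, 3.0,
3.6, 4.2, 4.8} Å bracket the observed optima of weak hydrogen bonds
(≈3.6 Å for CH/π measured ring-centre to donor carbon, ≈3.4 Å for CH/N);
crossing all 120 (k,l,m) triples with the five values gives 600 terms
(5/15/30/50/75/105/140/180 per type).

Coefficients minimize Δ = Σₙ w(Eₙ)(Eₙ − E(**r**ₙ))² via the normal
equations A_ji = Σₙ w(Eₙ)g_j g_i, B_j = Σₙ w(Eₙ)g_j Eₙ. The weighting
function is the four-parameter logistic w(E) = d + (a−d)/(1+e^(−b(E−c)))
with defaults a = 5, b = 15, c = 0.5, d = 1: weakly-bound and empty
regions get unit weight, the most favourable regions five-fold weight,
switching at E = 0.5. The parameters are fully configurable and recorded
in the fit report; any parameterization that stays positive on [0, 1] is
accepted.

Numerics: A is symmetrized, solved with `solve`, and on rank deficiency
the solver falls back to an SVD pseudo-inverse at relative tolerance
1e-10; an optional ridge λ (default 0) is exposed because the full
600-term normal matrix on a 15,964-point grid is ill-conditioned (the
five decay scales overlap). λ = 1e-8 suffices to stabilize the full
basis without visibly changing the fit. Fitted values are *not* clamped
to [0, 1]; clamping is a display option on evaluation, so residual
diagnostics (Δ, r², the report matrices) stay faithful to the linear
model. r² is the squared Pearson correlation between source and fitted
values, matching how scanned-versus-fitted scatter is usually assessed.

Evaluation lattices have inclusive endpoints and 2·(half_extent/spacing)
+ 1 nodes per axis — 161³ = 4,173,281 nodes for the standard 0.1 Å, ±8 Å
display cube. Evaluation is chunked (20,000 points per block) so large
lattices never materialize a dense design matrix.

# Density maps

Scatter clouds of contact-atom positions (donor carbons or donor
hydrogens — the role is always recorded, never inferred, because the two
give visibly different maps) are selected within a 7 Å cutoff of the
central substructure, optionally expanded by the substructure's point
symmetry (e.g. the pyridine mirror v → −v), and binned into origin-
anchored, half-open voxels: a point exactly on a boundary goes to the
higher-index voxel. Grid spacing is 0.5 Å for database-style maps and
0.4 Å for comparison maps. Smoothing averages each node with its up-to-26
neighbours; boundary nodes average over the neighbours that exist
(zero-padding is available by flag). Densities are reported as percent of
maximum with iso-masks at 75/50/25 or 80/50. A seeded subsampling utility
covers the situation where far more structures are available than needed
(e.g. picking 500), recording its seed.

The extent of the density grid is a user parameter: published maps do not
state theirs, and the right choice depends on the contact range of
interest.

# Complex projection

Superposition is the Kabsch algorithm on an explicit atom correspondence
(≥3 non-collinear pairs): SVD of the cross-covariance with the
determinant correction, so a proper rotation is always returned and
reflections are impossible; degenerate (collinear) sets are an error. The
recovered transform maps laboratory coordinates directly into the
reference molecule's (u,v,w) frame, where the fitted function is defined.

Two evaluation paths are kept separate by design: lattices
(`map_function`) exist only for export and visualization, while contact
reports evaluate the function *at atom positions exactly*, avoiding
interpolation error. The complex lattice is centred on the ligand-
substructure centroid; with an even node count (200 per axis at 0.1 Å —
8,000,000 nodes) the centre cannot coincide with a node, so nodes sit at
centroid + (i − (n−1)/2)·spacing, a documented half-spacing offset.
Crystal structures rarely resolve hydrogens, so reports use heavy-atom
positions by default and note that observed donor carbons may sit
slightly off the ≥0.8 area (by less than a C–H bond length); an optional
idealized-H extension (1.09 Å toward the frame origin) is off by default.
Near-miss atoms — below the top threshold but at or above the lowest —
are annotated with their value and their distance to the nearest lattice
node reaching the top threshold (that one annotation does use a lattice,
at 0.25 Å, since it asks a question about a region, not a point).

# Synthetic data: what it does and does not show

The fixtures module generates every input the pipeline consumes:

* `toy_ring_molecule()` — a regular planar C₆ ring (1.39 Å bonds) with
  outward hydrogens and an aromatic flag, the minimal target with the
  right symmetry.
* `synthetic_field()` — normalized values clamp(Σ c·g + noise, 0, 1)
  with the generating basis and coefficients attached. Recovery tests
  use even-order terms with positive coefficients scaled so the clean
  field stays inside [0, 1]; then the clamp is inactive, the field is
  exactly representable, and fitting must return the exact coefficients.
* `synthetic_scatter()` — a two-lobe Gaussian mixture at w = ±3.6 Å
  (s.d. 0.5 Å), the CH/π geometry, for density-pipeline tests.
* `toy_complex()` — a ring ligand at a seeded random rigid pose inside a
  4–8 Å shell of "protein" carbons, with the generating pose attached.

These fixtures validate the machinery — frames, alignment, least
squares, binning, superposition — under known ground truth. They do not
establish anything about real energetics: the classical backend is not a
substitute for dispersion-corrected DFT, synthetic scatter has none of
the occupancy/resolution artefacts of crystallographic data, and passing
tests therefore demonstrate correctness of the computations, not
chemical accuracy of their inputs.

# Problem sizes and determinism

The test suite runs the full 15,964-point combinatorics exactly but
keeps scans, fits and lattices small elsewhere (≤ 50-point scan oracles,
20-term fits, ≤ 9³ materialized lattices), which is ample to pin down
code paths whose cost scales but whose logic does not. The acceptance
script performs one full-grid classical scan, one 8,000,000-node complex
lattice evaluation and twenty solver-versus-oracle problems; everything
random is derived from a single seed, and repeated runs with the same
seed are bit-identical.

# Known limitations

* No automatic ring perception: ring atom sets are user-supplied (or
  come from the simple flags the file readers accept).
* The QM backend contract covers single-point dimer energies only; no
  engine output is parsed, and counterpoise arithmetic is limited to the
  three-energy combiner.
* α values are fixed by the r_max rule; non-linear refinement of
  exponents, basis pruning and coefficient uncertainties are out of
  scope.
* Crystallographic symmetry expansion of unit cells is not performed;
  density maps consume already-aligned scatter.
* The w-axis sign convention (largest-component-positive) is arbitrary
  for targets lacking mirror symmetry about the ring plane; users
  needing a chemically meaningful sign should orient their input
  coordinates accordingly.
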