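---
title: "Rigid-body, helical and interface analysis of actin filament models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body, helical and interface analysis of actin filament models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actifil)
library(dplyr)
```

## The problem

Actin switches between at least three subunit conformations: the monomeric
G-form, the F-form it adopts in the canonical filament, and the C-form it
adopts when the filament is decorated with cofilin (the decorated filament
is called *cofilactin*). These transitions are well described as rigid-body
motions: the inner domain (ID, subdomains 3 and 4) and the bulk of
subdomain 1 (SD1) each move as a nearly rigid unit, and the transition is a
rotation of one body relative to the other about a well-defined axis. The
G-to-F flattening is a roughly 15° rotation of the outer domain; the
G-to-C transition is a roughly 6° rotation about a nearly orthogonal axis.
Cofilin binding also changes the helical geometry of the filament — the
genetic (one-start) twist tightens from about −166.6° to −162.1° per
subunit, i.e. the rotation between neighbouring subunits on one long-pitch
strand (Δφ) grows from ~27° to ~36° — and remodels the actin–actin and
actin–cofilin interfaces.

`actifil` implements the computational side of this kind of analysis as a
set of composable, tested operations on atomic models:

1. **structio** — PDB/mmCIF input/output, residue selections, and
   residue correspondence across conformer ensembles;
2. **geometry** — Kabsch superposition, rigid transforms, screw-axis
   decomposition, and inter-domain rotation axes;
3. **rigidbody** — per-residue positional SDs and the two-pass rigid-body
   search;
4. **helical** — filament construction from twist/rise, symmetry fitting,
   strand-rotation conversion, centroid-to-axis distances;
5. **grafting** — rigid-body grafting of cofilin onto F-actin (F-, Gi-,
   Go-site recipes) and hybrid two-strand filaments;
6. **contacts** — van der Waals interface and steric-collision analysis;
7. **synth** — seed-deterministic synthetic fixtures with planted ground
   truth, plus `run_pipeline()`, which chains all stages.

Everything operates on atom-level tibbles (`struct_tbl`), so each step
composes with `dplyr` verbs and the pipe.

## Models and conventions

**Structures.** A `struct_tbl` has one row per atom with author numbering
(`chain`, `resno`, `insert`), atom name, element, coordinates in Å, and a
`het` flag for heteroatoms (ADP, Mg). Alternate locations are collapsed to
the highest-occupancy conformer at read time, so downstream geometry always
sees a single conformer. Filaments additionally carry a `subunit` index;
by convention the helical axis direction points toward the pointed (P) end,
so higher subunit indices are P-end-side, and the two long-pitch strands
are the odd and even subunit subsets.

**Correspondence.** Conformer ensembles are matched by author residue
numbering within matching chain ids — the actin structures being compared
share actin numbering, so no sequence alignment is attempted (a chain map
can re-letter chains first). The *shared core* is the set of residues
present in every member with a Cα atom; anything else is excluded and
reported, which is how unmodelled regions (actin residues 1–6 and the
D-loop 41–49 are disordered in cofilactin) drop out of ensemble statistics.

**Superposition.** `superpose()` computes the least-squares optimal proper
rotation (Kabsch, via SVD, with the determinant correction that forbids
reflections) plus translation, and the post-fit RMSD. Selections with
fewer than three matched pairs, or collinear ones, are rejected: the
problem is then degenerate. Superposition optimality is property-tested
against random rigid transforms, and cross-checked against the independent
`bio3d::fit.xyz` implementation.

**Screw decomposition.** Any non-identity rigid motion is a rotation about
a unique axis plus a translation along it. `rotation_to_axis_angle()`
extracts the direction (antisymmetric part of the rotation, with a
symmetric-part fallback near 180°), the angle in (0, 180], the axial
translation, and a point on the axis. Identity rotations are flagged
`no_rotation`, and asking for their direction is an error rather than a
silent NaN. `screw_axis_between()` implements the inter-domain recipe: fix
one rigid body by superposition, take the residual transform of the other
body, decompose it, and anchor the reported axis at the point nearest the
moving body's centroid so a rendered axis passes through the molecule.
Angles from conformer A to B and from B to A agree (directions flip),
which is also property-tested.

## The two-pass rigid-body search

The per-residue statistic is the positional SD of each Cα across the
aligned ensemble, pooled over the three coordinates:

$$\mathrm{sd}(r) = \sqrt{\tfrac{1}{N}\sum_{i=1}^N \lVert \mathbf{x}_{ir} - \bar{\mathbf{x}}_r \rVert^2}.$$

The divisor is the population size $N$ by default (`divisor = "n-1"` is
available); with isotropic per-coordinate noise σ the expected level is
$\sigma\sqrt{3(N-1)/N}$, which the tests verify by direct simulation.

`rigid_body_search()` then runs two passes: align on a seed region (for
actin, the ID, residues 138–336), keep residues inside it with SD < 1.0 Å
as a putative body; re-align on the putative body and keep residues with
SD < 0.7 Å as the final body. Membership uses strict `<` at both
thresholds. Final-pass SDs are reported for *all* shared-core residues, so
membership outside the seed region is visible (this is how SD1-body
residues appear when the search is seeded from the ID and vice versa).
Residues whose SD sits within ±0.05 Å of the final threshold are flagged
`borderline` — residues essentially on the cut (SDs like 0.72 or 0.62
against a 0.7 Å threshold) co-move with the body for practical purposes
and deserve explicit judgement rather than silent exclusion. Exactly two
passes are run by default; `iterate = TRUE` repeats the second pass to a
membership fixed point for users who want a self-consistent body.
Monotonicity in the final threshold (raising it never removes residues)
is property-tested across random ensembles.

## Helical geometry

`helical_symmetry(twist, rise)` uses the signed genetic twist per subunit
(negative = left-handed). The strand-rotation conversion is the closed
form Δφ = normalize(2·twist + 360) into (−180°, 180°]: one strand step is
two genetic steps, so −162.1° gives Δφ = 35.8° and −166.6° gives 26.8°.
The conversion's domain is closed at −180° (the straight-ladder limit,
Δφ = 0) even though constructed symmetries keep twist in (−180°, 180°].

`build_filament()` applies the screw operator per subunit and renames
chains from a 62-name pool (chain-name exhaustion is a hard error).
`fit_helical_axis()` inverts it: consecutive subunits are superposed
(atoms matched by residue number and atom name, ignoring the per-subunit
chain ids), each step is screw-decomposed, and the axis is oriented so
the rise is positive. Per-step twist/rise residuals are attached, and a
spread above 5° triggers a warning rather than a silent average — a
filament whose steps disagree that much is not one helix. At least three
subunits are required.

`centroid_axis_distance()` reports the perpendicular distance from the
centroid of the selected atoms to the axis. "Centre of gravity" is taken
as the unweighted centroid of non-hydrogen atoms: deposited models carry
no hydrogens, and on something the size of an actin protomer mass
weighting moves the centroid by well under 0.1 Å (a `mass_weighted` flag
and a Cα-only variant exist for sensitivity checks). The disordered-region
exclusion (`"1-6,41-49"`) is a parameter, defaulted to nothing, because it
is a convention of the comparison being made, not of the geometry.

## Grafting and hybrid filaments

The graft recipes mirror the three-step modelling procedure for placing
cofilin on F-actin. One actin plus one bound cofilin is extracted from the
decorated filament (`extract_site_complex()`; site F pairs the cofilin
with its barbed-side partner, site G with its pointed-side partner — the
axial order of the partners decides which is which). The chosen rigid body
of the donor actin (SD1 for F- and Go-site grafts, ID for Gi-site grafts)
is superposed onto the matching body of a target filament subunit, and
*only the cofilin* is merged — the donor actin is a positioning jig. The
grafted cofilin's internal geometry is untouched (tested to 1e-9 on
intra-chain distances), and grafting is equivariant under rigid motion of
the target.

`build_hybrid_filament()` replaces a stretch of 2–5 same-strand subunits
(plus the cofilins bound wholly within the stretch) with the decorated
conformation, aligned through the ID of the centre subunit; the opposite
strand's atom records are left bitwise identical. For even spans the
centre defaults to the P-end-side of the two middle subunits
(`center_rule = "b_end"` switches), since the pointed-end boundary of a
cofilin cluster is where severing analysis concentrates. The 2–5 span
limit matches the constructed model set; `allow_any_span = TRUE` lifts it.

## Contacts and collisions

An inter-molecular atom pair is an interface pair when its distance is
strictly below 1.1× the sum of the two van der Waals radii, and a steric
collision when strictly below 0.5× that sum, collisions being restricted
to non-hydrogen atoms. The radii default to the Bondi (1964) table
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Mg 1.73, H 1.20 Å) and are fully
overridable; unknown elements are an error unless a default radius is
declared, because silently guessing a radius corrupts counts. The default
implementation prunes candidate pairs with a uniform cell grid (cell edge
= the largest possible interface cutoff) and is tested to be identical to
the exhaustive all-pairs scan on random fixtures. Because the collision
factor is below the interface factor, collision pairs are a subset of
interface pairs by construction. "Number of colliding atoms" is counted as
distinct atoms appearing in at least one collision pair, per molecule,
with the pair-count variant also available, since either convention is
defensible.

## The synthetic generators

The generators produce the study conditions with known ground truth:

* `make_two_domain_ensemble()` plants a rigid body A, a body B rotated by
  per-conformer hinge angles about a planted axis, optional flexible-tail
  residues with 5× noise (a qualitative stand-in for D-loop-like
  disorder), and isotropic Gaussian coordinate noise. Body B is laid out
  at least ~10 Å from the hinge axis so that planted rotations of a few
  degrees displace its residues well beyond the SD thresholds. The
  rigid-body acceptance fixture uses 8 conformers, σ = 0.2 Å and hinge
  angles spread over 0–20°, matching an eight-structure comparison with
  sub-Å coordinate agreement in the core.
* `make_decorated_filament()` builds a dummy-protomer filament under exact
  helical symmetry (−162.1°/27.6 Å decorated, −166.6°/27.5 Å bare) and
  places one compact cofilin-like chain per same-strand subunit pair
  (k, k+2), with two deliberate 3.2 Å near-contacts to its partners:
  inside the interface cut, outside the collision cut, so pairing
  detection and collision-freeness both have planted truth.
* `make_clash_fixture()` constructs chains with exactly the requested
  interface and collision counts by placing partner atoms at 3.0 Å or
  1.2 Å from anchors spaced 10 Å apart.

Dummy chains are Cα traces with a pseudo-side-chain atom: all downstream
mathematics is coordinate- and element-based, so stereochemistry would add
nothing to what the tests can show. What passing on these fixtures does
*not* show is behaviour on real coordinate error structure (anisotropic,
correlated along the chain), on sequence/numbering mismatches between
depositions, or on the actual actin/cofilin shapes — the deposited-model
checks in the test suite cover those, and run only when the released
accession files are locally available, since they are not redistributed
with the package.

Every generator is seed-deterministic (same seed → bitwise-identical
output, caller's RNG stream untouched) and emits a machine-readable truth
record next to optional PDB output.

## Numerical choices

* Rotations are validated to orthogonality and det = +1 at 1e-9;
  screw round-trips hold at 1e-9.
* The screw direction uses the antisymmetric part of the rotation when
  `sin θ` is healthy and the dominant column of `R + I` near 180°, with
  the sign fixed against the residual antisymmetric part.
* Collinearity in superposition is detected from the second singular
  value of the cross-covariance (relative threshold 1e-8).
* SD ties at a threshold are exclusions (strict `<`), and the boundary
  band reported as borderline is ±0.05 Å.
* Angle averaging in `fit_helical_axis()` first orients all step axes
  with the first step, so left-handed twists near −162° do not cancel
  against their +198° aliases.

## Problem sizes

The test-suite simulations are sized to exercise every claim while staying
quick: ensembles of 3–8 members with 60–240 atoms per conformer for the
rigid-body properties, 1,000-sample optimality/round-trip sweeps for the
superposition and screw properties, 100 random 40–50-atom molecule pairs
for the contact oracle equivalence, and filaments of 5–11 subunits for
the helical, graft and hybrid stages. `run_pipeline()` on its default
synthetic configuration covers an 8-member ensemble, two 11-subunit
filaments, three grafts and four hybrids in a few seconds.

## Known limitations

* Residue correspondence is by author numbering only; structures with
  renumbered or mutated constructs need an explicit chain map or
  renumbering before ensemble analysis.
* The rigid-body search does not auto-detect hinge regions (no clustering
  of rotation vectors); bodies are seeded by the user and refined by SD.
* No energy minimisation or side-chain repacking follows grafting: small
  steric overlaps that a relaxed model would resolve are reported as-is.
* Helical fitting assumes a single helix (no seam or pseudo-symmetry
  handling) and no map-space refinement is attempted.
* The Gi_l-site analysis is a distance screen; donor/acceptor geometry of
  salt bridges and hydrogen bonds is out of scope.
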