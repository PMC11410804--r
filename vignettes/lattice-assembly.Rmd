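---
title: "Assembling 2D protein lattices from predicted oligomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling 2D protein lattices from predicted oligomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symlattice)
```

## The problem and the model

A surface-layer (S-layer) protein tiles the cell surface as a 2D crystal in
one of the wallpaper groups p1, p2, p3, p4 or p6. Complex-structure
predictors produce finite oligomer models (dimers to hexamers) with
per-model confidence scores; the lattice itself is out of their reach. The
package's premise is that a correct lattice reveals itself through two
*rotational symmetry axes*: if a subchain oligomer model is a genuine piece
of the layer, its chains are related by a single k-fold rotation, and two
such axes with compatible geometry generate the whole plane group.

The pipeline therefore runs: domain identification → subchain truncation
bookkeeping → axis detection → quality filtering → interface clustering →
axis-pair ranking → superposition into a lattice patch → unit-cell
extraction and idealization → mmCIF emission. Each stage is exported on its
own; `run_pipeline()` wires them together.

### Axis detection

For each ordered chain pair, CA atoms matched by residue number are
superposed by least squares and the rigid transform is decomposed into a
screw motion. The consensus axis direction is the principal eigenvector of
the summed outer products of the pairwise axes (a sign-invariant
least-squares fit); chains are then ordered by their angular position
around that axis. Because a partial ring that spans more than 180° wraps in
the angular sort, each observed step between angular neighbors is read as
the nearest *multiple* of the elementary angle. The elementary step Δφ is
refined as the average over all chain pairs of an all-heavy-atom
superposition angle divided by its step multiple: the all-atom fit is used
here because its precision under coordinate noise scales with the full atom
count and spatial spread of the monomer, which matters most for two-copy
(m = 2) models where no cross-pair averaging is available. The axis order
is k = round(360°/Δφ) among the allowed orders (2/3/4/6 in layer mode, plus
5 in capsid mode), accepted when |Δφ − 360°/k| ≤ `angle_tol` (10° by
default) and m ≤ k.

Axis uniformity is enforced per monomer: each chain's CA centroid must lie
within `dev_monomer_max` = 5 Å of its angular predecessor's centroid rotated
by the appropriate multiple of 360°/k about the consensus axis. Layer mode
additionally bounds the screw shift per step (`screw_tol` = 3 Å); capsid
mode does not, since curved arrangements tolerate axial offsets.

### Filters

Four gates run without short-circuiting, so a rejection lists every failing
criterion:

* **Score**: the weighted model confidence 0.8·ipTM + 0.2·pTM must reach
  0.3 at homodimer pre-screening and 0.20 (inclusive) at the symmetry
  stage.
* **Clashes**: an intermolecular clash is a heavy-atom pair closer than
  r_i + r_j − 0.6 Å (vdW radii C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å;
  unknown elements default to 1.70 Å). Relaxed models fail at ≥ 3.0 clashes
  per 100 aa globally — the threshold itself fails, following the "at
  least … are excluded" phrasing — and when any 200-aa sequence window
  holds *more than* 6.0 per 100 aa (the window threshold itself passes,
  following the "only … allowed" phrasing). Unrelaxed limits are 60 and
  120 per 100 aa. The rate denominator is the full protein chain length.
* **Intermolecular β-strands**: residues in inter-chain β bridges (detected
  from backbone hydrogen bonds, below) must not exceed `beta_max` = 0.25 of
  all residues. No standard constant exists for this fraction; 0.25 is
  this package's default and a config key.
* **Interface existence**: at least one inter-chain residue contact at 5 Å.

### Secondary structure

A self-contained backbone hydrogen-bond assignment is used (the external
DSSP binary is not a dependency): amide hydrogens are placed by rigid
geometry, the classic electrostatic energy
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol marks a bond
below −0.5 kcal/mol, two consecutive i→i+4 turns label helices, and
parallel/antiparallel bridge patterns label strands. Only the three states
H/E/C are produced because nothing downstream consumes finer classes.

### Domain identification and subchains

Initial subsections crosslink consecutive secondary-structure segments that
share at least `k_link` = 8 residue contacts at 5 Å. Subsections merge
greedily: the adjacent pair with the highest score
s = contacts / (√min(surface) · √min(length)) fuses, until the best score
drops below `tau_merge` = 0.08 (saturation). The functional form is this
package's own; surfaces are Shrake–Rupley-style numeric areas (probe 1.4 Å,
240 sphere points per atom, deterministic golden-spiral sampling).
Boundaries are then cropped to the cut inside the inter-domain coil that
minimizes cross-contacts, ties resolving to the stretch midpoint. The
five-subchain scheme emits full-length, no-N-terminus, no-C-terminus, and
the first and last ceiling(D/3) *domains* — domain-count thirds rather than
residue thirds, because the truncation scheme is phrased in domains.
Lengths clamp to [120, 1200] aa; a single-domain protein yields only the
full-length spec, flagged.

### Interface clustering

The interface distogram of a complex is the residue×residue minimum
heavy-atom distance matrix between the reference monomer and its +1
neighbor around the axis, capped at `d_cap` = 10 Å and indexed in
full-length numbering so that differently cropped subchains align.
Similarity is the Pearson correlation of binarized contact indicators
(< 5 Å) over the shared index ranges; pairs with fewer than 20 shared
positions simply get no edge. Contact indicators were chosen over raw
distances so that the coefficient measures agreement of the *binding
pattern* rather than of the shared fold. Edges above `w_min` = 0.2 enter an
undirected graph partitioned by the Louvain method; the node order is
canonicalized and the RNG seeded (`louvain_seed` = 17, recorded in the
report) so the partition is deterministic and permutation-invariant. A
cluster's consensus order is a score-weighted vote among members with ties
to the higher order, because several molecule counts pointing at one order
(e.g. trimers stepping 60° joining hexamers) are evidence for that axis.

### Superposition and scoring

The higher-order complex A is aligned with its axis on +z and anchored at
the origin. For each A monomer, a copy of B is superposed over the shared
full-length residues; placement fails as `cannot_connect` without a shared
domain and as `gap_too_large` above `gap_max` = 5 Å overlap RMSD. In layer
mode each placed B axis is re-rotated to vertical about a pivot at the
linker between the shared and non-shared regions (the pre-realignment tilt
is what the bending score measures); in capsid mode the tilt is kept.
Copies of A then propagate over every non-anchor B monomer. Duplicate
placements are recognized in the lattice plane (xy) rather than in 3D,
because noisy re-parallelization can leave small axial offsets between two
routes to the same lattice point.

Scores: `score_clash` = clashes per residue over the merged patch (every
residue in the scored tile counts in the denominator), `score_bend` =
(2/π)·RMSD of the B-axis tilt angles in radians — 0 when flat, 1 at 90° —
and `score_quality` their sum, used to rank candidate pairs. All placed B
copies enter the bending average; the method defines no separate
nearest-neighbor subset, and for a planted lattice all B copies are
equidistant neighbors anyway.

### Termination

Assembly stops, emitting a report instead of a lattice, when any of these
fires: B-axis tilt strictly above 45°; an overlap gap above `gap_max`;
relative deviation of the individual lattice vectors from the averaged cell
above `dev_cell_max` = 0.10; or a non-rigid folding unit, operationalized
as the median pairwise intra-monomer RMSD across chains exceeding
`rigid_max` = 2.5 Å. A single detected axis stops the run with
`one_axis_only` — one rotation center cannot span a plane.

### Cell extraction and the p2 special case

Lattice vectors are the xy translations from the central complex to the
propagated peripheral copies, clustered into collinear families and
averaged with sign alignment. The group follows the maximum axis order
(6 → p6, 4 → p4, 3 → p3, 2 → p2), and the cell snaps to the group
constraints; oblique (p2) cells use the obtuse-angle convention γ ≥ 90°.

Two half-turn axes generate only a one-dimensional frieze — a mathematical
property of the group generated by two 2-fold rotations, not an
implementation limit. A p2 layer therefore needs a third 2-fold axis: when
the top-ranked pair yields collinear translations and another cluster
exists, the assembler augments the tile with the next cluster's
representative and combines the two independent translation families into
the oblique cell. The p2 fixture plants 2-fold axes at the (0,0), (½,0)
and (0,½) sites accordingly.

### p1 and capsid routes

In a p1 layer no rotational axis of order ≥ 2 exists. The p1 route instead
maps the full-length model onto each strongly bound single-domain copy in
full-length/single-domain heterodimers; each mapping is a lattice
translation, and two independent translations (score ≥ 0.20 each,
non-collinear) give the oblique cell directly. The capsid route allows
5-fold axes, skips axis re-parallelization and screw limits, and reports
the inter-axis angles of the assembled tile; for an icosahedral
pentamer/trimer pair this is the vertex-to-face angle of ≈ 37.38°. No
automated closure of the full capsid is attempted.

### Output

The final mmCIF holds the 2D cell embedded in a 3D crystallographic cell
(c = 500 Å, α = β = 90°), the wallpaper-group operators as explicit
`x,y,z` strings acting on fractional coordinates with z unchanged, the
in-plane basis orientation, and the asymmetric unit re-placed in the exact
cell. `read_lattice()` and `expand_lattice()` invert the emission;
emit → read → re-extract is a fixed point of the cell parameters.

## The synthetic generator

`make_monomer()` builds rigid pseudo-proteins: compact bundles of ideal
α-helices (backbone + CB with real element types, so clash and surface code
run unmodified) arranged antiparallel on a ring with 8.5 Å axis spacing,
joined by extended linkers of ≥ 12 residues with domains ≥ 15 Å apart, plus
a 0.03 Å seeded jitter so distinct seeds give distinct rigid monomers.
`make_oligomer()` places m ≤ k copies at 360°/k steps with optional screw
shift and isotropic Gaussian noise. `make_lattice_pair()` builds the full
wallpaper-group coordinates — one bundle domain per axis site, ring radii
fitted by bisection so adjacent copies sit ~4.5 Å apart (inside the 5 Å
contact cutoff, clear of the 2.8 Å carbon–carbon clash threshold even under
the default noise) — and then cuts complex A and complex B sharing one
monomer, exactly as the pipeline expects. Linkers are lifted 16 Å out of
the bundle plane, and the first linker leaves the high-order axis radially
before turning toward the B site, so that the rotated mates' linkers do not
crowd each other around a 6-fold axis. `make_capsid_patch()` cuts a vertex
pentamer and an adjacent face trimer from one icosahedral arrangement of 60
identical subunits sharing one subunit orientation.

What the fixtures emulate: rigid-body symmetry, partial axis
representations, controllable coordinate noise, score sidecars, planar and
curved geometry. What they do not: real protein energetics, side chains,
flexible linkers with physical continuity, prediction-specific error modes
(domain swaps, register shifts), or inter-model noise correlation —
complexes cut from one planted lattice share their common monomer's
coordinates exactly, where independent predictions would not. Passing tests
therefore demonstrate the correctness of the geometry, filtering, scoring
and assembly machinery under the stated noise model, not robustness to
everything a structure predictor can produce.

## Numerical choices and problem sizes

Superposition is SVD-based with the proper-rotation correction;
near-180° rotations recover the axis from the symmetric part of the
rotation matrix. Ties break deterministically throughout (merge ties to the
lower start index, crop ties to the linker midpoint, pair-rank ties to the
higher combined order). Degenerate inputs raise typed conditions
(`cannot_connect`, `gap_too_large`, `one_axis_only`, `p1_insufficient`,
`degenerate_cell`, `no_interface`) that the pipeline converts into stop
reasons.

The test suite exercises planted lattices for p2/p3/p4/p6 at 20 noisy seeds
per group (σ = 0.5 Å, cells 90–170 Å, monomers of two to three 24-residue
domains) and the noise-robustness property at 50 seeds per (k, m) with a
72-residue single-domain monomer — for two-copy models the step-angle
precision is set by the monomer's own size, so a realistically sized domain
is the appropriate test article. These sizes keep the full suite in the
low minutes on one CPU while leaving every claim statistically meaningful.

## Known limitations

* Multi-protein S-layers and automated capsid closure are out of scope.
* The domain-merge score is a stand-in with fixture-calibrated defaults
  (`tau_merge`, `k_link` are config keys); on real proteins they may need
  retuning.
* The β-strand gate's 0.25 fraction is a package default, not a literature
  constant.
* p2 assembly requires a third detected 2-fold cluster; inputs exposing
  only two half-turn interfaces stop with a collinearity reason rather
  than guessing a second cell vector.
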