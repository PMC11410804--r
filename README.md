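# symlattice

Many bacteria and archaea coat themselves with a surface layer (S-layer): a
two-dimensional crystalline array built from a single protein that tiles the
cell surface in one of the five wallpaper groups p1, p2, p3, p4 or p6.
Complex-structure predictors can model small oligomers of such a protein with
good confidence, but they cannot model the infinite lattice. `symlattice`
closes that gap: it takes a set of predicted oligomer models with their
confidence scores, finds the rotational symmetry axes hiding in them, and
assembles two compatible axes into the primitive unit cell of the 2D lattice
— or, with 5-fold axes enabled, into a curved tile of a small icosahedral
virus capsid. It is aimed at structural biologists working on S-layers,
surface arrays and capsids, and at method developers who need a fully
synthetic, ground-truthed test bed for symmetry-assembly code.

## Method

For every oligomer model the package asks whether one rotational axis maps
all chains onto each other. Chain pairs are superposed by least squares
(Kabsch); the transform is decomposed into a screw motion (axis direction,
anchor, angle, axial shift); and a consensus axis is fitted over all pairs.
The axis order k ∈ {2, 3, 4, 6} (plus 5 in capsid mode) is deduced from the
inter-monomer step angle Δφ as k = round(360°/Δφ), so a trimer stepping 120°
is a 3-fold axis while a trimer stepping 60° describes half of a 6-fold axis
(a *partial representation*, filled fraction m/k). An axis is accepted only
if every monomer sits within 5 Å of its predecessor's image under the ideal
360°/k rotation.

Candidate models are gated by the weighted model-confidence score
0.8·ipTM + 0.2·pTM (≥ 0.3 for homodimer pre-screening, ≥ 0.20 at the
symmetry stage), by steric-clash limits (relaxed models: fewer than 3.0
clashes per 100 aa overall and at most 6.0 per 100 aa in any 200-aa window),
and by the absence of excessive intermolecular β-strand pairing. Surviving
symmetry complexes are clustered by binding interface: each complex's
interface distogram (residue–residue minimum-distance matrix between axis
neighbors) is compared to every other by the Pearson correlation of contact
indicators, and the resulting weighted graph is partitioned with the Louvain
method. Each community is one candidate rotational axis of the lattice.

To build the layer, the higher-order complex A is aligned with its axis on
z, copies of complex B are superposed onto each A monomer over their shared
domain, B axes are re-parallelized to z about the linker pivot, and copies
of A are propagated outwards across the B monomers. The patch is scored by

    score_clash   = N_clashes / N_res
    score_bend    = (2/π) · sqrt( mean( φ_i² ) )      (φ_i = B-axis tilts, rad)
    score_quality = score_clash + score_bend

so a flat, clash-free lattice scores 0 and a patch whose neighbor axes are
perpendicular to the central axis scores 1 on the bending term. Assembly
terminates (no lattice is emitted) when a tilt exceeds 45°, when complexes
cannot be connected within the 5 Å overlap gap, when the modeled lattice
constant deviates from the ideal cell, or when the folding unit is not
rigid. Otherwise the lattice vectors are averaged from the central-to-
peripheral translations, snapped to the group constraints (p4: a = b,
γ = 90°; p3/p6: a = b, γ = 120°), and written as mmCIF with the cell,
the wallpaper-group symmetry operators and the asymmetric unit.

A synthetic fixture generator (`make_monomer()`, `make_oligomer()`,
`make_lattice_pair()`, `make_capsid_patch()`) replaces the structure
predictor: it plants pseudo-protein lattices with known cell constants,
noise levels and axis orders, so the whole pipeline is testable at desk
scale with exact ground truth.

## Worked example

Plant a noisy p4 lattice (cell constant 100 Å, coordinate noise 0.3 Å),
detect both 4-fold axes, and assemble the unit cell:

```r
library(symlattice)
cfg <- default_config()

fx  <- make_lattice_pair("p4", a = 100, noise_sigma = 0.3, seed = 11)
cxa <- detect_symmetry(fx$complex_a, "layer", cfg)
cxb <- detect_symmetry(fx$complex_b, "layer", cfg)
print(cxa$axis)
#> symmetry_axis: 4-fold (filled 1.00), delta_phi 89.99 deg, screw -0.03 A
#>   direction (-0.004, 0.001, 1.000), max monomer deviation 0.234 A

lat <- assemble_lattice(cxa, cxb, cfg)
print(lat)
#> unit_cell (p4): a = 100.00 A, b = 100.00 A, gamma = 90.0 deg
#>   4 symmetry operator(s); quality score 0.0032 (clash 0.0000 + bend 0.0032)

emit_lattice(lat, "unit_cell.cif")
```

The detected axis is 4-fold with a 89.99° step — the planted 90° rotation
recovered through 0.3 Å of coordinate noise — and the idealized cell comes
back at the planted 100 Å with γ snapped to 90°. The quality score is the
sum of clashes per residue (none) and the bending score (0.0032,
essentially flat). The emitted mmCIF carries the cell parameters
(`_cell.*`), the four `_space_group_symop.operation_xyz` operator strings
(`x,y,z`, `-y,x,z`, `-x,-y,z`, `y,-x,z`) and the asymmetric unit;
`read_lattice()` + `expand_lattice()` regenerate the full cell contents
from it.

The same stages are scriptable from a shell through the thin CLI at
`inst/scripts/symlat` (subcommands `run`, `domains`, `detect`, `fixtures`,
`report`, `dump-config`), and `run_pipeline()` drives the whole workflow on
a directory of models plus a `scores.json` sidecar.

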