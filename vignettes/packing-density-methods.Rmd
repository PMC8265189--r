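---
title: "Grid-based packing densities and buried cavities: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based packing densities and buried cavities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voropack)
```

## The model

An atom's packing density measures how much of the space that "belongs"
to it is actually filled by the atom itself. `voropack` computes it in
three stages, all on one cubic voxel lattice.

**Solvent-excluded region.** Atoms are hard spheres with united-atom van
der Waals radii. A spherical probe of radius 1.4 Å (a water molecule)
rolls over this body: space where no probe centre fits
(min over atoms of `|x − c_i| − r_i < 1.4`) is probe-excluded; the
probe-feasible space connected to the grid boundary (6-connected flood
fill) is accessible; and everything the accessible probes can sweep —
the dilation of the accessible set by the probe radius, outside the vdW
spheres — is solvent. What remains is the solvent-excluded (SE) region:
the vdW body, the sub-probe crevices between atoms, and any buried
interior space. This is a morphological closing, the standard
rolling-sphere construction of the solvent-excluded surface.

**Weighted Voronoi partition.** Every SE voxel outside a cavity is
assigned to the atom minimizing the additively weighted distance
`|v − c_i| − r_i` (an Apollonius diagram; bisectors are hyperboloid
sheets). Unlike the unweighted Voronoi or power diagram with planes,
this credits each atom with the space up to the surface-to-surface
midline, which is the appropriate notion when radii differ. Ties are
broken deterministically toward the lowest atom serial. The
implementation stamps each atom over a bounded neighbourhood
(`r_i + probe + 2h`) and certifies every voxel whose best candidate lies
within the stamped guarantee; the rare uncertified voxels fall back to
an exhaustive scan, so the production path is *exactly* the brute-force
argmin (this equality is asserted in the tests against an independent R
implementation).

From the owned voxel counts, `V_vdW` (inside the atom's own sphere) and
`V_se` (outside it), the packing density is
`PD = V_vdW / (V_vdW + V_se)`. Residue values pool the atoms:
`PD_res = Σ V_vdW / Σ (V_vdW + V_se)` — a volume-weighted mean, chosen
over the unweighted mean of atom PDs so that a residue's value equals
the PD of its pooled volume (the two differ when atom cells differ in
size; the choice is recorded in the output manifest implicitly through
the package version).

**Burial and cavities.** An atom is *exposed* if any voxel of its vdW
sphere touches (6-adjacency) a solvent voxel, else *buried*. The
operational rule for "exposed" is a choice — alternatives such as "any
positive solvent-accessible area" are not computable on the SE labelling
alone — and the shell-contact rule is deterministic and local. Buried
voids are found from *deep seeds*: probe-feasible voxels that the
boundary flood fill never reached. The void region is the probe-swept
volume of those seeds (their dilation by the probe radius, restricted to
SE voxels), mirroring exactly how the solvent region is built from the
accessible set. Consequences worth stating: a connected SE component is
*not* promoted wholesale (on a sealed shell the outer crevice skin and
the chamber are lattice-connected through sub-probe gap throats, and
promoting the component would relabel the entire surface skin), and
sub-probe crevices contain no seed, so they remain atom-assigned SE
space. Void voxels belong to cavities, not atoms, and are excluded from
`V_se`; this keeps the conservation identity exact in voxel counts:

```
Σ_atoms (n_vdW + n_se) + Σ_cavities n_void = total SE voxel count
```

Cavities are 26-connected components of void voxels (26 for permissive
grouping of diagonal chains of void space, versus the conservative
6-connectivity used for solvent paths). Each gets its volume, centroid,
equivalent-sphere radius (the only scale-free single-number size for an
irregular void), lining residues (atoms whose vdW surface comes within
2.8 Å — one water diameter — of a cavity voxel), and the unweighted mean
of the lining residues' hydrophobicity values, each residue counted
once.

**Cavity types and heteroatoms.** Types 1/2/4 are decided per cavity:
containing heteroatoms (4), heteroatom neighbours only (2), empty (1).
Type 3 — a cavity that exists only because heteroatoms fill it — is
found by rerunning the full geometry without heteroatoms and keeping the
het-free cavities that share no lattice voxel with any standard-run
cavity (grid origins are snapped to a common global lattice precisely so
that voxel identity is comparable across runs). "Contains" is decided
with the het-free rerun too: a heteroatom is contained if the voxel
under its centre is void space once heteroatoms are removed *and* its
vdW surface lies within one probe radius of the cavity. A naive
"centre inside the cavity voxel set" test cannot work, because a
contained molecule carves its own centre out of the void; the het-free
criterion recovers the intended meaning. Without any het-free run the
literal dilated-set fallback applies.

**Water policy.** Keeping only internal waters (the default) classifies
each water with the waters *excluded* from the occluding set — a water
must not shield itself from solvent — and keeps those whose oxygen
centre falls in a buried void voxel of that water-free labelling.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `spacing` | 0.4 Å (0.1 Å high accuracy) | voxel edge; accuracy/speed trade-off |
| `probeRadius` | 1.4 Å | water-sized probe defining SE space and cavities |
| `padding` | `2(probe + r_max) + 2h` | bulk solvent margin; guarantees the grid boundary is solvent |
| `liningCutoff` | 2.8 Å | vdW-surface-to-voxel distance for "lining"/"neighbour" (one water diameter) |
| `snap` | `TRUE` | snap grid origin to a multiple of the spacing (reproducibility, cross-run voxel identity) |
| hydrophobicity cutoffs | 0 and 1.45 | class boundaries on the membrane-insertion scale; the closed interval [0, 1.45] is medium polar |

The radius table bundled in `inst/extdata/united_atom_radii.tsv` is a
reconstruction of the ProtOr-style united-atom class radii (tetrahedral
C 1.88, trigonal CH 1.76, bare trigonal C 1.61, N 1.64, carbonyl O
1.42, hydroxyl/ester O 1.46, S 1.77, nucleotide P 2.04) mapped onto the
standard residues, with per-element fallbacks and a generic 1.70 Å
default; it is not the original published per-type fit, and both it and
the hydrophobicity scale can be replaced by files of the same layout.

## Numerical choices

*Voxel membership* is by centre: a voxel belongs to a sphere iff its
centre is inside — unbiased to first order, and the expectation of the
counted volume over grid offsets is exact.

*Half-voxel dilation compensation.* Dilating the accessible set is done
by thresholding a Euclidean distance transform at
`probeRadius + spacing/2`. The accessible set is quantized to voxel
centres, which sit on average about half a spacing beyond the continuum
boundary along the surface normal; without the `spacing/2` term the SE
surface would be inflated systematically by a comparable amount. With
it, the single-sphere volume test shows residual errors of a few tenths
of a percent with alternating sign across spacings, and strict error
decrease over 0.4 → 0.2 → 0.1 Å. The same threshold is used for the
void dilation, keeping solvent and void constructions symmetric.

*Determinism.* Snapped origins, serial-order tie-breaks, fixed cavity
ordering (descending volume, then centroid) and fixed-column output
formatting make two runs on identical input byte-identical; this is
asserted in the tests.

*Degenerate inputs.* Atoms that own no voxels (for example an atom
engulfed by a larger one) get `NA` packing density and a `noVolume`
flag; residues with zero assigned volume report the sentinel 0 with the
flag. Empty structures, over-cap grids (with advice to coarsen the
spacing) and over-limit batches error before any computation.

## The synthetic study set

No external data is needed: `makeFixture()` generates structures whose
ground truth is known by construction — single spheres (closed-form
volume), dimers (sphere-cap union formula), FCC-clipped clusters
(close-packed interiors with seeded rotation, jitter and a
protein-like mix of class radii), sealed hollow shells (an engineered
chamber; sealing is verified by a sampled covering argument at build
time and independently by a plain-R flood fill in the tests; variants
add a mouth, a central water, or a chamber-filling ligand), and compact
toy polymer chains (glycine-like N/CA/C/O residues on a self-avoiding
walk confined to a globule of radius `2.8 nRes^{1/3} + 3` Å, the scale
of a folded protein of that length).

The grid-accuracy study (`gridAccuracyStudy()`, also driven by
`scripts/acceptance.R`) runs ten such structures (clusters of 50–500
atoms and chains of 15–125 residues, seeds 1–10 by default) at 0.4 Å
and 0.1 Å and reports, per structure, the magnitude of the mean signed
per-atom relative difference in assigned volume and in packing density,
averaged across structures. The *signed* mean is deliberate: individual
atoms carry irreducible voxel-counting jitter at 0.4 Å (a carbon-sized
sphere of ~28 Å³ counts with roughly ±1% noise at that spacing
regardless of any algorithmic quality), and a mean of absolute per-atom
differences therefore has a floor near one percent that says nothing
about systematic accuracy. The signed aggregate cancels that jitter and
isolates the real resolution effect; the per-atom absolute variant is
returned alongside for transparency.

What these fixtures do *not* emulate: chemistry (no bond topology,
protonation or alternate conformers beyond the parser rules), crystal
artefacts, and — importantly for the accuracy study — the dense
side-chain packing of real proteins. The backbone-only toy chains are
much more crevice-rich than real structures, and narrow probe-feasible
channels are exactly where a 0.4 Å lattice loses connectivity and
over-assigns solvent-excluded space (the dominant contribution to the
measured accuracy loss; per-atom vdW volumes themselves agree across
spacings to within a few thousandths of a percent). Passing the study
therefore bounds the method's behaviour on worst-case synthetic
geometry, not its error on any particular real structure.

## Problem sizes

Defaults throughout target a single CPU: the study set spans 50–500
atoms per structure, which at 0.1 Å spacing means grids up to roughly
10⁸ voxels; the full study runs in a few minutes. The voxel cap
(6×10⁸ by default) and atom cap are configurable guards, with errors
that advise a coarser spacing.

## Known limitations

- Volumes, burial and voids all come from one grid substrate; there is
  no analytic (Delaunay/alpha-shape) cross-computation, and surface
  *areas* are out of scope.
- Euclidean dilation has no visibility test: solvent (or void) space can
  "reach through" a wall thinner than the probe radius in pathological
  geometries; at protein-like wall thicknesses this does not occur.
- Cavity types depend on the het-free rerun; for a structure consisting
  entirely of heteroatoms no rerun is possible and the literal
  contained-het fallback applies.
- mmCIF input, NMR ensemble averaging, protonation logic and
  pocket/channel (solvent-accessible) detection are non-goals; only
  buried cavities are reported.
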