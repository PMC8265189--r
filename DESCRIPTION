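Package: voropack
Title: Atomic Packing Densities and Buried Cavities of Macromolecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-atom and per-residue atomic packing densities of
    macromolecular structures by partitioning the solvent-excluded volume
    with an additively weighted (Apollonius) Voronoi scheme on a voxel grid,
    and detects and classifies buried internal cavities. Reads PDB files,
    assigns united-atom van der Waals radii, applies configurable water
    policies, and writes three PDB-formatted result files encoding packing
    density, cavity pseudo-atoms and cavity-lining residues in the b-factor
    and occupancy columns, together with machine-readable tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
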