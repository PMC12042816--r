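Package: mifkit
Title: Molecular Interaction Fields for Weak Hydrogen Bonds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for QM-level molecular interaction fields (MIFs) around
    ring-containing small molecules. Builds molecular coordinate frames and
    spherical probe-scan grids, places and orients probe molecules (methane,
    ethylene, benzene, acetylene) with a pluggable interaction-energy backend,
    contracts scanned fields into closed-form linear combinations of Cartesian
    Gaussian functions by sigmoid-weighted least squares, computes contact
    density maps from fragment scatter clouds with symmetry expansion and
    26-neighbour smoothing, and projects fitted fields onto protein/ligand
    complex structures to report residues inside interaction-formable areas.
    Includes counterpoise dimer input generation, XYZ/SDF/MOL2/PDB readers,
    OpenDX and Gaussian cube volumetric writers, and seeded synthetic fixtures
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
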