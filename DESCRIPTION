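Package: cgmem
Title: Analysis of Coarse-Grained Membrane-Protein Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for coarse-grained (MARTINI-style)
    simulations of membrane proteins embedded in phospholipid bilayers.
    Reads GRO/PDB snapshots, assigns bilayer leaflets and detects lipid
    flip-flop events, computes head-group radial distribution functions
    and annular lipid shells, reconstructs per-leaflet membrane surfaces
    with thickness and deformation maps, profiles per-residue contacts
    with lipid chemical groups and solvent, extracts transmembrane
    topology with B-spline helix diagrams, and aggregates per-residue
    analyses across related structures via multiple sequence alignment
    (contact propensity scales, amino-acid depth distributions, bulk
    thickness summaries). Includes a synthetic-system generator with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    splines,
    jsonlite,
    yaml,
    igraph,
    ape,
    mgcv,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
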