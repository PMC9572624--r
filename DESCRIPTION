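Package: interbond
Title: Detection and Classification of Intermolecular Bonds at
    Protein-Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies intermolecular hydrogen bonds, ionic bonds and salt
    bridges across protein-protein binding interfaces from atomic
    coordinates in PDB format, using geometric and chemical criteria
    (donor/acceptor distances and angles, residue-centroid and charged-atom
    distance cutoffs at physiological pH). Also classifies the effect of
    point mutations on predicted bonds (broken, intact, formed), computes
    binding free-energy changes from equilibrium dissociation constants
    with per-complex min-max normalization, scores predictions against
    curated reference bond lists (precision/recall with unknowable true
    negatives), and generates synthetic structures with planted bond
    geometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    optparse,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
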