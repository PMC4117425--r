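Package: flexsite
Title: Structure-Based Druggability Assessment with Light Protein Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@flexsite.dev", role = c("aut", "cre"))
Description: Detects candidate small-molecule binding pockets on protein
    structures with a fine site-point grid (van der Waals probe energy,
    ray-cast enclosure, hydrophobic/hydrophilic potentials), scores them with
    the Dscore+ druggability score, opens flexible and cryptic pockets with a
    two-stage hydrophobic-probe induced-fit procedure (naphthalene followed by
    a tetra-substituted naphthalene, with greedy side-chain rotamer repacking
    and light backbone relaxation), and classifies sites as druggable,
    difficult, or cryptic-druggable using score and drug-like volume gates.
    Includes a synthetic-receptor fixture generator with analytic ground truth
    and a validation harness for published protein-protein interaction and
    flexible-pocket benchmark tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    ChemmineR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
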