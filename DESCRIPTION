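Package: ncmfp
Title: Scaffold-Based Hierarchical Molecular Fingerprints for Natural Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds hierarchical Bemis-Murcko scaffold libraries from
    class-labelled natural compound collections and encodes molecules as
    fixed-length substructure-key fingerprints composed of scaffold,
    scaffold-fragment connection point (SFCP) and fragment bits. Includes
    library diagnostics (database coverage by scaffold level,
    class-assignment heat maps), a 1-nearest-neighbour Tanimoto
    classification benchmark with repeated 80/20 splits and tenfold
    cross-validation, Y-randomization significance testing, and a seeded
    synthetic compound-set generator so the whole pipeline is testable
    without external databases. Molecule parsing, aromaticity perception
    and canonical SMILES use Open Babel (via ChemmineOB); substructure
    matching uses subgraph-isomorphism search from igraph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
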