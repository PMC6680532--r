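Package: promisite
Title: Promiscuity Analysis of Druggable Binding Sites from Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies and characterizes the promiscuity of druggable binding
    sites (DBS) from collections of protein-ligand complexes. Ligand-proximity
    pockets (5.5 Angstrom heavy-atom contact shells) are extracted from PDB
    structures, superposed across homologous protein chains, and clustered into
    binding sites with an adaptive barycenter cutoff (C = D - k*sigma over the
    observed pocket radii); each site is labelled selective, moderately
    promiscuous or highly promiscuous from the number of distinct ligand
    chemotypes (MACCS-Tanimoto Butina clusters at 0.8) it binds. Includes
    drug-likeness filtering, pocket and ligand descriptor panels, grouped
    cross-validated CART discrimination of promiscuity classes, a bipartite
    site-ligand interaction network, and a synthetic complex generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    methods,
    yaml,
    igraph,
    rpart,
    bio3d,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
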