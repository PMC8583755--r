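Package: gagscape
Title: Conformational Landscapes of Glycosaminoglycan Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis for short glycosaminoglycan (GAG) chains:
    glycosidic phi/psi torsions and the collective dihedral-offset
    descriptor, end-to-end distance, residue contact maps, geometric
    hydrogen-bond counting, cation radial distribution functions and
    proximal-ion counts, neighbour-count (Daura-style) RMSD clustering, and
    a PCA-based free-energy-landscape heuristic with k-means state
    segregation. Includes an idealized chain builder and a synthetic
    conformational-ensemble generator with known mixture structure for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
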