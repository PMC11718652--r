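Package: hybridvs
Title: Hybrid Ligand-Based Virtual Screening with Dual Molecular Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening of SMILES compound libraries
    against a single query molecule. Implements a native SMILES parser,
    Morgan (ECFP-style) circular fingerprints and 2D pharmacophore pair
    fingerprints, Tanimoto/cosine/Euclidean similarity on bit sets,
    K-Means clustering of similarity profiles with elbow-based cluster
    count selection and silhouette validation, and a dual-fingerprint
    consensus hit selection step. Includes a deterministic synthetic
    library generator (planted query analogs among decoy scaffolds) for
    end-to-end benchmarking without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
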