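Package: ssapdiv
Title: Stability-Based Site-Specific Amino Acid Preferences and Their
    Divergence Between Protein Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms per-site mutational stability effects (ddG, kcal/mol)
    into site-specific amino acid preference (SSAP) profiles under three
    biophysical stability-to-fitness models (threshold, maximum and optimum
    stability), simulates replicate profiles with a calibrated correlation to
    the source profile, detects per-site significant SSAP differences between
    homologs with a replicate-aware Jensen-Shannon/RMSD exact permutation test
    under false-discovery-rate control, and relates those differences to
    structural deviation and residue contact-network rewiring. Includes a
    synthetic-data generator (ddG matrices with burial-dependent effect sizes,
    toy 3D structures, perturbed homolog pairs with planted preference shifts)
    so every stage can be exercised without external structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
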