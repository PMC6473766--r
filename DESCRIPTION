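Package: terminomix
Title: Peptide Terminome Deconvolution into Protease Contributions
Version: 0.1.0
Authors@R:
    person("Terminomix", "Developers", email = "maintainer@terminomix.org",
           role = c("aut", "cre"))
Description: Analysis of quantified peptidomes as cleavage-site terminomes.
    Maps peptides to their parent proteins, extracts Schechter-Berger
    cleavage contexts (P2, P1, P1', P2') at both peptide termini, builds
    abundance-weighted 20x4 amino-acid frequency matrices per sample group,
    and decomposes each observed matrix into per-protease contributions by
    simplex-constrained least squares against a panel of protease
    cleavage-site specificity matrices. Also provides label-free
    quantification of cleaved proteins (run normalization, peptide-to-protein
    aggregation, fold changes against a reference group), a synthetic
    digestion simulator with known ground-truth contribution vectors for
    validation, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    stringi,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
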