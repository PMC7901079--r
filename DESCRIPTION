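Package: bgcflux
Title: Metabolic Pathway Reconstruction and Flux Analysis for NRPS and PKS
    Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates antiSMASH-annotated non-ribosomal peptide synthetase
    (NRPS), type 1 polyketide synthase (PKS) and trans-AT PKS biosynthetic gene
    clusters into explicit stoichiometric metabolic pathways, using a
    domain-level reaction calculus for assembly-line biosynthesis. Reconstructed
    pathways are inserted into a genome-scale metabolic model and analysed with
    flux balance analysis: growth-coupled production maximisation and
    brute-force single-reaction knockout scanning for strain design. Includes a
    synthetic-fixture generator for antiSMASH-dialect region GenBank files and
    an analytically tractable toy reference model, so the whole pipeline runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
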