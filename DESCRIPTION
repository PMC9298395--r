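Package: kinrecon
Title: Kinship and Social-Structure Reconstruction for Cooperatively
    Breeding Fish Groups
Version: 0.1.0
Authors@R:
    person("Kin", "Recon", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Marker-based reconstruction of kinship and social structure in
    multi-layered cooperative breeding groups, as studied in polygynous
    lamprologine cichlids. Implements Queller-Goodnight pairwise relatedness
    with relatedness-corrected allele frequencies, likelihood-ratio dyad
    classification with simulated null distributions, pairwise Mendelian
    parentage assignment under growth-derived age constraints, immigrant and
    breeding-tenure reconstruction, bespoke resampling statistics (bootstrap
    ANOVA with Dunnett's C averaging, Gehan-Wilcoxon survival comparison),
    and a forward simulator of polygynous social groups that emits
    ground-truth pedigrees for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
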