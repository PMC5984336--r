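Package: triphase
Title: Triploid Haplotype Assembly from SNP Fragments by Genotype-Constrained Enumeration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the three haplotypes of a triploid individual from
    aligned SNP fragment matrices under the minimum error correction with
    genotype information (MEC/GI) model. Implements the EHTLD greedy
    column-wise enumeration phaser, the standard polyploid phasing accuracy
    measures (reconstruction rate, vector error, MEC score), shotgun and
    454-style SNP fragment simulators with controlled haplotype divergence,
    coverage and read-error rate, and an exhaustive exact MEC/GI solver for
    small instances used as a ground-truth oracle.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
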