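Package: seedopt
Title: Genomics-Assisted Seed Source Selection for Ecological Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for regional admixture provenancing: score candidate
    seed-source populations and all n-population combinations by pooled
    genetic diversity (expected heterozygosity) versus genetic load (the
    frequency-weighted nonsynonymous/synonymous ratio Pn*fn / Ps*fs),
    rank and select optimal source sets, and quantify the evolvability
    (genetic coefficient of variation) gained by pooling sources, from
    seedling monitoring data. Includes a Balding-Nichols genotype
    simulator and a plot-structured field-trial simulator so the whole
    pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
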