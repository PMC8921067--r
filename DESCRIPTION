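Package: scfaprof
Title: Multi-Taxonomy Assignment and Community Phenotype Profiling of
    SCFA-Supplemented Fecal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 16S rRNA amplicon surveys of in-vitro
    fecal communities supplemented with short-chain fatty acids (SCFAs).
    Implements the multi-taxonomy approach (MTA) for assigning amplicon
    sequence variants to reference 16S sequences under the M-(1-M)/4
    identity threshold with "/"-joined consensus names, 16S copy-number
    renormalization of relative abundance tables, probabilistic community
    phenotype profiling (Community Phenotype Index, CPI) from binary
    genome phenotype matrices, alpha/beta diversity and ordination,
    fivefold modulation classification, and exact two-tailed Mann-Whitney
    contrasts for small replicate groups. A seeded synthetic-community
    generator plants known per-strain effects so every stage of the
    pipeline can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
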