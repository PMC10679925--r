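Package: triovar
Title: Rare-Variant Prioritization for Trio and Sporadic Immunodeficiency Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes rare, potentially deleterious variants in small
    family-based disease cohorts such as common variable immunodeficiency
    (CVID) studies. Provides readers for multi-sample VCF with
    ANNOVAR-style annotations, PED pedigrees, gene panels, GMT gene sets
    and CNV/SV event tables; a site-QC and rarity/deleteriousness filter
    cascade with a per-variant audit trail; Mendelian segregation screening
    (de novo, homozygous recessive, compound heterozygous by parental
    origin, X-linked, sporadic case-only and oligogenic aggregation);
    reciprocal-overlap clustering and recurrence screening of CNV/SV
    events; an ACMG-style classification engine; hypergeometric gene-set
    over-representation; cohort summary reporting; and a seeded synthetic
    trio-cohort simulator with spiked causal variants for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
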