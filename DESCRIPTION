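Package: cvscan
Title: Candidate-Gene Discovery for Cyclic Vomiting Syndrome from Annotated Variant Tables
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a rare-variant qualification and gene-level burden
    scoring pipeline for cyclic vomiting syndrome (CVS) candidate-gene
    discovery. Per-variant rules classify annotated nuclear variants as
    recorded, Qualifying (coding, rare, conserved) and Key Qualifying
    (pathogenic/likely-pathogenic by ClinVar majority or loss-of-function, or
    matching a non-CVS paroxysmal clinical diagnosis); mitochondrial variants
    are classified by heteroplasmy bands, secondary-structure conservation
    exceptions and clinical-domain counts. Gene scores (3 points per Key, 1
    per Other Qualifying occurrence) are converted to evidence tiers, combined
    with literature family counts into composite tiers, and compared across
    gene panels with exact tests. Includes packaged gene panels and variant
    tables, Hardy-Weinberg carrier-frequency conversion, recurrent-variant
    enrichment tests against population allele counts, mixed-population
    frequency construction, and a seeded synthetic-cohort generator for
    end-to-end testing without access to protected cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    yaml
Config/testthat/edition: 3
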