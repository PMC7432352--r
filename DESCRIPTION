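Package: graftmobile
Title: SNP-Diagnostic Detection of Graft-Mobile mRNAs in Reciprocal Heterografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies long-distance mobile mRNAs in reciprocal heterograft
    RNA-seq experiments by classifying recipient-tissue reads to their species
    of origin with diagnostic SNPs. Provides consensus transcriptome
    construction from resequencing-style reads (pileup, majority variant
    calling, variant application), mismatch-bounded read alignment by k-mer
    seeding, FPKM quantification, the read-origin classifier with donor
    expression and replicate filters, directionality assignment by comparing
    reciprocal graft combinations, reciprocal-best-hit protein orthology,
    set-overlap summaries, RT-qPCR concordance and delta-delta-Ct utilities,
    and a fully seeded synthetic graft-experiment generator with a ground
    truth manifest for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
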