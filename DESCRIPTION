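Package: tecapture
Title: Screening and Statistics for Transposon-Derived Protein Domain Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the capture of transposable-element (TE) and viral
    protein domains by host multicopy gene families. Implements a eukaryote-wide
    domain co-occurrence screen over InterPro-style annotation tables (taxonomic
    spread, single versus multiple TE-domain architectures, family-size
    association, N-terminal positional bias), a bootstrap test for enrichment of
    TE copies near genes of a given PFAM family (capped window counts, shuffled
    nulls, ECDF empirical p-values, multiple-testing corrected scores), and
    triage of a proteome-wide structural interaction screen (ROC analysis and
    Kolmogorov-Smirnov threshold selection on pTM/ipTM confidences, van der
    Waals clash filtering, per-residue minimum-distance profiles and per-domain
    contact summaries). Seeded synthetic-data generators emulate every input so
    the full pipeline runs and tests without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
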