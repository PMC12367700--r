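Package: pannac
Title: Pan-Genome Analysis of Plant NAC Transcription Factor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for pan-genome characterization of a plant
    transcription-factor gene family across many accessions of a species:
    domain/homology evidence filtering, greedy identity-based orthogroup
    clustering with core/soft-core/shell/cloud classification and copy-number
    matrices, presence/absence and transposable-element characterization,
    simplified duplication typing, Nei-Gojobori (NG86) Ka/Ks estimation with
    nonparametric core-versus-dispensable contrasts, a codon-usage-bias suite
    (RSCU, ENC, CAI, GC3s, PR2, optimal codons), tissue expression summaries,
    fuzzy c-means time-course clustering, and a co-expression plus
    promoter-motif regulatory network with GO enrichment.  A seed-reproducible
    synthetic pan-genome generator with recorded ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    e1071,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
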