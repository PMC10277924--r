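Package: adiposcreen
Title: Dual-Tissue Transcriptomic Screening for Adipose-Origin NAFLD Biomarkers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for screening adipose-origin serum biomarker
    candidates for non-alcoholic fatty liver disease (NAFLD) from paired
    adipose and liver RNA-seq of the same individuals. Implements TMM
    normalization, precision-weighted moderated differential expression,
    cross-tissue "aware" DE sets, the serum-biomarker filter cascade
    (secretion, adipose abundance, adipose/liver enrichment), exhaustive
    best-subset selection with a permutation null, weighted co-expression
    networks with topological overlap, cis-eQTL mapping, approximate-Bayes-
    factor colocalization, instrument selection and two-sample Mendelian
    randomization (Wald, IVW, Egger, PRESSO-style global test), and
    logistic/linear added-value model comparison. A synthetic-data module
    generates all inputs with planted effects so every stage can be scored
    against a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
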