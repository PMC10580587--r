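Package: acetylprio
Title: Prioritizing Histone Acetyltransferase Genes Coupled to EMT Activity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative prioritization of histone acetyltransferase genes in staged
    expression cohorts. Scores per-sample epithelial-mesenchymal transition (EMT)
    activity by single-sample gene set enrichment (ssGSEA), combines two-group
    Wilcoxon differential expression with fold change into a composite rank score
    R = -log10(p) * log2(FC), screens genes by Spearman correlation with the EMT
    score, overlaps the top-ranked up-regulated genes with the positively correlated
    genes into a candidate set, and validates candidates by weighted Kolmogorov-
    Smirnov gene set enrichment with a gene-label permutation null. Includes a
    synthetic staged-cohort generator with planted candidates for calibration and
    end-to-end testing, plus small study metrics (immunohistochemistry staining
    index, xenograft tumour volume, 2^(-ddCt) fold change).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
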