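Package: promEI
Title: Expression-Index Analysis of Barcoded AAV Promoter Kits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of competitive-transduction AAV barcode-seq screens of
    promoter kits. Extracts vector barcodes from amplicon sequencing reads by
    anchored excision and Hamming-distance whitelist assignment, normalises
    gDNA (cell entry) and cDNA (expression) barcode abundances to the
    pre-transduction vector mix, computes the Expression Index (EI =
    premix-normalised mRNA share over premix-normalised gDNA share) per
    promoter, and runs tie-corrected Kruskal-Wallis omnibus tests with Dunn's
    Bonferroni-adjusted post-hoc comparisons across promoter classes
    (ubiquitous, cardiac-specific, liver-specific) and within the
    cardiac-specific subset. Includes a full generative simulator of the
    assay (equimolar premix, promoter-independent cell entry,
    tissue-dependent promoter activity, per-base substitution sequencing
    error) with recorded ground truth, so the whole pipeline is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
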