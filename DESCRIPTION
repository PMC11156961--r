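Package: valvemr
Title: Proteome-Wide Mendelian Randomization and Omics Integration for
    Mitral Valve Prolapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking blood-protein cis-pQTL summary
    statistics to mitral valve prolapse risk. Implements two-sample
    Mendelian randomization (inverse-variance-weighted, weighted-median
    and MR-Egger estimators with Cochran's Q heterogeneity, Egger
    intercept pleiotropy and Steiger directionality filtering) on
    cis instruments selected by p-value, TSS window, MAF and greedy LD
    clumping; hypergeometric gene-set over-representation against an
    explicit background; seed-based protein-protein-interaction
    subnetwork extraction with degree, maximal-clique, voterank and
    walktrap module analytics; variance-stabilized moderated-t
    differential expression and fold-change-ranked GSEA; reference-based
    immune-cell deconvolution; ridge-regression cytokine activity
    scoring with permutation z-scores; and directional drug-target
    actionability rules. A seeded synthetic-data module generates every
    input class with planted ground truth so all stages are testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    limma,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
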