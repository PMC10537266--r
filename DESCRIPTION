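Package: labvirome
Title: Detecting Natural Virus Infections in Laboratory Drosophila RNA-Seq
    and Their Impact on Host Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening bulk RNA-seq libraries of laboratory
    Drosophila melanogaster for incidental natural virus infections and for
    quantifying the effect of those infections on host gene expression.
    Implements contamination-aware presence/absence calling (a relative
    threshold against the per-virus maximum plus an absolute read floor,
    tuned from duplicate-sample discordance), verification of library sex
    from sex-specific marker genes, estimation of the index-hopping
    (barcode-switching) rate, per-project prevalence with exact binomial
    confidence intervals, pairwise co-infection association via an exact
    test on 2x2 contingency tables, per-gene linear mixed-model
    differential expression with sex, virus and sex:virus terms and a
    random intercept for dataset-genotype-tissue groups (REML with
    Satterthwaite-type degrees of freedom and empirical-Bayes variance
    moderation), Benjamini-Hochberg adjustment, and cross-virus
    correlation of expression effects. A synthetic-data generator with
    planted ground truth (index hopping across lane-mates, sex-limited
    marker genes, negative-binomial counts with planted fold changes)
    supports end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    limma,
    optparse
Config/testthat/edition: 3
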