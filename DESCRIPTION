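Package: speechmarkers
Title: Linguistic Phenotyping of Diarized Clinical Interview Speech
Version: 0.1.0
Authors@R: person("speechmarkers", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for quantifying language disturbance in diarized clinical
    interview transcripts on three levels: individual word usage compared
    between groups with log-odds ratios weighted by an informative Dirichlet
    prior; part-of-speech rates per 100 words through a pluggable tagger
    backend; and sentence-level coherence via next-sentence probabilities and
    prompt-anchored embedding-distance trajectories with linear fits. Includes
    the accompanying group-statistics battery (Shapiro-Wilk, Wilcoxon rank-sum,
    boxplot outlier flagging, ANCOVA with demographic covariates, Cohen's d),
    a Gaussian naive Bayes discrimination harness with leave-one-out and
    stratified k-fold cross-validation, and a deterministic synthetic corpus
    generator with a seeded toy embedding backend so the whole pipeline is
    testable without any speech recordings or pretrained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
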