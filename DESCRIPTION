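Package: genophen
Title: Bayesian Prediction of Dichotomous Clinical Phenotypes from Personal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the probability that an individual has a dichotomous
    clinical phenotype from their variant calls, integrating population
    prevalence priors stratified by ancestry, gender and age with four
    categories of genetic evidence: high-penetrance variants, GWAS hits
    converted to genotype penetrances under Hardy-Weinberg equilibrium,
    and high- or low-penetrance phenotype-associated genes scored from
    rare non-silent variants via Fisher's method on per-variant functional
    p-values. Evidence is aggregated through a noisy-OR Bayesian network
    into a posterior phenotype probability. Includes cohort evaluation
    (Mann-Whitney AUC, participant- and label-permutation significance,
    Benjamini-Hochberg FDR, a rare-allele burden baseline), genome to
    phenotypic-profile matching by Bernoulli likelihood with a
    random-matching null, and a synthetic-data generator that emulates the
    knowledge bases, cohorts and profiles the model consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
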