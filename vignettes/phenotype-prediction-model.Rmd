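---
title: "Predicting dichotomous phenotypes from personal genomes: the model behind genophen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dichotomous phenotypes from personal genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genophen)
```

## The problem

Given one person's variant calls and basic demographics, what is the
probability that they have a particular dichotomous clinical trait —
Graves' disease, Gilbert syndrome, a B blood group? Annotation databases
answer a different question (is this single variant associated with the
trait?); `genophen` aggregates all of the annotated evidence a genome
carries into a single posterior probability per phenotype, anchored to the
population prevalence appropriate for the individual's ancestry, gender and
age.

## The model

The model is a three-layer Bayesian network evaluated in closed form.

**Layer 1 — observed genotypes.** Three kinds of phenotype-relevant
genotype calls are extracted from the genome:

* matches to curated high-penetrance disease variants (the `DM` class of a
  mutation database), denoted $V_H$;
* risk-allele doses $g \in \{0,1,2\}$ at admitted GWAS hits ($V_L$),
  counting the absence of a call as homozygous reference;
* rare (MAF $<$ 0.01 in every recorded population) non-silent variants in
  phenotype-associated genes ($V_F$).

**Layer 2 — gene alteration probabilities.** Per-variant functional
p-values (any scorer that emits p-values qualifies; a score table is simply
joined by variant key) are combined per gene with Fisher's method,

$$T = -2 \sum_{i=1}^{k} \ln p_i,$$

and converted to a posterior probability that the gene product is
functionally altered. Under the null hypothesis of no alteration the
$p_i$ are Uniform(0,1) and $T \sim \chi^2_{2k}$; under the alternative we
model damaging p-values as $\mathrm{Beta}(a, 1)$ with shape $a \in (0,1]$,
making $T \sim \mathrm{Gamma}(k, a/2)$. The density ratio collapses
analytically, so Bayes' rule with prior $\rho$ gives posterior log-odds

$$\operatorname{logit} P(G = 1 \mid T)
  = \operatorname{logit} \rho + k \ln a + \tfrac{1 - a}{2}\, T,$$

strictly increasing in $T$ when $a < 1$ and identically $\rho$ when
$a = 1$. The defaults $a = 0.3$, $\rho = 0.05$ are package choices (both
exposed in `alteration_params()`): they preserve the Bayes-rule structure
and monotonicity the construction requires while remaining closed-form and
testable; they are not fitted to any cohort.

**Layer 3 — mechanisms and the phenotype.** Evidence is grouped into four
Bernoulli "mechanism" variables: altered by high-penetrance variants
($S_{VH}$), low-penetrance variants ($S_{VL}$), high-penetrance genes
($S_{GH}$) or low-penetrance genes ($S_{GL}$). Gene categories activate by
noisy-OR across their genes, $q_c = 1 - \prod_g (1 - P(G_g = 1))$. The GWAS
category updates the prevalence prior $\pi$ directly: each hit's reported
odds ratio is converted to absolute per-genotype risks $r_0 < \pi < r_2$ by
solving (one-dimensional root finding, tolerance $10^{-10}$)

$$(1-f)^2 r_0 + 2f(1-f)\, r_1 + f^2 r_2 = \pi, \qquad
  r_g = \frac{o_0\,\mathrm{OR}^g}{1 + o_0\,\mathrm{OR}^g},$$

so that the Hardy–Weinberg-weighted mean risk reproduces the prevalence,
and the hits then act as independent likelihood ratios
$\pi_{VL} = \min(\mathrm{cap},\ \pi \prod_i r_{g_i} / \pi)$. Finally the
phenotype variable $Y$ combines everything by noisy-OR, with $\pi_{VL}$ as
the leak term:

$$P(Y = 1) = 1 - (1 - \pi_{VL})
  (1 - q_{VH}\,\rho_{VH}) (1 - q_{GH}\,\rho_{GH}) (1 - q_{GL}\,\rho_{GL}).$$

This closed form equals the exact expectation over the $2^4$ joint
mechanism states under independent Bernoulli activations — the test suite
checks the identity to $10^{-12}$ against a state-enumeration oracle. With
no evidence it reduces to the prevalence; a matched high-penetrance variant
($q_{VH} = 1$ with $\rho_{VH}$ near 1) dominates the posterior. We make
that dominance emergent from a large $\rho_{VH}$ rather than a hard
override: a hard rule would be an equally defensible reading, but the
emergent version keeps the posterior a smooth function of its parameters
and preserves the enumeration identity.

### Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| $\rho_{VH}, \rho_{GH}, \rho_{GL}$ | category penetrance weights | 0.95 / 0.8 / 0.3 | probability |
| cap | clamp on the GWAS-updated prior | 0.99 | probability |
| $a$ | Beta shape of damaging p-values | 0.3 | — |
| $\rho$ | prior of gene alteration | 0.05 | probability |
| MAF cutoff | rarity threshold for gene scoring | 0.01 | frequency |
| eps | posterior clamp in profile matching | $10^{-6}$ | probability |

The weight ordering $\rho_{VH} \ge \rho_{GH} \ge \rho_{GL}$ encodes the
assumption that rare, curated variants act more strongly than mined gene
associations, which in turn act more strongly than common-variant signals;
`model_params()` warns if a configuration violates it but does not forbid
it. All parameters live in configuration objects; nothing is hard-coded.

## Knowledge-base admission rules

GWAS hits are admitted when their odds ratio lies in $(1, 20]$; effect
sizes reported as beta regression coefficients are interpreted as log-odds
and exponentiated first, with a per-record flag recording the conversion.
Literature-mined gene associations need a Z-score above 4.0 or a top-5 rank
within their phenotype (ties at the fifth place resolved by stable input
order, a choice the ranking rule itself leaves open); curated associations
are always kept. High-penetrance variants are admitted only from the most
confident disease-mutation class (`DM`). A gene annotated both HIGH (curated)
and LOW (mined) contributes only to the HIGH category — the curated label is
treated as the stronger claim.

Prevalence lookup returns the most specific entry for the individual and
falls back through progressively coarser keys — drop the age band, then
ancestry, then gender, down to the phenotype-global row. The chain is a
package decision (any fixed specificity order would do); tables should
always carry the phenotype-global row. A phenotype with no prevalence entry
at all is excluded from prediction rather than guessed at.

## Numerical choices and degenerate inputs

* p-values are floored at $10^{-10}$ before logs, so a reported zero
  cannot yield an infinite Fisher statistic.
* The gene-alteration posterior is computed on the log-odds scale; the
  Gamma/chi-square density ratio is evaluated analytically
  ($a^k e^{(1-a)T/2}$), avoiding 0/0 at $T = 0$ for $k > 1$.
* Risk-allele doses at sites whose call is inconsistent with the hit's
  allele pair are treated as missing and excluded from the likelihood-ratio
  product, not imputed.
* Alleles absent from the frequency map count as rare (an unobserved allele
  is, by construction, not common); this is the conventional reading and is
  applied silently.
* No indel left-alignment is performed: knowledge base and genomes must
  share coordinate provenance. This is a documented limitation.
* Ranking ties (equal posteriors, equal profile likelihoods, equal burden)
  break by ascending identifier so every report is deterministic.
* AUC is undefined (and flagged, not fabricated) when a phenotype has no
  cases or no controls after exclusions.

## Evaluation machinery

Cohort rankings are scored by Mann–Whitney AUC (half credit for ties),
with unknown statuses and, for gender-specific phenotypes, participants of
the non-applicable gender excluded. Significance comes from two permutation
tests: shuffling participant identities (one permutation applied to all
phenotype columns simultaneously, preserving the correlation structure
among phenotypes within a participant) or shuffling one phenotype's labels
(phenotypes treated as independent and exchangeable). P-values use the
add-one estimator $(1 + \#\{\mathrm{AUC}^{perm} \ge \mathrm{AUC}\}) /
(1 + B)$; for a phenotype with a single case the label null is enumerated
exactly, giving $p = r/n$ for a case at rank $r$. FDR control is
Benjamini–Hochberg on the permutation p-values — the permutation estimator
leaves the multiple-testing procedure open, and BH is the reproducible,
standard choice. A rare-allele burden baseline (count of damaging rare
alleles in the phenotype's gene set) is included as the comparator model.

Genome-to-profile matching scores each candidate profile by a Bernoulli
log-likelihood over its known statuses, with posteriors clamped into
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$ (how hard 0/1
posteriors should be handled is not dictated by the likelihood itself;
the clamp makes a single confidently-wrong phenotype costly but not
infinitely so). The random-matching null draws each genome's top profile
independently and uniformly — matching the "each profile equally possible"
formulation — so the number of correct top-1 matches is exactly
Binomial($n$, $1/m$); a permutation-without-replacement variant is
available behind a flag. The simulation and the analytic tail are reported
side by side.

## What the synthetic-data generator does and does not emulate

`gen_kb()` / `gen_cohort()` / `gen_profiles()` generate knowledge bases,
cohorts and questionnaire profiles with the statistical structure the model
assumes: Hardy–Weinberg genotypes at GWAS hits, odds ratios log-uniform on
$(1, 20]$, risk-allele frequencies uniform on $(0.05, 0.5)$, low carrier
frequencies ($< 0.01$) for high-penetrance variants (high penetrance
entails low prevalence), Poisson counts of rare non-silent variants per
gene, Beta($a$,1) functional p-values at damaging sites and Uniform(0,1)
elsewhere, and phenotype status drawn as Bernoulli(posterior) from the
model's own forward closed form.

Because status is generated by the same closed form used in inference,
recovery experiments are well-posed oracles: the model *should* recover the
planted ranking, and failing to would indicate an implementation defect.
The flip side is that passing them says nothing about model
misspecification on real data. The generator also omits sequencing error,
linkage disequilibrium between hits, population structure, phasing and
copy-number events; real-data performance additionally depends on
annotation quality, which the paper-scale experiments showed to be the
binding constraint.

Problem sizes in the shipped checks are chosen to keep the full suite in
the minutes range while leaving the statistics well-powered: recovery runs
20 replicates of 500 (high-penetrance recovery: 5 DM variants at carrier
frequency 0.005 against a 0.001-prevalence phenotype) or 200 participants
(GWAS-driven model-vs-burden: 8 hits, prevalence 0.1), calibration uses 200
null phenotypes at 500 permutations each, and distributional checks use
$10^4$ draws.

## Known limitations

* Absence of a call is read as homozygous reference; no-call regions are
  not represented in the input format and cannot be distinguished.
* Interactions among genes and variants are not modelled; all aggregation
  is independence-based (noisy-OR, likelihood-ratio products).
* Recessive inheritance is not modelled: any match to a high-penetrance
  variant, heterozygous or homozygous, activates the category.
* The gene-alteration alternative distribution is parametric by design;
  with a large cohort its parameters could be estimated rather than chosen.
* Structural variation, phasing and somatic mutation are out of scope.
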