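# genophen

Bayesian prediction of dichotomous clinical phenotypes from personal
genome variant calls.

## What it does and who it is for

Given an individual's variant calls and demographics (age, gender,
ancestry), `genophen` estimates the posterior probability that the
individual has a dichotomous clinical trait, for every phenotype with
entries in an annotation knowledge base. It is aimed at researchers working
with adult volunteer cohorts (trait questionnaires plus genomes) who want
calibrated per-phenotype probabilities and cohort-level evaluation, rather
than prioritized single-variant lists.

The model is a three-layer Bayesian network evaluated in closed form. The
population prevalence π — looked up by phenotype, ancestry, gender and age
band — is the prior. Four categories of genetic evidence update it:

- **high-penetrance variants** (curated disease mutations, class DM):
  any match activates mechanism S_VH;
- **GWAS hits** (odds ratio in (1, 20]): each reported OR and risk allele
  frequency f is converted to absolute genotype risks r₀ < π < r₂ by
  solving the Hardy–Weinberg constraint
  (1−f)²r₀ + 2f(1−f)r₁ + f²r₂ = π with multiplicative per-allele odds,
  and the observed dose g contributes the likelihood ratio r_g/π
  (mechanism S_VL);
- **high- / low-penetrance genes**: rare (MAF < 0.01) non-silent variants
  in each phenotype-associated gene are scored by Fisher's method
  T = −2Σln pᵢ over per-variant functional p-values, converted by Bayes'
  rule to P(gene altered | T), and aggregated noisy-OR within each category
  (mechanisms S_GH, S_GL).

The phenotype variable Y combines the mechanisms by noisy-OR with category
penetrance weights ρ:

    P(Y=1) = 1 − (1−π_VL)(1−q_VH·ρ_VH)(1−q_GH·ρ_GH)(1−q_GL·ρ_GL)

where π_VL = min(cap, π·Π r_g/π) is the GWAS-updated prior acting as the
leak term. With no evidence the posterior equals the prevalence; a matched
high-penetrance variant dominates it.

Around the core model the package provides cohort evaluation (Mann–Whitney
AUC with unknown-status and gender exclusions, participant- and
label-shuffle permutation significance, Benjamini–Hochberg FDR, a
rare-allele burden baseline), genome-to-phenotypic-profile matching by
Bernoulli likelihood with an exact and simulated random-matching null, and
a synthetic-data generator that emulates knowledge bases, cohorts and
trait-questionnaire profiles so the whole stack is testable without any
external database.

## Worked example

```r
library(genophen)

kb <- annotation_kb(
  gwas = data.frame(phenotype = "graves_disease", rsid = c("rs1", "rs2"),
                    chrom = "1", pos = c(100L, 200L), risk_allele = "A",
                    other_allele = "G", odds_ratio = c(2.5, 1.8),
                    risk_allele_freq = c(0.3, 0.2), risk_is_ref = FALSE),
  hp_variants = data.frame(phenotype = "graves_disease", chrom = "1",
                           pos = 900L, ref = "C", alt = "T", gene = "TSHR",
                           class = "DM"),
  prevalence = data.frame(phenotype = "graves_disease", ancestry = "ALL",
                          gender = c("F", "M"), age_lo = NA, age_hi = NA,
                          prevalence = c(0.03, 0.005), source = "example"))

genome <- personal_genome("PGP-48",
  data.frame(chrom = "1", pos = c(100L, 200L), ref = "G", alt = "A",
             allele_count = c(2L, 1L)),   # hom and het risk alleles
  age = 45, gender = "F", ancestry = "European")

predict_phenotype(genome, "graves_disease", kb)
#>   participant_id      phenotype prior posterior q_vh pi_vl q_gh q_gl mode
#> 1         PGP-48 graves_disease  0.03     0.114    0 0.114    0    0 full
```

The prior 0.03 is the female prevalence row. The genome carries a
homozygous risk genotype at an OR 2.5 hit and a heterozygous one at an
OR 1.8 hit; their likelihood ratios raise the posterior to 0.114
(`pi_vl`), while the unmatched DM variant leaves `q_vh` at 0. Had the
genome carried the `TSHR` DM variant, the posterior would jump to at least
ρ_VH = 0.95.

Cohort-scale workflows (`predict_cohort()`, `evaluate_cohort()`,
`rank_profiles()`, `gen_kb()`/`gen_cohort()`) are exercised end-to-end in
the test suite; a thin CLI over the same functions ships in
`inst/cli/genophen.R` with subcommands `predict`, `evaluate`, `match`,
`matchnull` and `simulate`.

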