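test_that("GWAS genotype penetrances satisfy the Hardy-Weinberg mean constraint", {
  set.seed(21)
  for (i in 1:50) {
    or <- exp(runif(1, 0.01, log(20)))
    f <- runif(1, 0.02, 0.95)
    pi <- runif(1, 0.001, 0.5)
    r <- gwas_genotype_penetrance(or, f, pi)
    hwe_mean <- (1 - f)^2 * r[1] + 2 * f * (1 - f) * r[2] + f^2 * r[3]
    expect_equal(hwe_mean, pi, tolerance = 1e-8)
    expect_lt(r[1], pi)
    expect_gt(r[3], pi)
  }
})

test_that("penetrances agree with an independent bisection oracle", {
  r <- gwas_genotype_penetrance(2, 0.3, 0.1)
  oracle <- bisect_penetrance(2, 0.3, 0.1)
  expect_equal(as.numeric(r), oracle, tolerance = 1e-8)
  expect_equal(r[3], 0.2125, tolerance = 1e-3)
})

test_that("a vanishing odds ratio leaves every genotype at the prevalence", {
  r <- gwas_genotype_penetrance(1 + 1e-9, 0.3, 0.1)
  expect_equal(as.numeric(r), rep(0.1, 3), tolerance = 1e-6)
})

test_that("invalid penetrance inputs are rejected", {
  expect_error(gwas_genotype_penetrance(1, 0.3, 0.1), "odds ratio")
  expect_error(gwas_genotype_penetrance(25, 0.3, 0.1), "odds ratio")
  expect_error(gwas_genotype_penetrance(2, 0, 0.1), "frequency")
  expect_error(gwas_genotype_penetrance(2, 0.3, 1), "prevalence")
})

test_that("the GWAS update multiplies per-hit likelihood ratios, clamped at the cap", {
  pi <- 0.1
  r <- gwas_genotype_penetrance(3, 0.2, pi)
  # no hits: prior unchanged
  expect_equal(gwas_update(pi, integer(0), list()), pi)
  # single hit at dose g: pi * (r_g / pi) = r_g
  for (g in 0:2) {
    expect_equal(gwas_update(pi, g, list(r)), as.numeric(r[g + 1]),
                 tolerance = 1e-12)
  }
  # dose 0 carries the protective residual r0 < pi
  expect_lt(gwas_update(pi, 0L, list(r)), pi)
  # many strong hits saturate at the cap
  strong <- gwas_genotype_penetrance(20, 0.4, pi)
  many <- gwas_update(pi, rep(2L, 10), rep(list(strong), 10), cap = 0.99)
  expect_equal(many, 0.99)
  # unresolvable doses are excluded, not imputed
  expect_equal(gwas_update(pi, c(1L, NA), list(r, r)),
               gwas_update(pi, 1L, list(r)))
  # a penetrance triple anchored to a different prior is rejected
  r2 <- gwas_genotype_penetrance(3, 0.2, 0.2)
  expect_error(gwas_update(pi, 1L, list(r2)), "different prior")
})

test_that("category activation is the noisy-OR over gene posteriors", {
  expect_equal(category_activation(numeric(0)), 0)
  expect_equal(category_activation(0.7), 0.7)
  # enumeration of the four joint outcomes for two genes at 0.5
  expect_equal(category_activation(c(0.5, 0.5)), 0.75)
  expect_error(category_activation(c(0.5, 1.2)), "0,1")
})

test_that("posterior closed form equals the 16-state enumeration oracle", {
  params <- model_params()
  # the worked case: only the high-penetrance gene category active
  ev <- mechanism_evidence(q_gh = 0.6)
  p <- posterior_phenotype(ev, model_params(rho_gh = 0.5), prior = 0.1)
  expect_equal(p$posterior,
               enum_posterior(0, 0.6, 0, 0.1, 0.95, 0.5, 0.3),
               tolerance = 1e-12)
  # randomized draws
  set.seed(31)
  for (i in 1:200) {
    q <- runif(3)
    pi <- runif(1, 0.001, 0.5)
    rho <- sort(runif(3))  # rho_gl <= rho_gh <= rho_vh
    pars <- suppressWarnings(model_params(rho_vh = rho[3], rho_gh = rho[2],
                                          rho_gl = rho[1]))
    ev <- mechanism_evidence(q_vh = q[1], q_gh = q[2], q_gl = q[3])
    got <- posterior_phenotype(ev, pars, prior = pi)$posterior
    want <- enum_posterior(q[1], q[2], q[3], pi, rho[3], rho[2], rho[1])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("posterior limits: empty evidence returns the prior, a matched hp variant dominates", {
  expect_equal(posterior_phenotype(mechanism_evidence(), prior = 0.07)$posterior,
               0.07)
  pars <- suppressWarnings(model_params(rho_vh = 1))
  p <- posterior_phenotype(mechanism_evidence(q_vh = 1, q_gh = 0.3, q_gl = 0.9),
                           pars, prior = 0.01)
  expect_equal(p$posterior, 1)
})

test_that("single-category modes zero the other evidence channels", {
  pi <- 0.1
  r <- gwas_genotype_penetrance(3, 0.2, pi)
  ev <- mechanism_evidence(q_vh = 1, q_gh = 0.5, q_gl = 0.5,
                           doses = 2L, penetrances = list(r))
  params <- model_params()
  expect_equal(posterior_phenotype(ev, params, pi, mode = "prevalence_only")$posterior,
               pi)
  expect_equal(posterior_phenotype(ev, params, pi, mode = "vl")$posterior,
               as.numeric(r[3]))
  expect_equal(posterior_phenotype(ev, params, pi, mode = "vh")$posterior,
               1 - (1 - pi) * (1 - params$rho_vh))
  expect_equal(posterior_phenotype(ev, params, pi, mode = "gh")$posterior,
               1 - (1 - pi) * (1 - 0.5 * params$rho_gh))
  expect_equal(posterior_phenotype(ev, params, pi, mode = "gl")$posterior,
               1 - (1 - pi) * (1 - 0.5 * params$rho_gl))
})

test_that("posterior is monotone in category activations and GWAS dose", {
  params <- model_params()
  pi <- 0.05
  base <- posterior_phenotype(mechanism_evidence(q_gh = 0.2, q_gl = 0.2),
                              params, pi)$posterior
  up <- posterior_phenotype(mechanism_evidence(q_gh = 0.4, q_gl = 0.2),
                            params, pi)$posterior
  expect_gt(up, base)
  r <- gwas_genotype_penetrance(2.5, 0.3, pi)
  post_by_dose <- vapply(0:2, function(g) {
    posterior_phenotype(mechanism_evidence(doses = as.integer(g),
                                           penetrances = list(r)),
                        params, pi)$posterior
  }, numeric(1))
  expect_true(all(diff(post_by_dose) > 0))
})

test_that("end-to-end prediction composes all evidence channels", {
  kb <- fixture_kb()
  scores <- fixture_scores()
  params <- model_params()
  # with no annotations for the phenotype, an empty genome scores the prior
  kb_bare <- kb
  kb_bare$gwas <- kb_bare$gwas[0, ]
  empty <- predict_phenotype(fixture_genome(), "asthma", kb_bare, scores, params)
  expect_equal(empty$posterior, empty$prior)
  expect_equal(empty$prior, 0.08)
  # under an annotated GWAS hit, homozygous reference is itself (protective)
  # evidence: dose 0 pulls the posterior below the prior
  hom_ref <- predict_phenotype(fixture_genome(), "asthma", kb, scores, params)
  expect_lt(hom_ref$posterior, hom_ref$prior)
  # carrying the KB's DM variant pushes the posterior to at least rho_vh
  carrier <- fixture_genome(call_row(pos = 500, ref = "C", alt = "T"))
  p <- predict_phenotype(carrier, "asthma", kb, scores, params)
  expect_gte(p$posterior, 0.95)
  expect_equal(p$q_vh, 1)
  # one extra risk allele strictly increases the posterior
  dose1 <- fixture_genome(call_row(pos = 100, ref = "G", alt = "A"))
  dose2 <- fixture_genome(call_row(pos = 100, ref = "G", alt = "A",
                                   allele_count = 2))
  expect_gt(predict_phenotype(dose2, "asthma", kb, scores, params)$posterior,
            predict_phenotype(dose1, "asthma", kb, scores, params)$posterior)
  # a phenotype without prevalence annotation is not predictable
  none <- predict_phenotype(fixture_genome(), "dandruff", kb, scores, params)
  expect_true(is.na(none$posterior))
})

test_that("a gene annotated both HIGH and LOW contributes only to the HIGH category", {
  kb <- fixture_kb()
  kb$genes <- rbind(kb$genes, data.frame(
    phenotype = "asthma", gene = "GENE_H", penetrance_class = "LOW",
    zscore = 7, stringsAsFactors = FALSE))
  g <- fixture_genome(call_row(pos = 1000, ref = "G", alt = "A"))
  p <- predict_phenotype(g, "asthma", kb, fixture_scores(), model_params())
  expect_gt(p$q_gh, 0)
  expect_equal(p$q_gl, 0)
})

test_that("genome-only mode substitutes a shared baseline prior", {
  kb <- fixture_kb()
  g <- fixture_genome()
  p <- predict_phenotype(g, "asthma", kb, fixture_scores(), model_params(),
                         mode = "genome_only", baseline_prior = 0.2)
  expect_equal(p$prior, 0.2)
  long <- predict_cohort(list(g), "asthma", kb, fixture_scores(),
                         model_params(), mode = "genome_only")
  expect_equal(long$prior, 0.08)  # cohort average of the global rows
})
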