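# Core model: convert per-category genetic evidence into mechanism
# probabilities and a posterior phenotype probability via a noisy-OR
# Bayesian network.
#
# Three layers: observed genotypes (doses at GWAS hits, matched
# high-penetrance variants, rare non-silent variants in associated genes);
# per-gene alteration probabilities; and four Bernoulli mechanism variables
# -- altered by high-penetrance variants (S_VH), low-penetrance variants
# (S_VL, the GWAS category), high-penetrance genes (S_GH) or low-penetrance
# genes (S_GL) -- whose joint state determines the phenotype variable Y.

#' Model parameters
#'
#' Category penetrance weights for the noisy-OR aggregation. Each activated
#' mechanism independently fails to produce the phenotype with probability
#' (1 - rho_c); the GWAS category enters through the updated prior instead
#' of a weight. Defaults encode the assumption that rare, curated
#' high-penetrance evidence acts more strongly than mined gene associations:
#' rho_vh >= rho_gh >= rho_gl.
#'
#' @param rho_vh penetrance weight of the high-penetrance-variant category
#'   (default 0.95).
#' @param rho_gh weight of the high-penetrance-gene category (default 0.8).
#' @param rho_gl weight of the low-penetrance-gene category (default 0.3).
#' @param posterior_cap upper clamp on the GWAS-updated prior (default 0.99).
#' @param alteration an [alteration_params()] used for gene scoring.
#' @return List of class `model_params`.
#' @export
model_params <- function(rho_vh = 0.95, rho_gh = 0.8, rho_gl = 0.3,
                         posterior_cap = 0.99,
                         alteration = alteration_params()) {
  for (v in c(rho_vh, rho_gh, rho_gl)) {
    if (!is_prob(v)) stopf("penetrance weights must lie in [0,1]")
  }
  if (!is.numeric(posterior_cap) || posterior_cap <= 0 || posterior_cap >= 1) {
    stopf("posterior_cap must lie in (0,1)")
  }
  if (!(rho_vh >= rho_gh && rho_gh >= rho_gl)) {
    warnf("penetrance weights do not satisfy the default ordering rho_vh >= rho_gh >= rho_gl")
  }
  structure(list(rho_vh = rho_vh, rho_gh = rho_gh, rho_gl = rho_gl,
                 posterior_cap = posterior_cap, alteration = alteration),
            class = "model_params")
}

#' Genotype penetrances implied by a GWAS odds ratio
#'
#' Converts a reported per-allele odds ratio and risk-allele frequency into
#' absolute risks (penetrances) per genotype dose, anchored to the phenotype
#' prevalence. Odds are multiplicative per risk allele: o_g = o0 * OR^g for
#' dose g in 0..2, with risks r_g = o_g / (1 + o_g). The baseline odds o0
#' are solved numerically so that the Hardy-Weinberg-weighted mean risk
#' equals the prevalence:
#'   (1-f)^2 r0 + 2 f (1-f) r1 + f^2 r2 = pi.
#'
#' @param or odds ratio, in (1, 20].
#' @param f risk allele frequency, in (0,1).
#' @param prior phenotype prevalence pi, in (0,1).
#' @param tol tolerance on the Hardy-Weinberg mean constraint (default 1e-10).
#' @return Numeric vector `c(r0, r1, r2)` with attribute `prior` recording
#'   the prevalence it was anchored to. Always `r0 < prior < r2`.
#' @export
gwas_genotype_penetrance <- function(or, f, prior, tol = 1e-10) {
  if (!is.numeric(or) || or <= 1 || or > 20) stopf("odds ratio must lie in (1, 20]")
  if (!is.numeric(f) || f <= 0 || f >= 1) stopf("risk allele frequency must lie in (0,1)")
  if (!is.numeric(prior) || prior <= 0 || prior >= 1) stopf("prevalence must lie in (0,1)")
  w <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  mean_risk <- function(o0) {
    o <- o0 * or^(0:2)
    sum(w * o / (1 + o)) - prior
  }
  # mean risk is strictly increasing in o0 from 0 to 1, so the root is unique
  root <- tryCatch(
    stats::uniroot(mean_risk, lower = 1e-300, upper = 1e3, tol = tol / 10),
    error = function(e) NULL)
  if (is.null(root) || abs(mean_risk(root$root)) > 1e-6) {
    stopf("no baseline odds in (0, 1e3) satisfy the prevalence constraint (or=%g, f=%g, prior=%g)",
          or, f, prior)
  }
  o <- root$root * or^(0:2)
  r <- o / (1 + o)
  attr(r, "prior") <- prior
  r
}

#' Update the prior with GWAS genotype evidence
#'
#' Each hit contributes a likelihood ratio LR_i = r_{g_i} / pi, the carrier
#' risk at the observed dose relative to prevalence; hits are treated as
#' independent, so the updated probability is pi * prod(LR_i), clamped at
#' `cap`. Missing (unresolvable) doses are excluded from the product. With
#' no hits the prior is returned unchanged.
#'
#' @param prior prevalence pi the penetrances were anchored to.
#' @param doses integer vector of risk-allele doses (0, 1, 2 or `NA`).
#' @param penetrances list of penetrance triples from
#'   [gwas_genotype_penetrance()], parallel to `doses`.
#' @param cap upper clamp (default 0.99).
#' @return Updated probability `pi_VL` in (0, cap].
#' @export
gwas_update <- function(prior, doses, penetrances, cap = 0.99) {
  if (length(doses) != length(penetrances)) {
    stopf("doses and penetrances must be parallel")
  }
  log_lr <- 0
  for (i in seq_along(doses)) {
    r <- penetrances[[i]]
    p0 <- attr(r, "prior")
    if (is.null(p0) || abs(p0 - prior) > 1e-12) {
      stopf("penetrance triple %d was anchored to a different prior", i)
    }
    if (is.na(doses[i])) next
    log_lr <- log_lr + log(r[doses[i] + 1L]) - log(prior)
  }
  min(cap, exp(log(prior) + log_lr))
}

#' Noisy-OR activation of a gene category
#'
#' Probability that at least one gene in the category is functionally
#' altered, assuming independence: q = 1 - prod(1 - p_gene). An empty
#' category yields 0.
#'
#' @param gene_posteriors numeric vector of per-gene alteration
#'   probabilities in \[0,1\].
#' @return Activation probability in \[0,1\].
#' @export
category_activation <- function(gene_posteriors) {
  if (length(gene_posteriors) == 0) return(0)
  if (!is_prob(gene_posteriors)) stopf("gene posteriors must lie in [0,1]")
  1 - prod(1 - gene_posteriors)
}

#' Bundle per-category mechanism evidence
#'
#' @param q_vh 1 if any high-penetrance variant matched, else 0.
#' @param q_gh,q_gl activation probabilities of the high-/low-penetrance
#'   gene categories from [category_activation()].
#' @param gwas_lr list of penetrance triples plus doses: supply `doses`
#'   (integer vector) and `penetrances` (list) as produced for
#'   [gwas_update()]; or leave empty for no GWAS evidence.
#' @return List of class `mechanism_evidence`.
#' @export
mechanism_evidence <- function(q_vh = 0, q_gh = 0, q_gl = 0,
                               doses = integer(0), penetrances = list()) {
  if (!is_prob(c(q_vh, q_gh, q_gl))) stopf("mechanism probabilities must lie in [0,1]")
  structure(list(q_vh = q_vh, q_gh = q_gh, q_gl = q_gl,
                 doses = doses, penetrances = penetrances),
            class = "mechanism_evidence")
}

#' Posterior phenotype probability from mechanism evidence
#'
#' The four mechanism categories combine by noisy-OR: the GWAS category
#' enters through the updated prior pi_VL (acting as the leak term, so the
#' posterior reduces to the prevalence with no evidence), and each remaining
#' category c activated with probability q_c causes the phenotype with
#' probability rho_c:
#'
#'   P(Y=1) = 1 - (1 - pi_VL) (1 - q_VH rho_VH) (1 - q_GH rho_GH) (1 - q_GL rho_GL)
#'
#' This equals the exact expectation over the 2^4 joint mechanism states
#' under independent Bernoulli activations. A matched high-penetrance
#' variant (q_VH = 1) with rho_VH near 1 dominates the posterior.
#'
#' Modes: `"full"` uses all categories; `"prevalence_only"` returns the
#' prior; `"genome_only"` is the full formula with whatever baseline prior
#' the caller supplied; `"vh"`, `"vl"`, `"gh"`, `"gl"` keep a single
#' category and zero the rest.
#'
#' @param evidence a [mechanism_evidence()].
#' @param params a [model_params()].
#' @param prior prevalence pi in (0,1).
#' @param mode evaluation mode (see details).
#' @return List with `prior`, `posterior`, `q_vh`, `pi_vl`, `q_gh`, `q_gl`,
#'   `mode`.
#' @export
posterior_phenotype <- function(evidence, params = model_params(), prior,
                                mode = c("full", "genome_only",
                                         "prevalence_only", "vh", "vl",
                                         "gh", "gl")) {
  mode <- match.arg(mode)
  if (is.na(prior)) stopf("no prevalence available for this phenotype")
  if (prior <= 0 || prior >= 1) stopf("prior must lie in (0,1)")
  q_vh <- evidence$q_vh; q_gh <- evidence$q_gh; q_gl <- evidence$q_gl
  doses <- evidence$doses; pens <- evidence$penetrances
  if (mode %in% c("prevalence_only")) {
    return(list(prior = prior, posterior = prior, q_vh = 0, pi_vl = prior,
                q_gh = 0, q_gl = 0, mode = mode))
  }
  if (mode %in% c("vh", "vl", "gh", "gl")) {
    if (mode != "vh") q_vh <- 0
    if (mode != "gh") q_gh <- 0
    if (mode != "gl") q_gl <- 0
    if (mode != "vl") { doses <- integer(0); pens <- list() }
  }
  pi_vl <- gwas_update(prior, doses, pens, cap = params$posterior_cap)
  post <- 1 - (1 - pi_vl) *
    (1 - q_vh * params$rho_vh) *
    (1 - q_gh * params$rho_gh) *
    (1 - q_gl * params$rho_gl)
  list(prior = prior, posterior = post, q_vh = q_vh, pi_vl = pi_vl,
       q_gh = q_gh, q_gl = q_gl, mode = mode)
}

#' Predict the posterior probability of a phenotype for one genome
#'
#' Full composition: prevalence lookup (stratified by the individual's
#' ancestry, gender and age); dose and penetrance per admitted GWAS hit;
#' gene-level functional scoring of the phenotype's HIGH and LOW penetrance
#' gene sets (a gene annotated both HIGH and LOW contributes only to HIGH);
#' high-penetrance variant matching; and the noisy-OR posterior.
#'
#' @param genome a [personal_genome()].
#' @param phenotype phenotype identifier.
#' @param kb an [annotation_kb()].
#' @param scores per-variant functional p-value table (see [score_gene()]).
#' @param params a [model_params()].
#' @param mode evaluation mode, see [posterior_phenotype()].
#' @param baseline_prior prior to use in `"genome_only"` mode (typically the
#'   cohort-average prevalence); ignored otherwise.
#' @return One-row data.frame: `participant_id`, `phenotype`, `prior`,
#'   `posterior`, `q_vh`, `pi_vl`, `q_gh`, `q_gl`, `mode`. A phenotype with
#'   no prevalence entry (and, a fortiori, no annotations) is not
#'   predictable: the row carries `NA` prior and posterior.
#' @export
predict_phenotype <- function(genome, phenotype, kb, scores = NULL,
                              params = model_params(), mode = "full",
                              baseline_prior = NULL) {
  prior <- lookup_prevalence(kb$prevalence, phenotype,
                             genome$ancestry, genome$gender, genome$age)
  if (mode == "genome_only") {
    if (is.null(baseline_prior)) stopf("genome_only mode needs a baseline_prior")
    prior <- baseline_prior
  }
  if (is.na(prior)) {
    return(data.frame(participant_id = genome$participant_id,
                      phenotype = phenotype, prior = NA_real_,
                      posterior = NA_real_, q_vh = NA_real_, pi_vl = NA_real_,
                      q_gh = NA_real_, q_gl = NA_real_, mode = mode,
                      stringsAsFactors = FALSE))
  }

  # high-penetrance variants: any het or hom match activates the category
  q_vh <- as.numeric(nrow(match_hp_variant(genome, kb, phenotype)) > 0)

  # GWAS hits
  hits <- kb$gwas[kb$gwas$phenotype == phenotype, , drop = FALSE]
  doses <- integer(0); pens <- list()
  if (nrow(hits) > 0 && mode != "prevalence_only") {
    doses <- vapply(seq_len(nrow(hits)), function(i) {
      risk_allele_dose(genome, hits[i, ])
    }, integer(1))
    pens <- lapply(seq_len(nrow(hits)), function(i) {
      gwas_genotype_penetrance(hits$odds_ratio[i], hits$risk_allele_freq[i], prior)
    })
  }

  # gene categories; HIGH takes precedence when a gene is annotated both ways
  ga <- kb$genes[kb$genes$phenotype == phenotype, , drop = FALSE]
  high_genes <- unique(ga$gene[ga$penetrance_class == "HIGH"])
  low_genes <- setdiff(unique(ga$gene[ga$penetrance_class == "LOW"]), high_genes)
  q_gh <- 0; q_gl <- 0
  if (!is.null(scores) && mode != "prevalence_only") {
    if (length(high_genes) > 0) {
      q_gh <- category_activation(vapply(high_genes, function(g) {
        score_gene(genome, g, phenotype, kb, scores, params$alteration)
      }, numeric(1)))
    }
    if (length(low_genes) > 0) {
      q_gl <- category_activation(vapply(low_genes, function(g) {
        score_gene(genome, g, phenotype, kb, scores, params$alteration)
      }, numeric(1)))
    }
  }

  ev <- mechanism_evidence(q_vh = q_vh, q_gh = q_gh, q_gl = q_gl,
                           doses = doses, penetrances = pens)
  res <- posterior_phenotype(ev, params, prior, mode)
  data.frame(participant_id = genome$participant_id, phenotype = phenotype,
             prior = res$prior, posterior = res$posterior, q_vh = res$q_vh,
             pi_vl = res$pi_vl, q_gh = res$q_gh, q_gl = res$q_gl,
             mode = mode, stringsAsFactors = FALSE)
}

#' Predict posteriors for a whole cohort
#'
#' Applies [predict_phenotype()] to every genome and phenotype. In
#' `"genome_only"` mode the baseline prior defaults to the average of the
#' phenotype-global prevalence rows (the same-prevalence-for-everyone
#' ablation).
#'
#' @param genomes list of [personal_genome()] objects.
#' @param phenotypes character vector of phenotype identifiers.
#' @param kb,scores,params,mode,baseline_prior see [predict_phenotype()].
#' @return Long data.frame, one row per genome x phenotype.
#' @export
predict_cohort <- function(genomes, phenotypes, kb, scores = NULL,
                           params = model_params(), mode = "full",
                           baseline_prior = NULL) {
  if (mode == "genome_only" && is.null(baseline_prior)) {
    glob <- kb$prevalence[kb$prevalence$ancestry == "ALL" &
                          kb$prevalence$gender == "ALL", , drop = FALSE]
    if (nrow(glob) == 0) stopf("genome_only mode needs a baseline_prior")
    baseline_prior <- mean(glob$prevalence)
  }
  out <- vector("list", length(genomes) * length(phenotypes))
  i <- 0
  for (g in genomes) {
    for (ph in phenotypes) {
      i <- i + 1
      out[[i]] <- predict_phenotype(g, ph, kb, scores, params, mode,
                                    baseline_prior)
    }
  }
  do.call(rbind, out)
}

#' Reshape cohort predictions to a participant-by-phenotype matrix
#'
#' @param predictions long data.frame from [predict_cohort()].
#' @param value column to spread (default `"posterior"`).
#' @return Numeric matrix with participant ids as rownames.
#' @export
posterior_matrix <- function(predictions, value = "posterior") {
  participants <- unique(predictions$participant_id)
  phenos <- unique(predictions$phenotype)
  m <- matrix(NA_real_, length(participants), length(phenos),
              dimnames = list(participants, phenos))
  m[cbind(match(predictions$participant_id, participants),
          match(predictions$phenotype, phenos))] <- predictions[[value]]
  m
}
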