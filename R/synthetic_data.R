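# Synthetic-data generator: knowledge bases, cohorts, prevalence tables and
# phenotypic profiles with the statistical structure the model assumes, so
# every module is testable without external databases.
#
# Phenotype status is drawn from the same forward model used in inference
# (genotypes -> mechanism evidence -> noisy-OR posterior -> Bernoulli),
# which makes rank-recovery a well-posed oracle; it deliberately does not
# test model misspecification.

#' Simulation configuration
#'
#' Per-phenotype parameters are recycled across `n_phenotypes`. Supports are
#' constrained to the model's admissible ranges: odds ratios in (1, 20]
#' (sampled log-uniformly), risk allele frequencies in (0.05, 0.5),
#' high-penetrance carrier frequencies below 0.01 (high penetrance entails
#' low carrier frequency).
#'
#' @param n_participants cohort size.
#' @param n_phenotypes number of phenotypes.
#' @param prevalence phenotype prevalence(s) in (0,1).
#' @param n_gwas_hits GWAS hits per phenotype.
#' @param n_hp_variants curated high-penetrance variants per phenotype.
#' @param n_high_pen_genes,n_low_pen_genes gene-category sizes per
#'   phenotype (beyond the genes hosting high-penetrance variants, which are
#'   HIGH by construction).
#' @param hp_carrier_freq per-variant carrier frequency of each
#'   high-penetrance variant, in \[0, 0.01).
#' @param or_range odds-ratio support (log-uniform), within (1, 20\].
#' @param raf_range risk-allele-frequency support (uniform).
#' @param beta_shape shape a of the Beta(a,1) p-value distribution of
#'   damaging variants.
#' @param damaging_site_frac fraction of candidate rare non-silent sites
#'   whose variants are truly damaging.
#' @param sites_per_gene candidate rare non-silent sites per gene.
#' @param rare_variant_mean Poisson mean of rare non-silent variants carried
#'   per gene per individual.
#' @param profile_missingness probability a profile entry is masked to
#'   unknown.
#' @param params a [model_params()] used both to generate statuses and as
#'   the matched inference parameters.
#' @param seed master RNG seed for the run.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_participants = 200, n_phenotypes = 3,
                       prevalence = 0.05, n_gwas_hits = 5, n_hp_variants = 5,
                       n_high_pen_genes = 2, n_low_pen_genes = 3,
                       hp_carrier_freq = 0.005,
                       or_range = c(1, 20), raf_range = c(0.05, 0.5),
                       beta_shape = 0.3, damaging_site_frac = 0.1,
                       sites_per_gene = 8, rare_variant_mean = 0.5,
                       profile_missingness = 0.2,
                       params = model_params(), seed = 1) {
  rec <- function(x) rep_len(x, n_phenotypes)
  stopifnot(n_participants >= 1, n_phenotypes >= 1)
  prevalence <- rec(prevalence)
  if (any(prevalence <= 0 | prevalence >= 1)) stopf("prevalence must lie in (0,1)")
  hp_carrier_freq <- rec(hp_carrier_freq)
  if (any(hp_carrier_freq < 0 | hp_carrier_freq >= 0.01)) {
    stopf("hp_carrier_freq must lie in [0, 0.01)")
  }
  if (or_range[1] < 1 || or_range[2] > 20 || or_range[1] >= or_range[2]) {
    stopf("or_range must lie within (1, 20]")
  }
  structure(list(
    n_participants = n_participants, n_phenotypes = n_phenotypes,
    prevalence = prevalence, n_gwas_hits = rec(n_gwas_hits),
    n_hp_variants = rec(n_hp_variants),
    n_high_pen_genes = rec(n_high_pen_genes),
    n_low_pen_genes = rec(n_low_pen_genes),
    hp_carrier_freq = hp_carrier_freq,
    or_range = or_range, raf_range = raf_range, beta_shape = beta_shape,
    damaging_site_frac = damaging_site_frac, sites_per_gene = sites_per_gene,
    rare_variant_mean = rare_variant_mean,
    profile_missingness = profile_missingness,
    params = params, seed = seed), class = "sim_config")
}

sim_phenotype_names <- function(config) {
  sprintf("PHENO%d", seq_len(config$n_phenotypes))
}

#' Generate a synthetic knowledge base
#'
#' Builds, per phenotype: GWAS hits with risk allele frequency uniform on
#' its support and odds ratio log-uniform on the configured range (all
#' admissible under the effect-size filter); curated high-penetrance (DM)
#' variants hosted in HIGH genes; HIGH and LOW gene associations (LOW ones
#' carry mined Z-scores above the admission threshold); candidate rare
#' non-silent sites per gene, plus one synonymous and one common site each
#' to exercise the selection filters; per-population allele frequencies for
#' half of the rare sites (the rest are unobserved, hence treated rare);
#' and a prevalence table of phenotype-global wildcard rows. Gene sets are
#' disjoint across categories and phenotypes.
#'
#' @param config a [sim_config()].
#' @return An [annotation_kb()].
#' @export
gen_kb <- function(config) {
  set.seed(config$seed)
  gwas <- list(); hp <- list(); genes <- list(); sites <- list()
  freqs <- list(); prev <- list()
  phenos <- sim_phenotype_names(config)
  for (i in seq_along(phenos)) {
    ph <- phenos[i]
    base <- i * 10000000L
    ng <- config$n_gwas_hits[i]
    if (ng > 0) {
      lo <- log(max(config$or_range[1], 1) + 1e-9)
      gwas[[ph]] <- data.frame(
        phenotype = ph, rsid = sprintf("rs%d_%d", i, seq_len(ng)),
        chrom = "1", pos = base + seq_len(ng),
        risk_allele = "A", other_allele = "G",
        odds_ratio = exp(stats::runif(ng, lo, log(config$or_range[2]))),
        risk_allele_freq = stats::runif(ng, config$raf_range[1],
                                        config$raf_range[2]),
        risk_is_ref = FALSE, stringsAsFactors = FALSE)
    }
    nh <- config$n_high_pen_genes[i]
    nv <- config$n_hp_variants[i]
    high_genes <- if (nh > 0) sprintf("%s_GH%d", ph, seq_len(nh)) else character(0)
    vh_hosts <- if (nv > 0 && nh == 0) sprintf("%s_VH%d", ph, seq_len(nv)) else character(0)
    low_genes <- if (config$n_low_pen_genes[i] > 0)
      sprintf("%s_GL%d", ph, seq_len(config$n_low_pen_genes[i])) else character(0)
    if (nv > 0) {
      hosts <- if (nh > 0) rep_len(high_genes, nv) else vh_hosts
      hp[[ph]] <- data.frame(
        phenotype = ph, chrom = "1", pos = base + 100000L + seq_len(nv),
        ref = "C", alt = "T", gene = hosts, class = "DM",
        stringsAsFactors = FALSE)
    }
    gene_rows <- list()
    if (length(high_genes) > 0) {
      gene_rows$high <- data.frame(phenotype = ph, gene = high_genes,
                                   penetrance_class = "HIGH", zscore = NA_real_,
                                   stringsAsFactors = FALSE)
    }
    if (length(low_genes) > 0) {
      gene_rows$low <- data.frame(phenotype = ph, gene = low_genes,
                                  penetrance_class = "LOW",
                                  zscore = stats::runif(length(low_genes), 4.5, 10),
                                  stringsAsFactors = FALSE)
    }
    if (length(gene_rows) > 0) genes[[ph]] <- do.call(rbind, gene_rows)

    all_genes <- c(high_genes, vh_hosts, low_genes)
    for (gi in seq_along(all_genes)) {
      g <- all_genes[gi]
      gbase <- base + 200000L + gi * 1000L
      nsite <- config$sites_per_gene
      rare_pos <- gbase + seq_len(nsite)
      sites[[g]] <- data.frame(
        chrom = "1",
        pos = c(rare_pos, gbase + 900L, gbase + 901L),
        ref = "G", alt = "A", gene = g,
        consequence = c(rep("missense", nsite), "synonymous", "missense"),
        stringsAsFactors = FALSE)
      # record MAFs for half of the rare sites; the common site gets 0.02
      observed <- rare_pos[seq_len(floor(nsite / 2))]
      freqs[[g]] <- data.frame(
        chrom = "1",
        pos = rep(c(observed, gbase + 901L), each = 2),
        alt = "A",
        population = rep(c("EUR", "AFR"), length(observed) + 1),
        maf = c(rep(stats::runif(length(observed), 0.0001, 0.009), each = 2),
                0.02, 0.02),
        stringsAsFactors = FALSE)
    }
    prev[[ph]] <- data.frame(phenotype = ph, ancestry = "ALL", gender = "ALL",
                             age_lo = NA_real_, age_hi = NA_real_,
                             prevalence = config$prevalence[i],
                             source = "synthetic", stringsAsFactors = FALSE)
  }
  bind <- function(lst, cols) if (length(lst) > 0) do.call(rbind, unname(lst)) else NULL
  annotation_kb(gwas = bind(gwas), hp_variants = bind(hp), genes = bind(genes),
                sites = bind(sites), freqs = bind(freqs),
                prevalence = do.call(rbind, unname(prev)))
}

#' Generate a synthetic cohort from a knowledge base
#'
#' Draws, per participant: demographics uniform over the declared
#' vocabularies; GWAS genotype doses from Hardy-Weinberg proportions at the
#' hit's risk allele frequency; high-penetrance variant carriage as
#' Bernoulli(hp_carrier_freq) heterozygotes; per-gene rare non-silent
#' variant counts as Poisson draws over the gene's candidate sites.
#' Per-site functional p-values are assigned once for the whole cohort:
#' Beta(a, 1) at damaging sites (a `damaging_site_frac` fraction of the
#' rare non-silent candidates) and Uniform(0,1) elsewhere. Phenotype status
#' is then drawn as Bernoulli(posterior) using the model's own forward
#' closed form with the configured parameters.
#'
#' @param kb the [annotation_kb()] from [gen_kb()] (same config).
#' @param config a [sim_config()].
#' @return List: `genomes` (list of [personal_genome()]), `statuses`
#'   (participant x phenotype integer matrix), `scores` (per-variant
#'   p-value table), `posteriors` (the forward posteriors, long format).
#' @export
gen_cohort <- function(kb, config) {
  force(kb)  # must be evaluated before reseeding (kb may come from gen_kb)
  set.seed(config$seed + 1L)
  phenos <- sim_phenotype_names(config)
  n <- config$n_participants
  ids <- sprintf("PGP%04d", seq_len(n))
  genders <- sample(c("F", "M"), n, replace = TRUE)
  ancestries <- sample(c("European", "African", "Asian"), n, replace = TRUE)
  ages <- sample(20:79, n, replace = TRUE)

  # per-site functional p-values (a property of the variant, not the carrier)
  scores <- kb$sites[c("chrom", "pos", "ref", "alt")]
  is_cand <- kb$sites$consequence %in% NONSILENT_CLASSES
  damaging <- is_cand & stats::runif(nrow(scores)) < config$damaging_site_frac
  p <- stats::runif(nrow(scores))
  if (any(damaging)) {
    p[damaging] <- stats::rbeta(sum(damaging), config$beta_shape, 1)
  }
  scores$p_value <- pmax(p, 1e-10)

  gene_sites <- split(seq_len(nrow(kb$sites)), kb$sites$gene)
  genomes <- vector("list", n)
  for (pi in seq_len(n)) {
    calls <- list()
    if (nrow(kb$gwas) > 0) {
      dose <- stats::rbinom(nrow(kb$gwas), 2, kb$gwas$risk_allele_freq)
      carried <- dose > 0
      if (any(carried)) {
        calls$gwas <- data.frame(
          chrom = kb$gwas$chrom[carried], pos = kb$gwas$pos[carried],
          ref = kb$gwas$other_allele[carried],
          alt = kb$gwas$risk_allele[carried],
          allele_count = as.integer(dose[carried]), stringsAsFactors = FALSE)
      }
    }
    if (nrow(kb$hp_variants) > 0) {
      cf <- config$hp_carrier_freq[match(kb$hp_variants$phenotype, phenos)]
      carrier <- stats::runif(nrow(kb$hp_variants)) < cf
      if (any(carrier)) {
        calls$hp <- data.frame(
          chrom = kb$hp_variants$chrom[carrier],
          pos = kb$hp_variants$pos[carrier],
          ref = kb$hp_variants$ref[carrier], alt = kb$hp_variants$alt[carrier],
          allele_count = 1L, stringsAsFactors = FALSE)
      }
    }
    if (config$rare_variant_mean > 0 && length(gene_sites) > 0) {
      picked <- integer(0)
      for (g in names(gene_sites)) {
        cand <- gene_sites[[g]]
        cand <- cand[kb$sites$consequence[cand] %in% NONSILENT_CLASSES]
        if (length(cand) == 0) next
        k <- min(stats::rpois(1, config$rare_variant_mean), length(cand))
        if (k > 0) picked <- c(picked, sample(cand, k))
      }
      if (length(picked) > 0) {
        calls$genes <- data.frame(
          chrom = kb$sites$chrom[picked], pos = kb$sites$pos[picked],
          ref = kb$sites$ref[picked], alt = kb$sites$alt[picked],
          allele_count = 1L, stringsAsFactors = FALSE)
      }
    }
    df <- if (length(calls) > 0) do.call(rbind, unname(calls)) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), allele_count = integer(),
                 stringsAsFactors = FALSE)
    genomes[[pi]] <- personal_genome(ids[pi], df, ages[pi], genders[pi],
                                     ancestries[pi])
  }

  posteriors <- predict_cohort(genomes, phenos, kb, scores, config$params,
                               mode = "full")
  pm <- posterior_matrix(posteriors)
  statuses <- matrix(stats::rbinom(length(pm), 1, as.vector(pm)),
                     nrow(pm), ncol(pm), dimnames = dimnames(pm))
  list(genomes = genomes, statuses = statuses, scores = scores,
       posteriors = posteriors)
}

#' Generate phenotypic profiles, decoys, eligibility and truth
#'
#' True profiles copy each participant's statuses with unknown masking at
#' the configured missingness rate. Decoys are drawn from the
#' prevalence-marginal distribution of each phenotype and masked the same
#' way. A configurable fraction of decoys is flagged ineligible (profiles
#' known to have no sequenced sample).
#'
#' @param statuses participant x phenotype status matrix from
#'   [gen_cohort()].
#' @param config a [sim_config()].
#' @param n_decoys number of decoy profiles.
#' @param ineligible_frac fraction of decoys flagged ineligible.
#' @param seed RNG seed (defaults to the config seed plus 2).
#' @return List: `profiles` (matrix), `eligible` (named logical), `truth`
#'   (named character vector, genome id -> profile id).
#' @export
gen_profiles <- function(statuses, config, n_decoys = 10,
                         ineligible_frac = 0.5, seed = config$seed + 2L) {
  force(statuses)
  set.seed(seed)
  miss <- config$profile_missingness
  phenos <- colnames(statuses)
  true_ids <- paste0("PR_", rownames(statuses))
  true_prof <- statuses
  rownames(true_prof) <- true_ids
  if (miss > 0 && length(true_prof) > 0) {
    mask <- stats::runif(length(true_prof)) < miss
    true_prof[mask] <- NA_integer_
  }
  if (n_decoys > 0) {
    prev <- rep_len(config$prevalence, length(phenos))
    dec <- matrix(stats::rbinom(n_decoys * length(phenos), 1,
                                rep(prev, each = n_decoys)),
                  n_decoys, length(phenos),
                  dimnames = list(sprintf("DECOY%03d", seq_len(n_decoys)), phenos))
    if (miss > 0) {
      mask <- stats::runif(length(dec)) < miss
      dec[mask] <- NA_integer_
    }
    profiles <- rbind(true_prof, dec)
  } else {
    profiles <- true_prof
  }
  eligible <- stats::setNames(rep(TRUE, nrow(profiles)), rownames(profiles))
  if (n_decoys > 0 && ineligible_frac > 0) {
    n_inelig <- floor(n_decoys * ineligible_frac)
    if (n_inelig > 0) {
      inelig <- sample(sprintf("DECOY%03d", seq_len(n_decoys)), n_inelig)
      eligible[inelig] <- FALSE
    }
  }
  truth <- stats::setNames(true_ids, rownames(statuses))
  list(profiles = profiles, eligible = eligible, truth = truth)
}

#' Write a full simulated dataset to disk
#'
#' Emits the TSV dialects the other modules read: the knowledge-base files,
#' per-participant `genome_<id>.tsv` files plus `participants.tsv`
#' metadata, `phenotypes.tsv`, `scores.tsv`, `profiles.tsv` and
#' `eligibility.tsv`. The seed is recorded in `sim_meta.tsv`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  kb <- gen_kb(config)
  cohort <- gen_cohort(kb, config)
  prof <- gen_profiles(cohort$statuses, config)
  write_kb(kb, outdir)
  meta <- do.call(rbind, lapply(cohort$genomes, function(g) {
    data.frame(participant_id = g$participant_id, age = g$age,
               gender = g$gender, ancestry = g$ancestry,
               stringsAsFactors = FALSE)
  }))
  write_tsv(meta, file.path(outdir, "participants.tsv"))
  for (g in cohort$genomes) {
    write_genome_tsv(g, file.path(outdir, sprintf("genome_%s.tsv", g$participant_id)))
  }
  write_phenotypes(cohort$statuses, file.path(outdir, "phenotypes.tsv"))
  write_tsv(cohort$scores, file.path(outdir, "scores.tsv"))
  write_profiles(prof$profiles, prof$eligible,
                 file.path(outdir, "profiles.tsv"),
                 file.path(outdir, "eligibility.tsv"))
  write_tsv(data.frame(key = "seed", value = config$seed),
            file.path(outdir, "sim_meta.tsv"))
  invisible(outdir)
}
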