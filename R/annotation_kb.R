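# Knowledge layer: phenotype-associated variants and genes, their penetrance
# classes, site-level annotations (consequence, allele frequencies) and the
# prevalence table used as the model's prior.

#' Construct an annotation knowledge base
#'
#' Bundles the per-phenotype annotation collections the predictive model
#' consumes: GWAS hits (low-penetrance variants), curated high-penetrance
#' variants, phenotype-associated genes labelled `HIGH` or `LOW` penetrance,
#' site-level consequence annotations, per-population allele frequencies, and
#' the stratified prevalence table.
#'
#' Invariants enforced here: every high-penetrance variant's host gene is
#' present as a `HIGH` gene association for the same phenotype (it is
#' auto-added when absent); duplicate (phenotype, site, allele) records are
#' dropped, keeping the first.
#'
#' @param gwas data.frame with columns `phenotype`, `rsid`, `chrom`, `pos`,
#'   `risk_allele`, `other_allele`, `odds_ratio`, `risk_allele_freq` and
#'   optionally `risk_is_ref` (logical; whether the risk allele is the genome
#'   reference allele at the site, default `FALSE`).
#' @param hp_variants data.frame with columns `phenotype`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `class`.
#' @param genes data.frame with columns `phenotype`, `gene`,
#'   `penetrance_class` (`"HIGH"` or `"LOW"`), `zscore` (`NA` marks a curated
#'   association; a number marks a literature-mined one).
#' @param sites data.frame mapping variant sites to genes and consequence
#'   labels: columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`.
#' @param freqs data.frame of per-population allele frequencies: columns
#'   `chrom`, `pos`, `alt`, `population`, `maf`.
#' @param prevalence data.frame prevalence table: columns `phenotype`,
#'   `ancestry`, `gender`, `age_lo`, `age_hi`, `prevalence`, `source`.
#'   `"ALL"` is the wildcard for ancestry/gender; `NA` age bounds are open.
#' @return An object of class `annotation_kb`.
#' @export
annotation_kb <- function(gwas = NULL, hp_variants = NULL, genes = NULL,
                          sites = NULL, freqs = NULL, prevalence = NULL) {
  gwas <- kb_default(gwas, c("phenotype", "rsid", "chrom", "pos", "risk_allele",
                             "other_allele", "odds_ratio", "risk_allele_freq"))
  hp_variants <- kb_default(hp_variants,
                            c("phenotype", "chrom", "pos", "ref", "alt", "gene", "class"))
  genes <- kb_default(genes, c("phenotype", "gene", "penetrance_class", "zscore"))
  sites <- kb_default(sites, c("chrom", "pos", "ref", "alt", "gene", "consequence"))
  freqs <- kb_default(freqs, c("chrom", "pos", "alt", "population", "maf"))
  prevalence <- kb_default(prevalence, c("phenotype", "ancestry", "gender",
                                         "age_lo", "age_hi", "prevalence", "source"))

  if (!"risk_is_ref" %in% names(gwas)) gwas$risk_is_ref <- rep(FALSE, nrow(gwas))
  gwas$risk_is_ref[is.na(gwas$risk_is_ref)] <- FALSE

  if (nrow(gwas) > 0) {
    if (any(!is.finite(gwas$odds_ratio) | gwas$odds_ratio <= 0)) {
      stopf("GWAS hit with non-positive odds ratio: %s",
            paste(gwas$rsid[!is.finite(gwas$odds_ratio) | gwas$odds_ratio <= 0],
                  collapse = ", "))
    }
    bad_f <- gwas$risk_allele_freq <= 0 | gwas$risk_allele_freq >= 1
    if (any(bad_f)) {
      stopf("GWAS risk allele frequency outside (0,1): %s",
            paste(gwas$rsid[bad_f], collapse = ", "))
    }
    if (any(gwas$risk_allele == gwas$other_allele)) {
      stopf("GWAS hit with identical risk and other alleles")
    }
    gwas <- gwas[!duplicated(gwas[c("phenotype", "chrom", "pos", "risk_allele")]), ,
                 drop = FALSE]
  }
  if (nrow(hp_variants) > 0) {
    hp_variants <- hp_variants[!duplicated(hp_variants[c("phenotype", "chrom",
                                                         "pos", "alt")]), ,
                               drop = FALSE]
  }
  if (nrow(genes) > 0 && !all(genes$penetrance_class %in% c("HIGH", "LOW"))) {
    stopf("penetrance_class must be HIGH or LOW")
  }
  if (nrow(prevalence) > 0) {
    bad <- prevalence$prevalence <= 0 | prevalence$prevalence >= 1
    if (any(bad)) stopf("prevalence values must lie in (0,1)")
  }

  # hp-variant host genes must be HIGH gene associations for that phenotype
  if (nrow(hp_variants) > 0) {
    have <- paste(genes$phenotype, genes$gene)[genes$penetrance_class == "HIGH"]
    need <- unique(hp_variants[c("phenotype", "gene")])
    miss <- need[!paste(need$phenotype, need$gene) %in% have, , drop = FALSE]
    if (nrow(miss) > 0) {
      genes <- rbind(genes, data.frame(phenotype = miss$phenotype,
                                       gene = miss$gene,
                                       penetrance_class = "HIGH",
                                       zscore = NA_real_,
                                       stringsAsFactors = FALSE))
    }
  }
  genes <- genes[!duplicated(genes[c("phenotype", "gene", "penetrance_class")]), ,
                 drop = FALSE]

  structure(list(gwas = reset_rows(gwas), hp_variants = reset_rows(hp_variants),
                 genes = reset_rows(genes), sites = reset_rows(sites),
                 freqs = reset_rows(freqs), prevalence = reset_rows(prevalence)),
            class = "annotation_kb")
}

kb_default <- function(df, cols) {
  if (is.null(df)) {
    return(as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stopf("missing column(s): %s", paste(missing, collapse = ", "))
  }
  as.data.frame(df, stringsAsFactors = FALSE)
}

reset_rows <- function(df) { rownames(df) <- NULL; df }

#' @export
print.annotation_kb <- function(x, ...) {
  cat("annotation_kb:",
      nrow(x$gwas), "GWAS hits,",
      nrow(x$hp_variants), "high-penetrance variants,",
      nrow(x$genes), "gene associations,",
      nrow(x$prevalence), "prevalence rows\n")
  invisible(x)
}

#' Filter GWAS hits by effect size
#'
#' Keeps hits whose odds ratio is strictly greater than 1 and at most 20,
#' the admissibility window for low-penetrance variant annotations. Effect
#' sizes reported as beta regression coefficients (flagged with a logical
#' `effect_is_beta` column) are interpreted as log-odds and exponentiated
#' before filtering; the returned records carry an `effect_converted` flag
#' recording which convention applied.
#'
#' The filter is idempotent and preserves input order.
#'
#' @param hits data.frame of GWAS hits (see [annotation_kb()]).
#' @return The subset of `hits` with odds ratio in (1, 20].
#' @export
filter_gwas_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  or <- hits$odds_ratio
  converted <- rep(FALSE, nrow(hits))
  if ("effect_is_beta" %in% names(hits)) {
    is_beta <- !is.na(hits$effect_is_beta) & hits$effect_is_beta
    or[is_beta] <- exp(or[is_beta])
    converted <- is_beta
  }
  if (any(is.na(or) | or <= 0)) {
    bad <- which(is.na(or) | or <= 0)
    stopf("non-positive or missing effect size for record(s): %s",
          paste(if ("rsid" %in% names(hits)) hits$rsid[bad] else bad, collapse = ", "))
  }
  hits$odds_ratio <- or
  hits$effect_converted <- converted
  hits$effect_is_beta <- NULL
  hits[or > 1 & or <= 20, , drop = FALSE]
}

#' Filter gene associations
#'
#' Curated associations (those with no Z-score) are always kept. Mined
#' associations are kept if their Z-score exceeds 4.0 or they rank in the
#' top 5 associated genes for their phenotype by Z-score. Rank ties at the
#' fifth position are broken by stable input order.
#'
#' @param assocs data.frame of gene associations with columns `phenotype`,
#'   `gene`, `penetrance_class`, `zscore` (`NA` = curated).
#' @return The retained subset, in input order.
#' @export
filter_gene_associations <- function(assocs) {
  if (nrow(assocs) == 0) return(assocs)
  curated <- is.na(assocs$zscore)
  keep <- curated
  mined_idx <- which(!curated)
  if (length(mined_idx) > 0) {
    z <- assocs$zscore[mined_idx]
    if (any(!is.finite(z))) stopf("mined association lacking a finite Z-score")
    for (ph in unique(assocs$phenotype[mined_idx])) {
      rows <- mined_idx[assocs$phenotype[mined_idx] == ph]
      # ties.method "first" keeps the stable input order of equal Z-scores
      rk <- rank(-assocs$zscore[rows], ties.method = "first")
      keep[rows] <- assocs$zscore[rows] > 4.0 | rk <= 5
    }
  }
  assocs[keep, , drop = FALSE]
}

#' Admit a high-penetrance variant record
#'
#' Variants enter the high-penetrance category only when they belong to the
#' most confident curated disease-mutation class, labelled `"DM"`. Weaker
#' classes (e.g. `"DM?"`, `"DP"`) are rejected.
#'
#' @param class character vector of source class labels.
#' @return Logical vector, `TRUE` where the record is admitted.
#' @export
admit_high_penetrance_variant <- function(class) {
  if (is.data.frame(class)) class <- class$class
  !is.na(class) & class == "DM"
}

#' Look up phenotype prevalence for an individual
#'
#' Returns the most specific prevalence entry matching the individual's
#' ancestry, gender and age, falling back through progressively coarser keys:
#' exact (ancestry, gender, age band), then dropping the age band, then the
#' ancestry, then the gender, down to the phenotype-global row. `"ALL"` rows
#' match any ancestry/gender; open (`NA`) age bounds match any age.
#'
#' @param table prevalence data.frame (see [annotation_kb()]).
#' @param phenotype phenotype identifier.
#' @param ancestry,gender individual's labels.
#' @param age age in years.
#' @return Prevalence in (0,1), or `NA_real_` when the phenotype has no
#'   prevalence entry at all (the "no prevalence" signal: such phenotypes are
#'   excluded from prediction).
#' @export
lookup_prevalence <- function(table, phenotype, ancestry, gender, age) {
  rows <- table[table$phenotype == phenotype, , drop = FALSE]
  if (nrow(rows) == 0) return(NA_real_)
  lo <- ifelse(is.na(rows$age_lo), -Inf, rows$age_lo)
  hi <- ifelse(is.na(rows$age_hi), Inf, rows$age_hi)
  anc_ok <- rows$ancestry == "ALL" | rows$ancestry == ancestry
  gen_ok <- rows$gender == "ALL" | rows$gender == gender
  age_ok <- age >= lo & age < hi
  cand <- which(anc_ok & gen_ok & age_ok)
  if (length(cand) == 0) return(NA_real_)
  anc_spec <- rows$ancestry[cand] != "ALL"
  gen_spec <- rows$gender[cand] != "ALL"
  age_spec <- !(is.na(rows$age_lo[cand]) & is.na(rows$age_hi[cand]))
  # fallback chain: full key > drop age band > drop ancestry > drop gender
  tier <- ifelse(anc_spec & gen_spec & age_spec, 1L,
          ifelse(anc_spec & gen_spec, 2L,
          ifelse(gen_spec & !anc_spec, 3L,
          ifelse(!anc_spec & !gen_spec, 4L, 5L))))
  pick <- cand[order(tier)][1]
  rows$prevalence[pick]
}

#' Load a knowledge base from TSV files
#'
#' Reads the knowledge-base dialect: `kb_gwas.tsv`, `kb_hpvariants.tsv`,
#' `kb_genes.tsv`, `kb_sites.tsv`, `kb_freqs.tsv`, `prevalence.tsv` (all
#' tab-separated with a header row; missing files yield empty collections).
#' When `apply_filters = TRUE` the admission rules are applied on load:
#' odds-ratio window for GWAS hits, Z-score/top-5 rule for mined gene
#' associations, and the DM-class rule for high-penetrance variants.
#'
#' @param dir directory containing the TSV files.
#' @param apply_filters apply the admission filters on load (default `TRUE`).
#' @return An [annotation_kb()] object.
#' @export
load_kb <- function(dir, apply_filters = TRUE) {
  gwas <- read_tsv_checked(file.path(dir, "kb_gwas.tsv"),
    c("phenotype", "rsid", "chrom", "pos", "risk_allele", "other_allele",
      "odds_ratio", "risk_allele_freq"),
    coltypes = list(pos = "integer", odds_ratio = "numeric",
                    risk_allele_freq = "numeric", chrom = "character"))
  hp <- read_tsv_checked(file.path(dir, "kb_hpvariants.tsv"),
    c("phenotype", "chrom", "pos", "ref", "alt", "gene", "class"),
    coltypes = list(pos = "integer", chrom = "character"))
  genes <- read_tsv_checked(file.path(dir, "kb_genes.tsv"),
    c("phenotype", "gene", "penetrance_class", "zscore"),
    coltypes = list(zscore = "numeric"))
  sites <- read_tsv_checked(file.path(dir, "kb_sites.tsv"),
    c("chrom", "pos", "ref", "alt", "gene", "consequence"),
    coltypes = list(pos = "integer", chrom = "character"))
  freqs <- read_tsv_checked(file.path(dir, "kb_freqs.tsv"),
    c("chrom", "pos", "alt", "population", "maf"),
    coltypes = list(pos = "integer", maf = "numeric", chrom = "character"))
  prev <- read_tsv_checked(file.path(dir, "prevalence.tsv"),
    c("phenotype", "ancestry", "gender", "age_lo", "age_hi", "prevalence", "source"),
    coltypes = list(age_lo = "numeric", age_hi = "numeric", prevalence = "numeric"))
  if ("risk_is_ref" %in% names(gwas)) {
    gwas$risk_is_ref <- as.logical(gwas$risk_is_ref)
  }
  if (apply_filters) {
    if (nrow(gwas) > 0) gwas <- filter_gwas_hits(gwas)
    if (nrow(genes) > 0) genes <- filter_gene_associations(genes)
    if (nrow(hp) > 0) hp <- hp[admit_high_penetrance_variant(hp$class), , drop = FALSE]
  }
  annotation_kb(gwas = gwas, hp_variants = hp, genes = genes,
                sites = sites, freqs = freqs, prevalence = prev)
}

#' Write a knowledge base to TSV files
#'
#' Inverse of [load_kb()]: writes the six TSV files into `dir`. A KB written
#' and re-loaded (with filters off) reproduces itself.
#'
#' @param kb an [annotation_kb()] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_kb <- function(kb, dir) {
  stopifnot(inherits(kb, "annotation_kb"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gwas <- kb$gwas
  gwas$effect_converted <- NULL
  write_tsv(gwas, file.path(dir, "kb_gwas.tsv"))
  write_tsv(kb$hp_variants, file.path(dir, "kb_hpvariants.tsv"))
  write_tsv(kb$genes, file.path(dir, "kb_genes.tsv"))
  write_tsv(kb$sites, file.path(dir, "kb_sites.tsv"))
  write_tsv(kb$freqs, file.path(dir, "kb_freqs.tsv"))
  write_tsv(kb$prevalence, file.path(dir, "prevalence.tsv"))
  invisible(dir)
}
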