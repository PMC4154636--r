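# Gene-level functional scoring: Fisher's method over per-variant functional
# p-values, and the posterior probability that the gene product is altered.

#' Parameters of the gene-alteration model
#'
#' The gene-level statistic T (Fisher's method over k variant p-values) is
#' compared between two hypotheses. Under the null (no functional
#' alteration) the variant p-values are Uniform(0,1), so T follows a
#' chi-square distribution with 2k degrees of freedom. Under the alternative
#' the p-values of damaging variants are modelled as Beta(a, 1) with
#' `beta_shape` a in (0,1]; -2 log p is then Exponential with rate a/2, so T
#' follows a Gamma(k, rate = a/2). Bayes' rule with prior `prior_altered`
#' gives the posterior probability of alteration.
#'
#' @param prior_altered prior probability that the gene is functionally
#'   altered given it carries rare non-silent variants (default 0.05).
#' @param beta_shape shape a of the Beta(a,1) p-value model for damaging
#'   variants (default 0.3); smaller a means damaging variants concentrate
#'   at small p-values, a = 1 collapses the alternative onto the null.
#' @return List of class `alteration_params`.
#' @export
alteration_params <- function(prior_altered = 0.05, beta_shape = 0.3) {
  if (!is_prob(prior_altered) || prior_altered <= 0 || prior_altered >= 1) {
    stopf("prior_altered must be in (0,1)")
  }
  if (!is.numeric(beta_shape) || beta_shape <= 0 || beta_shape > 1) {
    stopf("beta_shape must be in (0,1]")
  }
  structure(list(prior_altered = prior_altered, beta_shape = beta_shape),
            class = "alteration_params")
}

#' Combine variant p-values with Fisher's method
#'
#' Computes the gene-level statistic T = -2 * sum(log p_i) over the k
#' supplied p-values. P-values are floored at 1e-10 before taking logs so a
#' reported zero cannot produce an infinite statistic.
#'
#' @param pvalues numeric vector of p-values in (0,1].
#' @return List of class `gene_statistic` with elements `T` and `k`, or
#'   `NULL` when `pvalues` is empty (the "no evidence" signal).
#' @export
combine_fisher <- function(pvalues) {
  if (length(pvalues) == 0) return(NULL)
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stopf("p-values must lie in (0,1]")
  }
  p <- pmax(pvalues, 1e-10)
  structure(list(T = -2 * sum(log(p)), k = length(p)), class = "gene_statistic")
}

#' Posterior probability that a gene is functionally altered
#'
#' Applies Bayes' rule to a Fisher statistic: the chi-square(2k) null density
#' and the Gamma(k, a/2) alternative density have the closed-form ratio
#' f_alt/f_null = a^k * exp((1-a) T / 2), so the posterior log-odds are
#' logit(rho) + k log a + (1-a) T / 2. The result is strictly increasing in
#' T for a < 1 and equals the prior `rho` for every T when a = 1.
#'
#' @param stat a `gene_statistic` from [combine_fisher()].
#' @param params an [alteration_params()].
#' @return Posterior probability in (0,1).
#' @export
gene_alteration_posterior <- function(stat, params = alteration_params()) {
  if (!inherits(stat, "gene_statistic")) stopf("stat must come from combine_fisher()")
  if (!inherits(params, "alteration_params")) stopf("invalid params")
  a <- params$beta_shape
  rho <- params$prior_altered
  logit <- stats::qlogis(rho) + stat$k * log(a) + (1 - a) * stat$T / 2
  stats::plogis(logit)
}

#' Score a gene for one individual
#'
#' Composition of rare non-silent variant selection, Fisher combination and
#' the alteration posterior. A gene with no qualifying scored variants
#' contributes probability 0.
#'
#' @param genome a [personal_genome()].
#' @param gene gene symbol.
#' @param kb an [annotation_kb()].
#' @param scores data.frame of per-variant functional p-values with columns
#'   `chrom`, `pos`, `ref`, `alt`, `p_value` (the pluggable scorer contract:
#'   any method producing per-variant p-values qualifies).
#' @param params an [alteration_params()].
#' @param on_missing_score `"skip"` (default) drops variants without a
#'   p-value; `"error"` rejects them.
#' @param ... passed to [select_rare_nonsilent()] (e.g. `rare_in`).
#' @return Probability that the gene is functionally altered, in \[0,1).
#' @export
score_gene <- function(genome, gene, phenotype = NULL, kb, scores,
                       params = alteration_params(),
                       on_missing_score = c("skip", "error"), ...) {
  on_missing_score <- match.arg(on_missing_score)
  calls <- select_rare_nonsilent(genome, gene, kb, ...)
  if (nrow(calls) == 0) return(0)
  ck <- site_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  sk <- site_key(scores$chrom, scores$pos, scores$ref, scores$alt)
  idx <- match(ck, sk)
  if (any(is.na(idx))) {
    if (on_missing_score == "error") {
      stopf("no functional score for variant(s): %s",
            paste(ck[is.na(idx)], collapse = ", "))
    }
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0) return(0)
  stat <- combine_fisher(scores$p_value[idx])
  gene_alteration_posterior(stat, params)
}

#' Read a per-variant functional score table
#'
#' @param path `scores.tsv` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `p_value`.
#' @return data.frame.
#' @export
read_scores <- function(path) {
  read_tsv_checked(path, c("chrom", "pos", "ref", "alt", "p_value"),
                   coltypes = list(pos = "integer", p_value = "numeric",
                                   chrom = "character"))
}
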