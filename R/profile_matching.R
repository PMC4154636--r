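# Genome-to-phenotypic-profile matching: Bernoulli likelihood over known
# statuses, profile ranking, truth-based evaluation, and the uniformly
# random matching null.

#' Bernoulli log-likelihood of a phenotypic profile given posteriors
#'
#' Sums, over phenotypes whose status is known in the profile, log(p) when
#' the profile reports the phenotype PRESENT and log(1 - p) when ABSENT,
#' where p is the genome's posterior probability clamped into
#' \[eps, 1 - eps\]. Unknown statuses are skipped, so an all-unknown profile
#' has log-likelihood 0 (the empty product).
#'
#' @param posteriors named numeric vector, phenotype -> posterior
#'   probability.
#' @param profile named vector of statuses in `{1, 0, NA}` (present /
#'   absent / unknown), phenotype names matching `posteriors`.
#' @param eps clamp width in (0, 0.5), default 1e-6.
#' @return Log-likelihood, or `NA` when the profile shares no known-status
#'   phenotype with the posterior map (the "no overlap" signal).
#' @export
match_loglik <- function(posteriors, profile, eps = 1e-6) {
  if (eps <= 0 || eps >= 0.5) stopf("eps must lie in (0, 0.5)")
  common <- intersect(names(posteriors), names(profile))
  if (length(common) == 0) return(NA_real_)  # no overlap signal
  known <- common[!is.na(profile[common])]
  if (length(known) == 0) return(0)  # all-unknown profile: empty product
  p <- pmin(pmax(posteriors[known], eps), 1 - eps)
  y <- profile[known]
  sum(ifelse(y == 1, log(p), log1p(-p)))
}

#' Rank phenotypic profiles for one genome
#'
#' Ineligible profiles (decoys known to belong to no sequenced sample) are
#' excluded up front; the rest are ranked by descending Bernoulli
#' log-likelihood, ties broken by ascending profile id.
#'
#' @param posteriors named numeric vector of the genome's per-phenotype
#'   posteriors.
#' @param profiles matrix (profiles x phenotypes) of statuses in
#'   `{1,0,NA}`, profile ids as rownames.
#' @param eligible logical vector named by profile id; `NULL` means all
#'   eligible.
#' @param eps clamp width for [match_loglik()].
#' @return data.frame `profile_id`, `loglik`, `rank` (class
#'   `match_result`), best first.
#' @export
rank_profiles <- function(posteriors, profiles, eligible = NULL, eps = 1e-6) {
  ids <- rownames(profiles)
  if (!is.null(eligible)) {
    keep <- ids[eligible[ids]]
  } else {
    keep <- ids
  }
  if (length(keep) == 0) stopf("no eligible profiles")
  ll <- vapply(keep, function(pid) {
    match_loglik(posteriors, profiles[pid, ], eps)
  }, numeric(1))
  ord <- order(-ll, keep)
  out <- data.frame(profile_id = keep[ord], loglik = ll[ord],
                    rank = seq_along(keep), stringsAsFactors = FALSE)
  class(out) <- c("match_result", class(out))
  out
}

#' Evaluate profile matching against truth
#'
#' @param results named list of [rank_profiles()] outputs, one per genome.
#' @param truth named character vector mapping each genome id to its true
#'   profile id.
#' @return List: `n_top1_correct`, `mean_rank_of_truth`, `ranks` (named
#'   vector of the truth's rank per genome; `NA` when the true profile was
#'   not among the eligible candidates).
#' @export
evaluate_matching <- function(results, truth) {
  if (length(results) == 0) {
    return(list(n_top1_correct = 0L, mean_rank_of_truth = NA_real_,
                ranks = stats::setNames(numeric(0), character(0))))
  }
  missing <- setdiff(names(results), names(truth))
  if (length(missing) > 0) {
    stopf("genome(s) missing from the truth map: %s",
          paste(missing, collapse = ", "))
  }
  ranks <- vapply(names(results), function(gid) {
    res <- results[[gid]]
    i <- match(truth[[gid]], res$profile_id)
    if (is.na(i)) NA_real_ else res$rank[i]
  }, numeric(1))
  list(n_top1_correct = sum(ranks == 1, na.rm = TRUE),
       mean_rank_of_truth = mean(ranks, na.rm = TRUE),
       ranks = ranks)
}

#' Significance of a top-1 match count under random matching
#'
#' Null model of the matching experiment: for each genome, every phenotypic
#' profile is equally probable, so each genome's top-ranked profile is drawn
#' independently and uniformly from the eligible profiles. The simulation
#' records, per trial, how many genomes hit their true profile; the
#' empirical significance is the fraction of trials reaching `threshold` or
#' more correct top-1 matches. The exact value, from the
#' Binomial(n_genomes, 1/n_profiles) upper tail, is returned alongside.
#'
#' @param n_genomes number of genomes.
#' @param n_profiles number of eligible profiles.
#' @param threshold observed count of correct top-1 matches.
#' @param n_trials number of simulated matchings (default 10000).
#' @param seed RNG seed.
#' @param permutation if `TRUE`, draw each trial's matching as a permutation
#'   without replacement instead of independent uniform picks.
#' @return List: `significance` (empirical fraction), `exact` (binomial
#'   upper tail; `NA` under the permutation null), `counts` (per-trial
#'   correct counts).
#' @export
null_matching_significance <- function(n_genomes, n_profiles, threshold,
                                       n_trials = 10000, seed = 1,
                                       permutation = FALSE) {
  stopifnot(n_genomes >= 1, n_profiles >= 1, n_trials >= 1)
  set.seed(seed)
  if (threshold <= 0) {
    exact <- 1
  } else {
    exact <- stats::pbinom(threshold - 1, n_genomes, 1 / n_profiles,
                           lower.tail = FALSE)
  }
  counts <- integer(n_trials)
  # genome i's true profile, wlog cycling through the profile set
  truth <- ((seq_len(n_genomes) - 1L) %% n_profiles) + 1L
  for (t in seq_len(n_trials)) {
    if (permutation) {
      pick <- sample.int(n_profiles)[truth]
    } else {
      pick <- sample.int(n_profiles, n_genomes, replace = TRUE)
    }
    counts[t] <- sum(pick == truth)
  }
  list(significance = mean(counts >= threshold),
       exact = if (permutation) NA_real_ else exact,
       counts = counts)
}

#' Read phenotypic profiles from TSV
#'
#' `profiles.tsv`: columns `profile_id`, `phenotype`, `status` in
#' `{1,0,NA}`. Optional `eligibility.tsv`: `profile_id`, `eligible` in
#' `{1,0}`.
#'
#' @param path profiles TSV path.
#' @param eligibility_path optional eligibility TSV path.
#' @return List: `profiles` (matrix profiles x phenotypes), `eligible`
#'   (named logical vector).
#' @export
read_profiles <- function(path, eligibility_path = NULL) {
  df <- read_tsv_checked(path, c("profile_id", "phenotype", "status"),
                         coltypes = list(status = "integer"))
  ids <- unique(df$profile_id)
  phenos <- unique(df$phenotype)
  m <- matrix(NA_integer_, length(ids), length(phenos),
              dimnames = list(ids, phenos))
  if (nrow(df) > 0) {
    m[cbind(match(df$profile_id, ids), match(df$phenotype, phenos))] <- df$status
  }
  eligible <- stats::setNames(rep(TRUE, length(ids)), ids)
  if (!is.null(eligibility_path)) {
    e <- read_tsv_checked(eligibility_path, c("profile_id", "eligible"),
                          coltypes = list(eligible = "integer"))
    eligible[e$profile_id] <- e$eligible == 1L
  }
  list(profiles = m, eligible = eligible)
}

#' Write phenotypic profiles to TSV
#'
#' @param profiles matrix profiles x phenotypes.
#' @param eligible named logical vector.
#' @param path profiles TSV path.
#' @param eligibility_path eligibility TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, eligible, path, eligibility_path) {
  df <- data.frame(
    profile_id = rep(rownames(profiles), times = ncol(profiles)),
    phenotype = rep(colnames(profiles), each = nrow(profiles)),
    status = as.vector(profiles), stringsAsFactors = FALSE)
  write_tsv(df, path)
  edf <- data.frame(profile_id = names(eligible),
                    eligible = as.integer(eligible), stringsAsFactors = FALSE)
  write_tsv(edf, eligibility_path)
  invisible(path)
}
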