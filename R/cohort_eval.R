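# Cohort evaluation: per-phenotype ranking, Mann-Whitney AUC with
# exclusions, permutation significance (participant and label shuffles),
# Benjamini-Hochberg FDR, and the rare-allele burden baseline.

#' Mann-Whitney AUC
#'
#' Threshold-free ranking metric: the probability that a randomly chosen
#' case outranks a randomly chosen control, with half credit for ties.
#' Computed from rank sums, which is algebraically identical to pair
#' counting. Participants with unknown (`NA`) status are excluded first.
#'
#' @param scores numeric vector.
#' @param statuses vector in `{1, 0, NA}` parallel to `scores`.
#' @return AUC in \[0,1\], or `NA` when no cases or no controls remain (the
#'   "undefined AUC" signal).
#' @export
auc_mw <- function(scores, statuses) {
  keep <- !is.na(statuses) & !is.na(scores)
  s <- scores[keep]; y <- statuses[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Participant-shuffle permutation test
#'
#' Null: scores are exchangeable across participants. Each permutation
#' applies a single participant shuffle to all phenotype columns of the
#' score matrix simultaneously, which preserves the correlation structure
#' among phenotypes within each participant, then recomputes every
#' phenotype's AUC against the fixed status matrix. The p-value is
#' (1 + #\{permuted AUC >= observed\}) / (1 + n_perm).
#'
#' @param score_matrix numeric matrix, participants x phenotypes.
#' @param status_matrix integer matrix in `{1,0,NA}`, aligned with
#'   `score_matrix`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed (mandatory for reproducible reports).
#' @return Named numeric vector of per-phenotype p-values (`NA` where the
#'   observed AUC is undefined).
#' @export
permutation_test_participants <- function(score_matrix, status_matrix,
                                          n_perm = 10000, seed) {
  stopifnot(all(dim(score_matrix) == dim(status_matrix)))
  if (n_perm < 1) stopf("n_perm must be at least 1")
  set.seed(seed)
  n <- nrow(score_matrix)
  obs <- vapply(seq_len(ncol(score_matrix)), function(j) {
    auc_mw(score_matrix[, j], status_matrix[, j])
  }, numeric(1))
  count <- rep(0L, ncol(score_matrix))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    for (j in seq_len(ncol(score_matrix))) {
      if (is.na(obs[j])) next
      a <- auc_mw(score_matrix[idx, j], status_matrix[, j])
      if (!is.na(a) && a >= obs[j]) count[j] <- count[j] + 1L
    }
  }
  p <- (1 + count) / (1 + n_perm)
  p[is.na(obs)] <- NA_real_
  stats::setNames(p, colnames(score_matrix))
}

#' Label-shuffle permutation test
#'
#' Null: the phenotype's status labels are exchangeable across participants
#' (phenotypes treated as independent). Shuffles one phenotype's status
#' vector against the fixed scores. With `exact = TRUE` and exactly one
#' case, the n equally likely case positions are enumerated instead of
#' sampled, giving the analytic p-value r/n for a case at rank r among n.
#'
#' @param scores numeric vector.
#' @param statuses vector in `{1,0,NA}`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param exact enumerate the null exactly (single-case phenotypes only).
#' @return p-value in (0,1\].
#' @export
permutation_test_labels <- function(scores, statuses, n_perm = 10000, seed,
                                    exact = FALSE) {
  keep <- !is.na(statuses) & !is.na(scores)
  s <- scores[keep]; y <- statuses[keep]
  obs <- auc_mw(s, y)
  if (is.na(obs)) return(NA_real_)
  if (exact) {
    if (sum(y == 1) != 1) {
      stopf("exact enumeration is implemented for single-case phenotypes only")
    }
    n <- length(y)
    aucs <- vapply(seq_len(n), function(i) {
      y2 <- rep(0L, n); y2[i] <- 1L
      auc_mw(s, y2)
    }, numeric(1))
    return(sum(aucs >= obs - 1e-12) / n)
  }
  if (n_perm < 1) stopf("n_perm must be at least 1")
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    a <- auc_mw(s, sample(y))
    if (!is.na(a) && a >= obs) count <- count + 1L
  }
  (1 + count) / (1 + n_perm)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control on a vector of (permutation)
#' p-values, via [stats::p.adjust()]. `NA` entries propagate.
#'
#' @param p_values numeric vector of p-values.
#' @return q-values, same length and names.
#' @export
fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Rare-allele burden baseline
#'
#' Simple comparator model: each participant is scored by the number of
#' putatively damaging rare alleles (MAF < 0.01, non-silent, functional
#' p-value below `damaging_threshold`) they carry in the phenotype's
#' annotated gene set, summing allele counts (a homozygous variant counts
#' twice). Participants are ranked by descending burden, ties broken by
#' ascending participant id.
#'
#' @param genomes list of [personal_genome()] objects.
#' @param kb an [annotation_kb()].
#' @param phenotype phenotype identifier (must have an annotated gene set).
#' @param scores per-variant functional p-value table.
#' @param damaging_threshold p-value cutoff for calling a variant damaging
#'   (default 0.05).
#' @return data.frame `participant_id`, `burden`, sorted by rank.
#' @export
burden_baseline <- function(genomes, kb, phenotype, scores,
                            damaging_threshold = 0.05) {
  ga <- kb$genes[kb$genes$phenotype == phenotype, , drop = FALSE]
  gene_set <- unique(ga$gene)
  if (length(gene_set) == 0) stopf("phenotype %s has no annotated gene set", phenotype)
  sk <- site_key(scores$chrom, scores$pos, scores$ref, scores$alt)
  burden <- vapply(genomes, function(g) {
    total <- 0L
    for (gene in gene_set) {
      calls <- suppressWarnings(select_rare_nonsilent(g, gene, kb))
      if (nrow(calls) == 0) next
      idx <- match(site_key(calls$chrom, calls$pos, calls$ref, calls$alt), sk)
      dam <- !is.na(idx) & scores$p_value[idx] < damaging_threshold
      total <- total + sum(calls$allele_count[dam])
    }
    as.integer(total)
  }, integer(1))
  ids <- vapply(genomes, `[[`, character(1), "participant_id")
  out <- data.frame(participant_id = ids, burden = burden,
                    stringsAsFactors = FALSE)
  out[order(-out$burden, out$participant_id), , drop = FALSE]
}

#' Evaluate a cohort of predictions
#'
#' For each phenotype: rank participants by descending posterior (ties by
#' ascending participant id), compute the Mann-Whitney AUC after excluding
#' unknown statuses and participants of a non-applicable gender for
#' gender-specific phenotypes, attach permutation p-values and
#' Benjamini-Hochberg FDR, and emit a rank-ordered status string (one
#' character per participant: `1` case, `0` control, `.` unknown, `x`
#' gender-excluded).
#'
#' @param score_matrix numeric matrix, participants x phenotypes (e.g. from
#'   [posterior_matrix()]).
#' @param status_matrix integer matrix in `{1,0,NA}`, aligned.
#' @param n_perm permutations for significance (default 1000).
#' @param seed RNG seed.
#' @param test `"participants"` (default) or `"labels"`.
#' @param gender_map optional named character vector mapping gender-specific
#'   phenotypes to the applicable gender label.
#' @param genders optional named character vector of participant genders
#'   (required when `gender_map` is given).
#' @return List with `results` (data.frame: phenotype, auc, p_value, fdr,
#'   n_cases, n_controls, n_excluded) and `report` (named character vector
#'   of rank-ordered status strings).
#' @export
evaluate_cohort <- function(score_matrix, status_matrix, n_perm = 1000, seed = 1,
                            test = c("participants", "labels"),
                            gender_map = NULL, genders = NULL) {
  test <- match.arg(test)
  stopifnot(all(dim(score_matrix) == dim(status_matrix)))
  phenos <- colnames(score_matrix)
  ids <- rownames(score_matrix)

  # gender exclusions are applied by masking the status to NA for evaluation
  # but remembered separately for the report
  excluded <- matrix(FALSE, nrow(score_matrix), ncol(score_matrix),
                     dimnames = dimnames(score_matrix))
  if (!is.null(gender_map)) {
    if (is.null(genders)) stopf("gender_map requires participant genders")
    for (ph in intersect(names(gender_map), phenos)) {
      excluded[, ph] <- genders[ids] != gender_map[[ph]]
    }
  }
  eval_status <- status_matrix
  eval_status[excluded] <- NA_integer_

  if (test == "participants") {
    p <- permutation_test_participants(score_matrix, eval_status, n_perm, seed)
  } else {
    p <- vapply(seq_along(phenos), function(j) {
      permutation_test_labels(score_matrix[, j], eval_status[, j], n_perm,
                              seed + j)
    }, numeric(1))
    names(p) <- phenos
  }

  rows <- lapply(seq_along(phenos), function(j) {
    st <- eval_status[, j]
    data.frame(phenotype = phenos[j],
               auc = auc_mw(score_matrix[, j], st),
               p_value = p[j],
               n_cases = sum(st == 1, na.rm = TRUE),
               n_controls = sum(st == 0, na.rm = TRUE),
               n_excluded = sum(excluded[, j]),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$fdr <- fdr(results$p_value)
  results <- results[c("phenotype", "auc", "p_value", "fdr",
                       "n_cases", "n_controls", "n_excluded")]

  report <- vapply(seq_along(phenos), function(j) {
    ord <- order(-score_matrix[, j], ids)
    st <- status_matrix[ord, j]
    chars <- ifelse(excluded[ord, j], "x",
             ifelse(is.na(st), ".", as.character(st)))
    paste(chars, collapse = "")
  }, character(1))
  names(report) <- phenos

  list(results = results, report = report)
}
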