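# Per-individual variant calls and metadata; genotype resolution at
# annotated sites; rare non-silent variant selection.

#' Consequence labels counted as non-silent
#'
#' Default set of consequence labels treated as non-silent when selecting
#' variants for gene-level functional scoring.
#' @export
NONSILENT_CLASSES <- c("missense", "nonsense", "frameshift", "splice-site",
                       "in-frame indel", "stop-loss")

#' Construct a personal genome
#'
#' One participant's variant calls plus the demographic metadata the
#' prevalence prior needs. Participants lacking age, gender or ancestry are
#' rejected, mirroring the exclusion of genomes without complete metadata
#' from cohort analysis.
#'
#' @param participant_id identifier.
#' @param calls data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `allele_count` (number of alternative alleles carried, 1 or 2).
#' @param age age in years.
#' @param gender gender label.
#' @param ancestry ancestry label.
#' @return An object of class `personal_genome`.
#' @export
personal_genome <- function(participant_id, calls, age, gender, ancestry) {
  if (is.null(participant_id) || is.na(participant_id) ||
      missing(age) || is.null(age) || is.na(age) ||
      missing(gender) || is.null(gender) || is.na(gender) ||
      missing(ancestry) || is.null(ancestry) || is.na(ancestry)) {
    stopf("participant rejected: missing metadata (id/age/gender/ancestry)")
  }
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "allele_count")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols) > 0) {
    stopf("calls missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(calls) > 0) {
    if (!all(calls$allele_count %in% c(1L, 2L))) {
      stopf("allele_count must be 1 or 2")
    }
    if (any(calls$ref == calls$alt)) stopf("call with identical ref and alt allele")
    key <- allele_key(calls$chrom, calls$pos, calls$alt)
    if (anyDuplicated(key)) stopf("duplicate call for the same (chrom,pos,alt)")
  }
  rownames(calls) <- NULL
  structure(list(participant_id = participant_id, calls = calls,
                 age = age, gender = gender, ancestry = ancestry),
            class = "personal_genome")
}

#' @export
print.personal_genome <- function(x, ...) {
  cat("personal_genome", x$participant_id, "-", nrow(x$calls), "calls;",
      "age", x$age, x$gender, x$ancestry, "\n")
  invisible(x)
}

#' Read a personal genome from file
#'
#' Supported formats: VCF v4.x (only `CHROM`, `POS`, `REF`, `ALT` and the
#' first sample's `GT` are used) and a TSV dialect mirroring the VCF columns
#' (`participant_id`, `chrom`, `pos`, `ref`, `alt`, `allele_count`).
#' Multi-allelic VCF records are split into one call per alternative allele
#' carried. Coordinates are 1-based on the forward strand.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`.
#' @param metadata list with `participant_id` (optional for TSV, where the
#'   file carries it), `age`, `gender`, `ancestry`.
#' @return A [personal_genome()].
#' @export
read_genome <- function(path, format = c("vcf", "tsv"), metadata) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_checked(path,
      c("participant_id", "chrom", "pos", "ref", "alt", "allele_count"),
      coltypes = list(pos = "integer", allele_count = "integer",
                      chrom = "character"))
    pid <- metadata$participant_id
    if (is.null(pid)) pid <- if (nrow(df) > 0) df$participant_id[1] else NA
    calls <- df[c("chrom", "pos", "ref", "alt", "allele_count")]
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(gt) || ncol(gt) < 1) stopf("%s: VCF has no sample genotypes", path)
    gts <- gt[, 1]
    rows <- list()
    for (i in seq_len(nrow(fix))) {
      g <- gts[i]
      if (is.na(g)) next
      alleles <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      alleles <- alleles[!is.na(alleles)]
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      for (ai in seq_along(alts)) {
        ac <- sum(alleles == ai)
        if (ac > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
            ref = fix[i, "REF"], alt = alts[ai], allele_count = as.integer(ac),
            stringsAsFactors = FALSE)
        }
      }
    }
    calls <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), allele_count = integer(),
                 stringsAsFactors = FALSE)
    pid <- metadata$participant_id
  }
  personal_genome(pid, calls, metadata$age, metadata$gender, metadata$ancestry)
}

#' Write a personal genome to the TSV dialect
#'
#' @param genome a [personal_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_tsv <- function(genome, path) {
  df <- cbind(participant_id = genome$participant_id, genome$calls)
  write_tsv(df, path)
}

#' Count risk alleles carried at a GWAS hit
#'
#' Returns the risk-allele dose in 0..2 for one individual at one hit.
#' Absence of any call at the site is interpreted as homozygous reference
#' (the input format records variants only), so the dose is then 2 when the
#' risk allele is the reference allele (`risk_is_ref`) and 0 otherwise.
#' When a call exists, its alleles must pair up with the hit's risk/other
#' alleles; an inconsistent call yields `NA` (the "unresolvable site"
#' signal), and such doses are excluded from the evidence product rather
#' than imputed.
#'
#' @param genome a [personal_genome()].
#' @param hit one-row data.frame (or list) with `chrom`, `pos`,
#'   `risk_allele`, `other_allele`, optional `risk_is_ref`.
#' @return Integer dose in `{0,1,2}` or `NA`.
#' @export
risk_allele_dose <- function(genome, hit) {
  risk_is_ref <- isTRUE(hit$risk_is_ref)
  calls <- genome$calls
  at <- which(calls$chrom == hit$chrom & calls$pos == hit$pos)
  if (length(at) == 0) {
    return(if (risk_is_ref) 2L else 0L)
  }
  # a called site: identify which allele of the pair is the alternative
  doses <- integer(0)
  for (i in at) {
    alt <- calls$alt[i]; ref <- calls$ref[i]; ac <- calls$allele_count[i]
    if (alt == hit$risk_allele && ref == hit$other_allele) {
      doses <- c(doses, ac)
    } else if (alt == hit$other_allele && ref == hit$risk_allele) {
      doses <- c(doses, 2L - ac)
    } else {
      return(NA_integer_)
    }
  }
  if (length(doses) > 1) return(NA_integer_)  # conflicting alt calls at one site
  as.integer(doses[1])
}

#' Select rare non-silent variants in a gene
#'
#' Returns the individual's calls falling in `gene` that carry a non-silent
#' consequence label and are rare. Rarity defaults to MAF < 0.01 in every
#' population recorded in the knowledge base (`rare_in = "all"`); the
#' alternative reading, rare in at least one recorded population, is
#' available as `rare_in = "any"`. Alleles with no recorded frequency are
#' treated as rare.
#'
#' @param genome a [personal_genome()].
#' @param gene gene symbol.
#' @param kb an [annotation_kb()] supplying site-to-gene mapping,
#'   consequence labels and per-population allele frequencies.
#' @param nonsilent character vector of consequence labels counted as
#'   non-silent.
#' @param rare_in `"all"` (default) or `"any"`.
#' @param maf_cutoff rarity threshold (default 0.01).
#' @return data.frame of qualifying calls (subset of `genome$calls` with a
#'   `consequence` column appended).
#' @export
select_rare_nonsilent <- function(genome, gene, kb,
                                  nonsilent = NONSILENT_CLASSES,
                                  rare_in = c("all", "any"),
                                  maf_cutoff = 0.01) {
  rare_in <- match.arg(rare_in)
  sites <- kb$sites[kb$sites$gene == gene, , drop = FALSE]
  empty <- cbind(genome$calls[0, , drop = FALSE], consequence = character(0))
  if (nrow(sites) == 0) {
    warnf("gene %s has no annotated sites in the knowledge base", gene)
    return(empty)
  }
  calls <- genome$calls
  if (nrow(calls) == 0) return(empty)
  ck <- site_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  sk <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  idx <- match(ck, sk)
  in_gene <- !is.na(idx)
  if (!any(in_gene)) return(empty)
  calls <- calls[in_gene, , drop = FALSE]
  calls$consequence <- sites$consequence[idx[in_gene]]
  calls <- calls[calls$consequence %in% nonsilent, , drop = FALSE]
  if (nrow(calls) == 0) return(calls)
  rare <- vapply(seq_len(nrow(calls)), function(i) {
    f <- kb$freqs[kb$freqs$chrom == calls$chrom[i] &
                  kb$freqs$pos == calls$pos[i] &
                  kb$freqs$alt == calls$alt[i], "maf"]
    if (length(f) == 0) return(TRUE)  # unobserved allele: assumed rare
    if (rare_in == "all") all(f < maf_cutoff) else any(f < maf_cutoff)
  }, logical(1))
  calls[rare, , drop = FALSE]
}

#' Match high-penetrance variants carried by a genome
#'
#' Exact (chrom, pos, ref, alt) join between the individual's calls and the
#' knowledge base's high-penetrance variants for a phenotype, carrying
#' zygosity (`allele_count`) through. Any match, heterozygous or homozygous,
#' counts: high-penetrance variants are treated as dominant-acting.
#'
#' @param genome a [personal_genome()].
#' @param kb an [annotation_kb()].
#' @param phenotype phenotype identifier.
#' @return data.frame of matched variants with `allele_count`.
#' @export
match_hp_variant <- function(genome, kb, phenotype) {
  hp <- kb$hp_variants[kb$hp_variants$phenotype == phenotype, , drop = FALSE]
  out <- cbind(hp[0, , drop = FALSE], allele_count = integer(0))
  if (nrow(hp) == 0 || nrow(genome$calls) == 0) return(out)
  hk <- site_key(hp$chrom, hp$pos, hp$ref, hp$alt)
  ck <- site_key(genome$calls$chrom, genome$calls$pos,
                 genome$calls$ref, genome$calls$alt)
  idx <- match(hk, ck)
  hit <- !is.na(idx)
  if (!any(hit)) return(out)
  res <- hp[hit, , drop = FALSE]
  res$allele_count <- genome$calls$allele_count[idx[hit]]
  rownames(res) <- NULL
  res
}

#' Read a cohort phenotype-status table
#'
#' Reads `phenotypes.tsv` (`participant_id`, `phenotype`, `status` in
#' `{1,0,NA}`) into a participant-by-phenotype integer matrix; `NA` encodes
#' unknown status.
#'
#' @param path file path.
#' @return Integer matrix with participant ids as rownames and phenotypes as
#'   colnames.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path, c("participant_id", "phenotype", "status"),
                         coltypes = list(status = "integer"))
  participants <- unique(df$participant_id)
  phenos <- unique(df$phenotype)
  m <- matrix(NA_integer_, length(participants), length(phenos),
              dimnames = list(participants, phenos))
  if (nrow(df) > 0) {
    m[cbind(match(df$participant_id, participants), match(df$phenotype, phenos))] <-
      df$status
  }
  m
}

#' Write a cohort phenotype-status matrix to TSV
#'
#' @param statuses integer matrix as returned by [read_phenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(statuses, path) {
  df <- data.frame(
    participant_id = rep(rownames(statuses), times = ncol(statuses)),
    phenotype = rep(colnames(statuses), each = nrow(statuses)),
    status = as.vector(statuses), stringsAsFactors = FALSE)
  write_tsv(df, path)
}
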