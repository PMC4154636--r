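test_that("GWAS effect-size filter keeps exactly the (1, 20] window, preserving order", {
  hits <- do.call(rbind, lapply(c(20, 1.0, 0.8, 1.5, 21), function(or) {
    fixture_gwas(odds_ratio = or, rsid = sprintf("rs_%g", or))
  }))
  kept <- filter_gwas_hits(hits)
  expect_equal(kept$rsid, c("rs_20", "rs_1.5"))
  # brute-force check of both bounds on every record
  expect_equal(kept$odds_ratio, hits$odds_ratio[hits$odds_ratio > 1 &
                                                hits$odds_ratio <= 20])
  # idempotent, output subset of input
  expect_equal(filter_gwas_hits(kept)$rsid, kept$rsid)
  expect_true(all(kept$rsid %in% hits$rsid))
})

test_that("beta regression coefficients are exponentiated before filtering and flagged", {
  hits <- rbind(fixture_gwas(odds_ratio = 0.5, rsid = "beta1"),
                fixture_gwas(odds_ratio = 1.5, rsid = "or1"))
  hits$effect_is_beta <- c(TRUE, FALSE)
  kept <- filter_gwas_hits(hits)
  expect_equal(kept$rsid, c("beta1", "or1"))
  expect_equal(kept$odds_ratio[1], exp(0.5))
  expect_equal(kept$effect_converted, c(TRUE, FALSE))
})

test_that("non-positive effect sizes are rejected with the record identifier", {
  hits <- fixture_gwas(odds_ratio = -1, rsid = "rs_bad")
  expect_error(filter_gwas_hits(hits), "rs_bad")
})

test_that("gene association filter: curated kept, mined need Z>4 or top-5 rank", {
  assoc <- function(gene, z, ph = "asthma") {
    data.frame(phenotype = ph, gene = gene, penetrance_class = "LOW",
               zscore = z, stringsAsFactors = FALSE)
  }
  # mined Z=4.5 outside the top 5 is still kept (Z > 4)
  many <- do.call(rbind, c(lapply(1:11, function(i) assoc(paste0("G", i), 20 - i)),
                           list(assoc("G_45", 4.5))))
  expect_true("G_45" %in% filter_gene_associations(many)$gene)
  # mined Z=4.0 at rank 6 fails both criteria
  six <- do.call(rbind, c(lapply(1:5, function(i) assoc(paste0("T", i), 10 - i)),
                          list(assoc("T6", 4.0))))
  expect_false("T6" %in% filter_gene_associations(six)$gene)
  # enumeration of both rules over 7 records with a tie at rank 5:
  # Z = (5,3,3,3,3,3,3) keeps the Z>4 record plus the first four ties
  tied <- do.call(rbind, lapply(1:7, function(i) {
    assoc(paste0("Z", i), c(5, rep(3, 6))[i])
  }))
  expect_equal(filter_gene_associations(tied)$gene, paste0("Z", 1:5))
  # curated rows are always kept regardless of rank pressure
  cur <- rbind(many, data.frame(phenotype = "asthma", gene = "CURATED",
                                penetrance_class = "HIGH", zscore = NA_real_,
                                stringsAsFactors = FALSE))
  expect_true("CURATED" %in% filter_gene_associations(cur)$gene)
})

test_that("top-5 ranking is computed within each phenotype separately", {
  assoc <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(phenotype = c("A", "B")[1 + i %% 2], gene = paste0("G", i),
               penetrance_class = "LOW", zscore = 3 + i / 10,
               stringsAsFactors = FALSE)
  }))
  kept <- filter_gene_associations(assoc)
  expect_equal(nrow(kept), 6)  # three per phenotype, all within top 5
})

test_that("only the most confident disease-mutation class is admitted", {
  expect_true(admit_high_penetrance_variant("DM"))
  expect_false(admit_high_penetrance_variant("DM?"))
  expect_equal(sum(admit_high_penetrance_variant(c("DM", "DP", "DM"))), 2)
})

test_that("prevalence lookup falls back through age band, ancestry, then gender", {
  tab <- data.frame(
    phenotype = rep("gout", 4),
    ancestry = c("European", "European", "ALL", "ALL"),
    gender = c("M", "M", "M", "ALL"),
    age_lo = c(40, NA, NA, NA), age_hi = c(50, NA, NA, NA),
    prevalence = c(0.10, 0.08, 0.06, 0.04),
    source = "x", stringsAsFactors = FALSE)
  expect_equal(lookup_prevalence(tab, "gout", "European", "M", 45), 0.10)
  expect_equal(lookup_prevalence(tab, "gout", "European", "M", 70), 0.08)
  expect_equal(lookup_prevalence(tab, "gout", "Asian", "M", 45), 0.06)
  expect_equal(lookup_prevalence(tab, "gout", "Asian", "F", 45), 0.04)
  expect_true(is.na(lookup_prevalence(tab, "dandruff", "European", "M", 45)))
  # deterministic and in (0,1)
  p1 <- lookup_prevalence(tab, "gout", "European", "M", 45)
  expect_identical(p1, lookup_prevalence(tab, "gout", "European", "M", 45))
  expect_true(p1 > 0 && p1 < 1)
})

test_that("hp-variant host genes are auto-added as HIGH associations", {
  kb <- annotation_kb(
    hp_variants = data.frame(phenotype = "x", chrom = "1", pos = 1L,
                             ref = "C", alt = "T", gene = "NEW", class = "DM",
                             stringsAsFactors = FALSE))
  hit <- kb$genes[kb$genes$gene == "NEW", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$penetrance_class, "HIGH")
})

test_that("knowledge base round-trips through its TSV dialect", {
  kb <- fixture_kb()
  dir <- withr::local_tempdir()
  write_kb(kb, dir)
  kb2 <- load_kb(dir, apply_filters = FALSE)
  for (part in c("hp_variants", "genes", "sites", "freqs", "prevalence")) {
    expect_equal(kb2[[part]], kb[[part]], ignore_attr = TRUE)
  }
  expect_equal(kb2$gwas[names(kb$gwas) != "effect_converted"],
               kb$gwas[names(kb$gwas) != "effect_converted"],
               ignore_attr = TRUE)
  # loading twice yields equal KBs
  expect_equal(load_kb(dir, apply_filters = FALSE), kb2)
})

test_that("loading an empty directory yields an empty KB without error", {
  dir <- withr::local_tempdir()
  kb <- load_kb(dir)
  expect_s3_class(kb, "annotation_kb")
  expect_equal(nrow(kb$gwas), 0)
  expect_equal(nrow(kb$prevalence), 0)
})

test_that("admission filters are applied on load", {
  kb <- fixture_kb()
  kb$gwas <- rbind(kb$gwas,
                   fixture_gwas(rsid = "rs_or25", pos = 101L, odds_ratio = 25),
                   fixture_gwas(rsid = "rs_ok", pos = 102L, odds_ratio = 3))
  kb$hp_variants <- rbind(kb$hp_variants, data.frame(
    phenotype = "asthma", chrom = "1", pos = 501L, ref = "C", alt = "T",
    gene = "GENE_H", class = "DM?", stringsAsFactors = FALSE))
  dir <- withr::local_tempdir()
  write_kb(kb, dir)
  loaded <- load_kb(dir, apply_filters = TRUE)
  expect_equal(nrow(loaded$gwas), 2)  # rs_or25 dropped
  expect_false("rs_or25" %in% loaded$gwas$rsid)
  expect_equal(nrow(loaded$hp_variants), 1)  # DM? dropped
})

test_that("malformed rows are rejected naming file, line and column", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "kb_gwas.tsv")
  writeLines(c("phenotype\trsid\tchrom\tpos\trisk_allele\tother_allele\todds_ratio\trisk_allele_freq",
               "asthma\trs1\t1\tnot_a_number\tA\tG\t2\t0.3"), path)
  expect_error(load_kb(dir), "kb_gwas.tsv.*line 2.*pos")
})
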