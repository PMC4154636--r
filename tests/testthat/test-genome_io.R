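test_that("VCF genomes load with correct allele counts and multi-allelic splitting", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(path, c(
    "1\t100\t.\tG\tA\t.\tPASS\t.\tGT\t0/1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1",
    "1\t300\t.\tG\tA,T\t.\tPASS\t.\tGT\t1/2",
    "1\t400\t.\tG\tA\t.\tPASS\t.\tGT\t0/0"))
  g <- read_genome(path, "vcf",
                   metadata = list(participant_id = "P1", age = 40,
                                   gender = "F", ancestry = "European"))
  expect_equal(nrow(g$calls), 4)  # hom-ref record contributes no call
  expect_equal(g$calls$allele_count[g$calls$pos == 100], 1L)
  expect_equal(g$calls$allele_count[g$calls$pos == 200], 2L)
  split_alts <- g$calls[g$calls$pos == 300, ]
  expect_setequal(split_alts$alt, c("A", "T"))
  expect_equal(split_alts$allele_count, c(1L, 1L))
  # reading the same file twice yields equal genomes
  g2 <- read_genome(path, "vcf",
                    metadata = list(participant_id = "P1", age = 40,
                                    gender = "F", ancestry = "European"))
  expect_equal(g, g2)
})

test_that("the TSV dialect round-trips a genome", {
  g <- fixture_genome(rbind(call_row(pos = 100, ref = "G", alt = "A"),
                            call_row(pos = 200, ref = "C", alt = "T",
                                     allele_count = 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genome_tsv(g, path)
  g2 <- read_genome(path, "tsv",
                    metadata = list(age = 40, gender = "F",
                                    ancestry = "European"))
  expect_equal(g2$calls, g$calls)
  expect_equal(g2$participant_id, "P1")
})

test_that("participants with missing metadata are rejected", {
  expect_error(personal_genome("P1", NULL[0],
                               age = NA, gender = "F", ancestry = "European"),
               "metadata")
  expect_error(fixture_genome(gender = NA), "metadata")
})

test_that("risk allele dose covers all risk-orientation by call-state cases", {
  hit_alt <- fixture_gwas()                      # risk allele is the alternative
  hit_ref <- fixture_gwas(risk_allele = "G", other_allele = "A",
                          risk_is_ref = TRUE)    # risk allele is the reference
  het <- fixture_genome(call_row(pos = 100, ref = "G", alt = "A"))
  hom <- fixture_genome(call_row(pos = 100, ref = "G", alt = "A",
                                 allele_count = 2))
  none <- fixture_genome()
  # enumerate (risk in {alt, ref}) x (call in {none, het, hom})
  expect_equal(risk_allele_dose(het, hit_alt), 1L)
  expect_equal(risk_allele_dose(hom, hit_alt), 2L)
  expect_equal(risk_allele_dose(none, hit_alt), 0L)
  expect_equal(risk_allele_dose(het, hit_ref), 1L)
  expect_equal(risk_allele_dose(hom, hit_ref), 0L)
  expect_equal(risk_allele_dose(none, hit_ref), 2L)
  # inconsistent alleles at the site give the unresolvable signal
  odd <- fixture_genome(call_row(pos = 100, ref = "G", alt = "C"))
  expect_true(is.na(risk_allele_dose(odd, hit_alt)))
  # dose never leaves {0,1,2,NA}
  for (g in list(het, hom, none, odd)) {
    for (h in list(hit_alt, hit_ref)) {
      expect_true(risk_allele_dose(g, h) %in% c(0L, 1L, 2L, NA_integer_))
    }
  }
})

test_that("rare non-silent selection filters consequence and population MAF", {
  kb <- fixture_kb()
  g <- fixture_genome(rbind(
    call_row(pos = 1000, ref = "G", alt = "A"),   # missense, MAF 0.005
    call_row(pos = 1001, ref = "G", alt = "A"),   # synonymous
    call_row(pos = 1002, ref = "G", alt = "A"),   # 0.005 EUR but 0.02 AFR
    call_row(pos = 999, ref = "G", alt = "A")))   # not an annotated site
  sel <- select_rare_nonsilent(g, "GENE_H", kb)
  expect_equal(sel$pos, 1000L)
  # "rare in any recorded population" reading keeps the split-MAF variant
  sel_any <- select_rare_nonsilent(g, "GENE_H", kb, rare_in = "any")
  expect_setequal(sel_any$pos, c(1000L, 1002L))
  # unrecorded frequency counts as rare
  g2 <- fixture_genome(call_row(pos = 2001, ref = "G", alt = "A"))
  expect_equal(select_rare_nonsilent(g2, "GENE_L", kb)$pos, 2001L)
  # output is a subset of the genome's calls in the gene
  expect_true(all(sel$pos %in% g$calls$pos))
  # unknown gene warns and returns an empty set
  expect_warning(out <- select_rare_nonsilent(g, "NOT_A_GENE", kb), "NOT_A_GENE")
  expect_equal(nrow(out), 0)
})

test_that("high-penetrance variant matching joins on exact coordinates and alleles", {
  kb <- fixture_kb()
  kb$hp_variants <- rbind(kb$hp_variants, data.frame(
    phenotype = "asthma", chrom = "1", pos = c(501L, 502L), ref = "C",
    alt = "T", gene = "GENE_H", class = "DM", stringsAsFactors = FALSE))
  g <- fixture_genome(rbind(call_row(pos = 500, ref = "C", alt = "T"),
                            call_row(pos = 502, ref = "C", alt = "T",
                                     allele_count = 2)))
  m <- match_hp_variant(g, kb, "asthma")
  expect_equal(nrow(m), 2)  # 3 KB variants, genome carries 2
  expect_equal(m$allele_count[m$pos == 500], 1L)
  expect_equal(m$allele_count[m$pos == 502], 2L)
  # same position but a different alternative allele does not match
  g2 <- fixture_genome(call_row(pos = 500, ref = "C", alt = "G"))
  expect_equal(nrow(match_hp_variant(g2, kb, "asthma")), 0)
})

test_that("phenotype status tables round-trip", {
  m <- matrix(c(1L, 0L, NA, 1L), 2, 2,
              dimnames = list(c("P1", "P2"), c("ph1", "ph2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(m, path)
  expect_equal(read_phenotypes(path), m)
})
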