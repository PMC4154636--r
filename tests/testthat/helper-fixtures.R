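# Small in-code fixtures shared across test files.

fixture_gwas <- function(...) {
  defaults <- data.frame(
    phenotype = "asthma", rsid = "rs1", chrom = "1", pos = 100L,
    risk_allele = "A", other_allele = "G", odds_ratio = 2,
    risk_allele_freq = 0.3, risk_is_ref = FALSE, stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  defaults
}

# A minimal KB: one phenotype with one GWAS hit, one DM variant in GENE_H,
# one HIGH gene (the host) and one LOW gene with two rare missense sites.
fixture_kb <- function() {
  annotation_kb(
    gwas = fixture_gwas(),
    hp_variants = data.frame(
      phenotype = "asthma", chrom = "1", pos = 500L, ref = "C", alt = "T",
      gene = "GENE_H", class = "DM", stringsAsFactors = FALSE),
    genes = data.frame(
      phenotype = "asthma", gene = c("GENE_H", "GENE_L"),
      penetrance_class = c("HIGH", "LOW"), zscore = c(NA, 6),
      stringsAsFactors = FALSE),
    sites = data.frame(
      chrom = "1", pos = c(1000L, 1001L, 1002L, 2000L, 2001L),
      ref = "G", alt = "A",
      gene = c("GENE_H", "GENE_H", "GENE_H", "GENE_L", "GENE_L"),
      consequence = c("missense", "synonymous", "missense",
                      "missense", "missense"),
      stringsAsFactors = FALSE),
    freqs = data.frame(
      chrom = "1", pos = c(1000L, 1002L, 1002L, 2000L),
      alt = "A", population = c("EUR", "EUR", "AFR", "EUR"),
      maf = c(0.005, 0.005, 0.02, 0.001), stringsAsFactors = FALSE),
    prevalence = data.frame(
      phenotype = "asthma", ancestry = "ALL", gender = "ALL",
      age_lo = NA_real_, age_hi = NA_real_, prevalence = 0.08,
      source = "fixture", stringsAsFactors = FALSE))
}

fixture_genome <- function(calls = NULL, id = "P1", age = 40,
                           gender = "F", ancestry = "European") {
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        allele_count = integer(), stringsAsFactors = FALSE)
  }
  personal_genome(id, calls, age, gender, ancestry)
}

call_row <- function(chrom = "1", pos, ref, alt, allele_count = 1L) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             allele_count = as.integer(allele_count), stringsAsFactors = FALSE)
}

fixture_scores <- function() {
  data.frame(chrom = "1", pos = c(1000L, 1002L, 2000L, 2001L),
             ref = "G", alt = "A",
             p_value = c(0.05, 0.1, 0.001, 0.9), stringsAsFactors = FALSE)
}

write_fixture_vcf <- function(path, records,
                              header_sample = "S1") {
  lines <- c("##fileformat=VCFv4.2",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    header_sample),
             records)
  writeLines(lines, path)
  path
}
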