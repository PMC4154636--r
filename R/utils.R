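# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Composite site keys used for joins between genomes and the knowledge base.
# Coordinates are 1-based throughout; keys are plain strings so that
# data.frame joins stay fast and deterministic.
site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

pos_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

allele_key <- function(chrom, pos, alt) paste(chrom, pos, alt, sep = ":")

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

# Read a TSV with a mandatory header; a missing or empty file yields a
# zero-row data.frame with the expected columns.
read_tsv_checked <- function(path, required, coltypes = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(required)), required),
                        stringsAsFactors = FALSE)
    return(df)
  }
  # read everything as character first: nucleotide alleles like "T" must
  # never be auto-coerced to logicals
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stopf("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  }
  if (!is.null(coltypes)) {
    for (col in names(coltypes)) {
      if (!col %in% names(df) || coltypes[[col]] == "character") next
      conv <- suppressWarnings(switch(coltypes[[col]],
        numeric = as.numeric(df[[col]]),
        integer = as.integer(df[[col]]),
        logical = as.logical(df[[col]])))
      bad <- which(is.na(conv) & !is.na(df[[col]]))
      if (length(bad) > 0) {
        stopf("%s: line %d, column '%s': cannot parse value '%s'",
              path, bad[1] + 1L, col, df[[col]][bad[1]])
      }
      df[[col]] <- conv
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
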