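# File-format plumbing: FASTQ/FASTA read sets (gzip auto-detected by magic
# bytes, not extension), TSV tables, and YAML flavor catalogs.

is_gzipped <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Read sequences from a FASTQ or FASTA file
#'
#' Format is sniffed from the first record character, gzip compression from
#' the file's magic bytes (the extension is ignored). Paired files are simply
#' concatenated: the features used downstream are orientation-free.
#'
#' @param path primary read file (FASTQ or FASTA, optionally gzipped).
#' @param path2 optional mate file.
#' @return character vector of read sequences.
#' @export
read_reads <- function(path, path2 = NULL) {
  read_one <- function(p) {
    if (!file.exists(p)) stopf("read file not found: %s", p)
    if (is_gzipped(p) && !grepl("\\.gz$", p)) {
      # ShortRead/Biostrings key decompression off the extension
      tmp <- paste0(tempfile(), ".fastq.gz")
      file.copy(p, tmp)
      on.exit(unlink(tmp), add = TRUE)
      p <- tmp
    }
    con <- if (grepl("\\.gz$", p)) gzfile(p, "rt") else file(p, "rt")
    first <- readLines(con, n = 1L)
    close(con)
    if (!length(first)) stopf("empty read file: %s", path)
    if (startsWith(first, "@")) {
      if (!requireNamespace("ShortRead", quietly = TRUE))
        stopf("reading FASTQ requires the ShortRead package")
      as.character(ShortRead::sread(ShortRead::readFastq(p)))
    } else if (startsWith(first, ">")) {
      if (!requireNamespace("Biostrings", quietly = TRUE))
        stopf("reading FASTA requires the Biostrings package")
      as.character(Biostrings::readDNAStringSet(p))
    } else stopf("%s: neither FASTQ nor FASTA (first character '%s')", path, substr(first, 1, 1))
  }
  reads <- read_one(path)
  if (!is.null(path2)) reads <- c(reads, read_one(path2))
  unname(reads)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a species-by-sample abundance table
#'
#' TSV with species ids in the first column and one column per sample.
#' @param path file path.
#' @return numeric matrix, rows = species, columns = samples.
#' @export
read_abundance_table <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stopf("abundance table contains negative values")
  m
}

#' @rdname read_abundance_table
#' @param table numeric species-by-sample matrix.
#' @export
write_abundance_table <- function(table, path) {
  write_tsv(cbind(data.frame(species = rownames(table)), as.data.frame(table)), path)
}

#' Read sample metadata (sample_id, country, region, optional coverage)
#'
#' @param path TSV path with a header naming at least `sample_id`, `country`
#'   and `region`; `nonpareil_coverage_pct` is optional.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "country", "region")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  df
}

#' Write a FASTQ file
#'
#' @param readset data.frame with columns `id`, `sequence`, `quality`
#'   (e.g. from [simulate_readset()]).
#' @param path output path; written gzip-compressed if it ends in `.gz` or
#'   `gzip = TRUE`.
#' @param gzip force gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(readset, path, gzip = grepl("\\.gz$", path)) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(readset)))
  lines <- as.vector(rbind(paste0("@", readset$id), readset$sequence,
                           "+", readset$quality))
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
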