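# Read-set and k-mer-spectrum feature extraction. The spectrum of a read set
# maps each occurrence frequency f to c_f, the number of distinct canonical
# k-mers seen exactly f times; all model features derive from it.

#' Per-read-set summary statistics
#'
#' Tallies the read-level candidate features used by the peak-RAM model:
#' number of reads, total bases, GC fraction, minimum and average read
#' length. GC is computed as (#G + #C) / (#A + #C + #G + #T) over all reads;
#' ambiguous symbols (N etc.) are excluded from both numerator and
#' denominator but still count toward read lengths.
#'
#' @param reads character vector of read sequences (case-insensitive).
#' @return A `read_set_stats` list with fields `n_reads`, `total_bases`,
#'   `gc_fraction`, `min_read_length`, `avg_read_length`.
#' @examples
#' compute_read_stats(c("ACGT", "AAAA"))
#' @export
compute_read_stats <- function(reads) {
  reads <- as.character(reads)
  if (length(reads) == 0L) stopf("empty read set: at least one read is required")
  t <- read_base_tallies_cpp(reads)
  acgt <- sum(t$acgt)
  if (acgt == 0) stopf("GC content undefined: reads contain no A/C/G/T bases")
  structure(list(
    n_reads = length(reads),
    total_bases = sum(t$length),
    gc_fraction = sum(t$gc) / acgt,
    min_read_length = min(t$length),
    avg_read_length = mean(t$length)
  ), class = "read_set_stats")
}

#' Construct a k-mer spectrum
#'
#' @param k k-mer size (>= 1).
#' @param histogram named numeric vector: names are occurrence frequencies
#'   `f >= 1`, values are the counts `c_f > 0` of distinct canonical k-mers
#'   observed exactly `f` times. Zero-valued entries are dropped.
#' @return A `kmer_spectrum` object.
#' @export
kmer_spectrum <- function(k, histogram = numeric()) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stopf("k must be an integer >= 1")
  if (length(histogram)) {
    f <- suppressWarnings(as.numeric(names(histogram)))
    if (anyNA(f) || any(f < 1) || any(f != round(f)))
      stopf("histogram names must be integer frequencies >= 1")
    if (any(histogram < 0) || any(histogram != round(histogram)))
      stopf("histogram counts must be non-negative integers")
    keep <- histogram > 0
    histogram <- histogram[keep][order(f[keep])]
  }
  structure(list(k = k, histogram = as.numeric(histogram) |>
                   stats::setNames(names(histogram))),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("k-mer spectrum (k = %d): %d occupied bins, %s distinct / %s total k-mers\n",
              x$k, length(x$histogram),
              format(sum(x$histogram), big.mark = ","),
              format(sum(as.numeric(names(x$histogram)) * x$histogram), big.mark = ",")))
  invisible(x)
}

#' Count canonical k-mers of a read set
#'
#' Counts each k-window by its canonical form (the lexicographically smaller
#' of the k-mer and its reverse complement), so counting is strand
#' independent. Windows containing a non-ACGT symbol are skipped, matching
#' common k-mer-counter behaviour; reads shorter than `k` contribute nothing.
#'
#' @param reads character vector of read sequences.
#' @param k k-mer size (>= 1).
#' @return A [kmer_spectrum()]; empty if no read reaches length `k`.
#' @examples
#' count_canonical_kmers("ACGTT", 4)  # canonical forms ACGT and AACG
#' @export
count_canonical_kmers <- function(reads, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stopf("k must be an integer >= 1")
  res <- count_canonical_kmers_cpp(as.character(reads), k)
  kmer_spectrum(k, stats::setNames(res$count, format(res$frequency, scientific = FALSE, trim = TRUE)))
}

#' Summary statistics of a k-mer spectrum
#'
#' Let `v_f = f * c_f` be the total number of k-mers in occupied bin `f`.
#' Reports the total and distinct k-mer counts, the mean, population SD and
#' maximum of `v_f` over occupied bins, and two 5% tail masses: `q5_sum` is
#' the sum of `v_f` over the largest low-frequency prefix of bins whose
#' cumulative mass stays within 5% of the total (it tracks the number of
#' rare k-mers, mostly sequencing errors and low-coverage community
#' members), and `q95_sum` is the analogous high-frequency suffix.
#'
#' @param spectrum a [kmer_spectrum()] with at least one occupied bin.
#' @return A `spectrum_stats` list with fields `total_kmers`,
#'   `distinct_kmers`, `mean_total_per_freq`, `sd_total_per_freq`,
#'   `max_total_per_freq`, `q5_sum`, `q95_sum`.
#' @export
spectrum_statistics <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  h <- spectrum$histogram
  if (length(h) == 0L)
    stopf("empty k-mer spectrum (all reads shorter than k = %d?)", spectrum$k)
  f <- as.numeric(names(h))
  v <- f * h
  total <- sum(v)
  cap <- 0.05 * total
  asc <- cumsum(v)              # bins already sorted by ascending frequency
  desc <- cumsum(rev(v))
  structure(list(
    total_kmers = total,
    distinct_kmers = sum(h),
    mean_total_per_freq = mean(v),
    sd_total_per_freq = sqrt(mean((v - mean(v))^2)),
    max_total_per_freq = max(v),
    q5_sum = sum(v[asc <= cap]),
    q95_sum = sum(rev(v)[desc <= cap])
  ), class = "spectrum_stats")
}

#' Read a two-column k-mer histogram file
#'
#' Parses the whitespace-separated `frequency count` text dialect emitted by
#' `kmc_tools transform ... histogram`. Zero-count lines are dropped.
#'
#' @param path path to the histogram text file.
#' @param k the k-mer size the histogram was computed with (not recorded in
#'   the file format, so the caller must state it).
#' @return A [kmer_spectrum()].
#' @export
read_kmc_histogram <- function(path, k) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  freq <- numeric(length(lines)); cnt <- numeric(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(fields) != 2L)
      stopf("line %d: expected two whitespace-separated fields, got %d", i, length(fields))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals) || any(vals != round(vals)) || any(vals < 0))
      stopf("line %d: fields must be non-negative integers ('%s')", i, lines[[i]])
    freq[i] <- vals[1]; cnt[i] <- vals[2]
  }
  keep <- cnt > 0
  kmer_spectrum(k, stats::setNames(cnt[keep],
    format(freq[keep], scientific = FALSE, trim = TRUE)))
}

#' Write a spectrum in the two-column histogram dialect
#'
#' @param spectrum a [kmer_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmc_histogram <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  writeLines(paste(names(spectrum$histogram),
                   format(spectrum$histogram, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}

#' Candidate feature names for a set of k-mer sizes
#'
#' @param ks integer vector of k-mer sizes (default the 13/21/71 trio).
#' @return character vector in the stable column order used throughout.
#' @export
feature_names <- function(ks = c(13L, 21L, 71L)) {
  per_k <- c("total_kmers", "distinct_kmers", "mean", "sd", "max", "q5", "q95")
  c("gc_content", "total_reads", "min_read_length", "avg_read_length", "total_bases",
    as.vector(t(outer(per_k, ks, function(s, k) sprintf("%s_%d", s, k)))),
    "nonpareil_diversity")
}

#' Assemble the candidate feature vector of one dataset
#'
#' Combines read-level statistics with per-k spectrum statistics into the
#' named feature vector consumed by the model pipeline. A missing diversity
#' index is recorded as `NA` (missing), never as zero.
#'
#' @param stats a [compute_read_stats()] result.
#' @param spectra named list of [spectrum_statistics()] results; names are
#'   the k-mer sizes, e.g. `list("13" = ..., "21" = ..., "71" = ...)`.
#' @param diversity optional externally computed sequence-diversity index
#'   (e.g. Nonpareil's); `NULL` if unavailable.
#' @param ks k-mer sizes that must be present (default `c(13, 21, 71)`).
#' @param dataset_id identifier for the dataset.
#' @return A `feature_vector`: list with `dataset_id` and named numeric
#'   `values` in [feature_names()] order.
#' @export
assemble_feature_vector <- function(stats, spectra, diversity = NULL,
                                    ks = c(13L, 21L, 71L), dataset_id = "dataset") {
  stopifnot(inherits(stats, "read_set_stats"))
  ks <- as.integer(ks)
  if (anyDuplicated(ks)) stopf("duplicate k in configuration: %s",
                               paste(ks[duplicated(ks)], collapse = ", "))
  have <- suppressWarnings(as.integer(names(spectra)))
  missing_k <- setdiff(ks, have)
  if (length(missing_k))
    stopf("no spectrum statistics provided for k = %s", paste(missing_k, collapse = ", "))
  vals <- c(gc_content = stats$gc_fraction,
            total_reads = stats$n_reads,
            min_read_length = stats$min_read_length,
            avg_read_length = stats$avg_read_length,
            total_bases = stats$total_bases)
  for (k in ks) {
    s <- spectra[[as.character(k)]]
    stopifnot(inherits(s, "spectrum_stats"))
    vals[sprintf(c("total_kmers_%d", "distinct_kmers_%d", "mean_%d",
                   "sd_%d", "max_%d", "q5_%d", "q95_%d"), k)] <-
      c(s$total_kmers, s$distinct_kmers, s$mean_total_per_freq,
        s$sd_total_per_freq, s$max_total_per_freq, s$q5_sum, s$q95_sum)
  }
  vals["nonpareil_diversity"] <- if (is.null(diversity)) NA_real_ else as.numeric(diversity)
  if (any(vals[setdiff(names(vals), c("gc_content", "nonpareil_diversity"))] < 0, na.rm = TRUE))
    stopf("negative counts in feature vector")
  structure(list(dataset_id = dataset_id, values = vals[feature_names(ks)]),
            class = "feature_vector")
}

#' Extract all candidate features from a read set in one call
#'
#' Convenience composition of [compute_read_stats()],
#' [count_canonical_kmers()], [spectrum_statistics()] and
#' [assemble_feature_vector()].
#'
#' @inheritParams assemble_feature_vector
#' @param reads character vector of read sequences.
#' @return A `feature_vector`.
#' @export
extract_features <- function(reads, ks = c(13L, 21L, 71L), diversity = NULL,
                             dataset_id = "dataset") {
  stats <- compute_read_stats(reads)
  spectra <- lapply(ks, function(k) spectrum_statistics(count_canonical_kmers(reads, k)))
  names(spectra) <- as.character(as.integer(ks))
  assemble_feature_vector(stats, spectra, diversity = diversity, ks = ks,
                          dataset_id = dataset_id)
}

#' Bind feature vectors into a one-row-per-dataset table
#'
#' @param fvs list of `feature_vector` objects.
#' @return data.frame with `dataset_id` and one column per feature.
#' @export
feature_table <- function(fvs) {
  if (inherits(fvs, "feature_vector")) fvs <- list(fvs)
  stopifnot(all(vapply(fvs, inherits, TRUE, "feature_vector")))
  df <- as.data.frame(do.call(rbind, lapply(fvs, function(f) f$values)))
  cbind(dataset_id = vapply(fvs, function(f) f$dataset_id, ""), df,
        stringsAsFactors = FALSE)
}
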