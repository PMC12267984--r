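# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: brute-force window extraction with Biostrings
# canonicalization for spectra, textbook formulas for Pearson screening, a
# re-coded bootstrap, and interpolated quantiles by the closed-form type-7
# rule.

# brute-force canonical k-mer spectrum: enumerate every window, drop windows
# with non-ACGT symbols, canonicalize via Biostrings, tabulate twice
oracle_spectrum <- function(reads, k) {
  kmers <- unlist(lapply(toupper(reads), function(r) {
    n <- nchar(r)
    if (n < k) return(character())
    subs <- substring(r, 1:(n - k + 1), k:n)
    subs[grepl("^[ACGT]+$", subs)]
  }))
  if (!length(kmers)) return(stats::setNames(numeric(), character()))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(rc < kmers, rc, kmers)
  tt <- table(table(canon))
  stats::setNames(as.numeric(tt), names(tt))
}

# direct-arithmetic spectrum statistics from a named frequency histogram
oracle_spectrum_stats <- function(hist) {
  f <- as.numeric(names(hist))
  o <- order(f)
  f <- f[o]; c_f <- as.numeric(hist[o])
  v <- f * c_f
  total <- sum(v)
  q5 <- 0; acc <- 0
  for (i in seq_along(v)) { acc <- acc + v[i]; if (acc > 0.05 * total) break; q5 <- acc }
  q95 <- 0; acc <- 0
  for (i in rev(seq_along(v))) { acc <- acc + v[i]; if (acc > 0.05 * total) break; q95 <- acc }
  list(total_kmers = total, distinct_kmers = sum(c_f), mean_total_per_freq = mean(v),
       sd_total_per_freq = sqrt(sum((v - mean(v))^2) / length(v)),
       max_total_per_freq = max(v), q5_sum = q5, q95_sum = q95)
}

# textbook Pearson r and two-sided P-value via the t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# type-7 quartile by the closed-form interpolation rule
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h) + 1
  x[lo] + (h - floor(h)) * (x[min(lo + 1, length(x))] - x[lo])
}

# random read set with occasional ambiguous bases, for oracle-equivalence runs
random_readset <- function(n_reads, max_len, seed, n_frac = 0.02) {
  withr::with_seed(seed, {
    vapply(seq_len(n_reads), function(i) {
      len <- sample(10:max_len, 1)
      paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                   prob = c(rep((1 - n_frac) / 4, 4), n_frac)), collapse = "")
    }, "")
  })
}

# small training table with a planted nonlinear response (trees should beat a
# straight line here)
nonlinear_table <- function(n = 120, seed = 1, noise_sd = 0.5) {
  withr::with_seed(seed, {
    x1 <- runif(n, 0, 10); x2 <- runif(n, 0, 10); x3 <- runif(n, 0, 10)
    y <- 5 + 3 * sin(x1) + (x2 > 5) * 8 + 0.5 * x1 * (x2 < 3) + rnorm(n, 0, noise_sd)
    training_table(data.frame(dataset_id = sprintf("d%03d", 1:n),
                              x1 = x1, x2 = x2, x3 = x3,
                              observed_peak_ram_gb = y + 20), "default")
  })
}
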