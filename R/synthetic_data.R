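# Seeded synthetic-data generators. These state a small, explicit world --
# community genomes, shotgun reads with substitution errors, a training
# corpus whose peak-RAM response is linear in the distinct 21- and 71-mer
# counts, and abundance tables with planted global/regional core species --
# so that every pipeline stage can be exercised and recovered against a
# known truth without any external download. All generators are pure
# functions of their seed and arguments.

revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), ""),
         function(s) paste(rev(s), collapse = ""), "")
}

#' Simulate random genomes
#'
#' I.i.d. bases with `P(G) + P(C) = gc`, split evenly within each pair.
#'
#' @param n number of genomes (>= 1).
#' @param length genome length in bp.
#' @param gc GC content in `[0, 1]` (default 0.5).
#' @param seed RNG seed.
#' @return character vector of genome sequences.
#' @export
simulate_genomes <- function(n, length, gc = 0.5, seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  if (length < 1) stopf("length must be >= 1")
  if (gc < 0 || gc > 1) stopf("gc must lie in [0, 1]")
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(names(prob), length, replace = TRUE, prob = prob), collapse = ""), ""))
}

#' Community specification for read simulation
#'
#' @param n_genomes number of community members.
#' @param genome_length genome length in bp (>= `read_length`).
#' @param gc GC content of the genomes.
#' @param abundance either an explicit weight vector of length `n_genomes`
#'   or `NULL` to draw lognormal weights with `lognormal_sigma`.
#' @param lognormal_sigma sigma of the lognormal abundance model (default 1,
#'   a common skew for microbial communities).
#' @param read_length read length in bp.
#' @param n_reads number of reads to draw.
#' @param error_rate per-base substitution probability (default 0.1%,
#'   Illumina-like; no indels).
#' @param seed RNG seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_genomes = 5L, genome_length = 20000L, gc = 0.5,
                           abundance = NULL, lognormal_sigma = 1,
                           read_length = 150L, n_reads = 2000L,
                           error_rate = 0.001, seed = 1L) {
  if (error_rate < 0 || error_rate > 1) stopf("error_rate must lie in [0, 1]")
  if (genome_length < read_length) stopf("genome_length must be >= read_length")
  if (!is.null(abundance) && length(abundance) != n_genomes)
    stopf("abundance weights must have length n_genomes")
  structure(list(n_genomes = as.integer(n_genomes), genome_length = as.integer(genome_length),
                 gc = gc, abundance = abundance, lognormal_sigma = lognormal_sigma,
                 read_length = as.integer(read_length), n_reads = as.integer(n_reads),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_spec")
}

#' Simulate a shotgun read set from community genomes
#'
#' Reads are drawn from genomes proportionally to the abundance weights,
#' start positions uniform, strand 50/50, with per-base substitutions at
#' `spec$error_rate` and a constant quality string (downstream features
#' never read qualities).
#'
#' @param genomes character vector of genome sequences (e.g. from
#'   [simulate_genomes()]).
#' @param spec a [community_spec()]; `spec$n_genomes` must match.
#' @return data.frame with columns `id`, `sequence`, `quality`, `genome`
#'   (source genome index).
#' @export
simulate_readset <- function(genomes, spec) {
  stopifnot(inherits(spec, "community_spec"))
  if (length(genomes) != spec$n_genomes)
    stopf("expected %d genomes, got %d", spec$n_genomes, length(genomes))
  if (any(nchar(genomes) < spec$read_length))
    stopf("read_length (%d) exceeds the shortest genome (%d bp)",
          spec$read_length, min(nchar(genomes)))
  rl <- spec$read_length
  with_seed(spec$seed, {
    w <- spec$abundance %||% rlnorm(spec$n_genomes, 0, spec$lognormal_sigma)
    src <- sample.int(spec$n_genomes, spec$n_reads, replace = TRUE, prob = w / sum(w))
    starts <- floor(runif(spec$n_reads) * (nchar(genomes)[src] - rl + 1)) + 1
    seqs <- substr(genomes[src], starts, starts + rl - 1L)
    rev <- runif(spec$n_reads) < 0.5
    seqs[rev] <- revcomp(seqs[rev])
    n_err <- rbinom(spec$n_reads, rl, spec$error_rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(n_err > 0)) {
      pos <- sample.int(rl, n_err[i])
      chars <- strsplit(seqs[i], "")[[1]]
      for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
      seqs[i] <- paste(chars, collapse = "")
    }
    data.frame(id = sprintf("read_%06d", seq_len(spec$n_reads)),
               sequence = seqs, quality = strrep("I", rl), genome = src,
               stringsAsFactors = FALSE)
  })
}

# Default planted response: peak RAM (GB) linear in the distinct 21- and
# 71-mer counts. Coefficients are chosen so that datasets of a few Gbp with
# 1e8..5e9 distinct k-mers land in the 10..130 GB range a short-read
# metagenome assembler actually occupies.
default_ram_response <- function(mode = "default", via_reads = FALSE) {
  scale <- if (identical(mode, "meta-sensitive")) 1.4 else 1.0
  if (via_reads)
    list(intercept = 4, distinct_kmers_21 = 2e-4 * scale, distinct_kmers_71 = 1.5e-4 * scale)
  else
    list(intercept = 4, distinct_kmers_21 = 12e-9 * scale, distinct_kmers_71 = 9e-9 * scale)
}

#' Synthetic peak-RAM training table with planted response
#'
#' Emulates a training corpus of shotgun metagenomes of varying depth and
#' community complexity. Features are drawn from declared distributions
#' (default) or measured from simulated read sets (`via_reads = TRUE`, much
#' slower, desk scale only). The response is
#' `intercept + b21 * distinct_kmers_21 + b71 * distinct_kmers_71 +
#' N(0, noise_sd)`, the two planted predictors being the features a
#' de Bruijn graph assembler's memory actually scales with.
#'
#' @param n_datasets number of rows (default 300).
#' @param noise_sd Gaussian response noise in GB (default 2).
#' @param coef named list of response coefficients; default
#'   [default_ram_response()].
#' @param mode assembler setting label; "meta-sensitive" scales the
#'   coefficients by 1.4 (wider k-mer range, higher RAM).
#' @param via_reads measure features from simulated read sets instead of
#'   sampling them.
#' @param seed RNG seed.
#' @return list with `table` (a [training_table()]) and `truth` (response id,
#'   coefficients, noise SD, planted feature names).
#' @export
synth_training_table <- function(n_datasets = 300L, noise_sd = 2,
                                 coef = NULL, mode = "default",
                                 via_reads = FALSE, seed = 1L) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  coef <- coef %||% default_ram_response(mode, via_reads)
  n <- as.integer(n_datasets)
  df <- if (via_reads) {
    rows <- with_seed(seed, lapply(seq_len(n), function(i) {
      ngen <- sample(1:12, 1)
      list(ngen = ngen, seed = sample.int(1e6, 1))
    }))
    fvs <- lapply(seq_len(n), function(i) {
      sp <- community_spec(n_genomes = rows[[i]]$ngen, genome_length = 4000L,
                           n_reads = 400L, read_length = 100L,
                           seed = rows[[i]]$seed)
      genomes <- simulate_genomes(sp$n_genomes, sp$genome_length, seed = rows[[i]]$seed + 1L)
      extract_features(simulate_readset(genomes, sp)$sequence,
                       dataset_id = sprintf("synth_%04d", i))
    })
    feature_table(fvs)
  } else {
    with_seed(seed, {
      total_bases <- rlnorm(n, log(5e9), 0.6)          # ~ a few Gbp per dataset
      richness <- rlnorm(n, log(2e9), 0.8)             # community 21-mer capacity
      distinct_21 <- richness * (1 - exp(-total_bases / richness))
      distinct_71 <- distinct_21 * runif(n, 1.25, 1.35) # less saturation at k=71
      distinct_13 <- pmin(3.35e7, distinct_21)          # 4^13/2 canonical cap
      avg_read_length <- runif(n, 140, 151)
      kmer_frac <- function(k) (avg_read_length - k + 1) / avg_read_length
      total_13 <- total_bases * kmer_frac(13)
      total_21 <- total_bases * kmer_frac(21)
      total_71 <- total_bases * kmer_frac(71)
      occ_bins <- runif(n, 200, 2000)                  # occupied spectrum bins
      data.frame(
        dataset_id = sprintf("synth_%04d", seq_len(n)),
        gc_content = runif(n, 0.35, 0.62),
        total_reads = round(total_bases / avg_read_length),
        min_read_length = sample(c(35, 50, 75), n, replace = TRUE),
        avg_read_length = avg_read_length,
        total_bases = total_bases,
        total_kmers_13 = total_13, distinct_kmers_13 = distinct_13,
        mean_13 = total_13 / occ_bins, sd_13 = total_13 / occ_bins * runif(n, 2, 8),
        max_13 = distinct_13 * runif(n, 0.3, 0.9),
        q5_13 = 0.05 * total_13 * runif(n, 0.2, 1),
        q95_13 = 0.05 * total_13 * runif(n, 0.2, 1),
        total_kmers_21 = total_21, distinct_kmers_21 = distinct_21,
        mean_21 = total_21 / occ_bins, sd_21 = total_21 / occ_bins * runif(n, 2, 8),
        max_21 = distinct_21 * runif(n, 0.5, 0.95),
        q5_21 = distinct_21 * runif(n, 0.3, 0.8),
        q95_21 = 0.05 * total_21 * runif(n, 0.2, 1),
        total_kmers_71 = total_71, distinct_kmers_71 = distinct_71,
        mean_71 = total_71 / occ_bins, sd_71 = total_71 / occ_bins * runif(n, 2, 8),
        max_71 = distinct_71 * runif(n, 0.5, 0.95),
        q5_71 = distinct_71 * runif(n, 0.3, 0.8),
        q95_71 = 0.05 * total_71 * runif(n, 0.2, 1),
        nonpareil_diversity = 13 + 2 * (log(distinct_21) - log(2e9)) + rnorm(n, 0, 0.4),
        stringsAsFactors = FALSE)
    })
  }
  response <- coef$intercept +
    coef$distinct_kmers_21 * df$distinct_kmers_21 +
    coef$distinct_kmers_71 * df$distinct_kmers_71
  noise <- with_seed(seed + 1L, rnorm(n, 0, noise_sd))
  df$observed_peak_ram_gb <- pmax(0.5, response + noise)
  truth <- list(response = "linear_distinct_21_71", coef = coef, noise_sd = noise_sd,
                planted_features = c("distinct_kmers_21", "distinct_kmers_71"),
                seed = seed, via_reads = via_reads)
  list(table = training_table(df, mode), truth = truth)
}

#' Synthetic abundance table with planted core structure
#'
#' Builds a species-by-sample abundance table plus sample metadata in which
#' a known set of species is planted as the global core (present in every
#' sample), one or more species per region are planted as regional core
#' members (present in all samples of 80% of the region's countries, rare
#' elsewhere), and a pool of background species appears independently at a
#' low rate. Abundances of present species are lognormal.
#'
#' @param regions named list mapping region name to a character vector of
#'   country codes.
#' @param samples_per_country samples per country (default 10).
#' @param n_global planted global-core species (default 3).
#' @param n_regional_per_region planted regional species per region (default 1).
#' @param n_background background species (default 30).
#' @param background_rate background presence probability in `[0, 1]`
#'   (default 0.3 -- typical sparse prevalence, safely below a 60% core rule).
#' @param offregion_rate presence probability of a regional species outside
#'   its designated countries (default 0.2, keeping its expected global prevalence
#:   well below a 60% global-core rule for any seed).
#' @param seed RNG seed.
#' @return list with `abundance` (matrix), `metadata` (data.frame:
#'   `sample_id`, `country`, `region`, `nonpareil_coverage_pct`) and `truth`
#'   (planted global species, per-region planted species with expected
#'   percent of countries, rates).
#' @export
synth_abundance_fixture <- function(regions = list(
                                      "Europe and Central Asia" = c("DE", "FR", "DK", "ES", "PL"),
                                      "North America" = c("US", "CA", "MX"),
                                      "East Asia and Pacific" = c("CN", "JP", "AU", "NZ")),
                                    samples_per_country = 10L,
                                    n_global = 3L, n_regional_per_region = 1L,
                                    n_background = 30L, background_rate = 0.3,
                                    offregion_rate = 0.2, seed = 1L) {
  if (!length(regions) || !all(lengths(regions) >= 1)) stopf("need >= 1 region with >= 1 country")
  if (background_rate < 0 || background_rate > 1) stopf("background_rate must lie in [0, 1]")
  if (offregion_rate < 0 || offregion_rate > 1) stopf("offregion_rate must lie in [0, 1]")
  all_countries <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_countries)) stopf("countries must be unique across regions")

  metadata <- do.call(rbind, lapply(names(regions), function(rg) {
    do.call(rbind, lapply(regions[[rg]], function(cn) data.frame(
      country = cn, region = rg,
      sample_id = sprintf("%s_s%02d", cn, seq_len(samples_per_country)),
      stringsAsFactors = FALSE)))
  }))
  n_samples <- nrow(metadata)

  species <- c(if (n_global > 0) sprintf("global_core_%02d", seq_len(n_global)),
               unlist(lapply(names(regions), function(rg)
                 if (n_regional_per_region > 0)
                   sprintf("regional_%s_%02d", gsub("[^A-Za-z]+", "_", rg),
                           seq_len(n_regional_per_region))), use.names = FALSE),
               if (n_background > 0) sprintf("background_%02d", seq_len(n_background)))

  with_seed(seed, {
    present <- matrix(FALSE, length(species), n_samples,
                      dimnames = list(species, metadata$sample_id))
    regional_truth <- NULL
    for (sp in species) {
      if (startsWith(sp, "global_core_")) {
        present[sp, ] <- TRUE
      } else if (startsWith(sp, "background_")) {
        present[sp, ] <- runif(n_samples) < background_rate
      } else { # regional species
        rg <- names(regions)[vapply(names(regions), function(r)
          startsWith(sp, paste0("regional_", gsub("[^A-Za-z]+", "_", r))), TRUE)]
        countries <- regions[[rg]]
        n_pass <- ceiling(0.8 * length(countries))
        designated <- sample(countries, n_pass)
        in_designated <- metadata$country %in% designated
        present[sp, in_designated] <- TRUE
        present[sp, !in_designated] <- runif(sum(!in_designated)) < offregion_rate
        regional_truth <- rbind(regional_truth, data.frame(
          region = rg, species = sp,
          expected_pct_countries_min = 100 * n_pass / length(countries),
          stringsAsFactors = FALSE))
      }
    }
    abundance <- matrix(0, length(species), n_samples,
                        dimnames = dimnames(present))
    hi <- grepl("^global_core_", species)
    abundance[present] <- rlnorm(sum(present), log(5), 1)
    if (any(hi)) {
      mask <- present & matrix(hi, length(species), n_samples)
      abundance[mask] <- rlnorm(sum(mask), log(50), 1)
    }
    metadata$nonpareil_coverage_pct <- runif(n_samples, 60, 95)
    truth <- list(global = species[hi],
                  regional = regional_truth,
                  background = species[grepl("^background_", species)],
                  background_rate = background_rate, offregion_rate = offregion_rate,
                  samples_per_country = samples_per_country, seed = seed)
    list(abundance = abundance,
         metadata = metadata[, c("sample_id", "country", "region", "nonpareil_coverage_pct")],
         truth = truth)
  })
}

#' Serialize / restore a planted-truth sidecar
#'
#' @param truth the `truth` element returned by a generator.
#' @param path JSON file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   restored list.
#' @export
write_truth <- function(truth, path) {
  writeLines(jsonlite::toJSON(truth, digits = I(17), auto_unbox = TRUE, null = "null",
                              dataframe = "rows"), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
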