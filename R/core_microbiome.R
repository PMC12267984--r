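# Core-microbiome analysis over a species-by-sample abundance table: low
# sequencing-depth sample filtering (Q1 - 1.5*IQR on the Nonpareil genome
# coverage percentage), ubiquity-abundance curves, a global core (strictly
# > 60% of all samples by default), a per-region "range-through" core (> 90%
# of a country's samples in >= 80% of the region's countries), and the share
# of samples in which each species is the single most abundant one.
#
# Presence defaults to abundance > 0: upstream read mapping is assumed to
# have applied its own base-coverage and identity thresholds before the
# table was built, so any non-zero entry is already a vetted detection.

check_abundance <- function(table) {
  table <- as.matrix(table)
  storage.mode(table) <- "double"
  if (!nrow(table) || !ncol(table)) stopf("empty abundance table")
  if (any(table < 0)) stopf("abundance table contains negative values")
  if (is.null(rownames(table)) || anyDuplicated(rownames(table)))
    stopf("abundance table needs unique species row names")
  if (is.null(colnames(table)) || anyDuplicated(colnames(table)))
    stopf("abundance table needs unique sample column names")
  table
}

#' Filter out low sequencing-depth samples
#'
#' Removes samples whose genome-coverage percentage (as estimated by an
#' external redundancy tool such as Nonpareil) lies strictly below
#' `Q1 - multiplier * IQR`, with quartiles by linear interpolation
#' (R quantile type 7). With fewer than 4 coverage values, or no coverage
#' column at all, no filtering is done and a warning is emitted.
#'
#' @param metadata data.frame with `sample_id` and (optionally)
#'   `nonpareil_coverage_pct`.
#' @param multiplier the IQR multiplier (default 1.5).
#' @return character vector of retained sample ids; the cutoff is attached
#'   as attribute `cutoff`.
#' @export
filter_samples_by_coverage <- function(metadata, multiplier = 1.5) {
  stopifnot(is.data.frame(metadata), "sample_id" %in% names(metadata))
  if (!"nonpareil_coverage_pct" %in% names(metadata)) {
    warnf("no nonpareil_coverage_pct column; returning all samples unfiltered")
    return(metadata$sample_id)
  }
  cov <- metadata$nonpareil_coverage_pct
  known <- !is.na(cov)
  if (sum(known) < 4L) {
    warnf("fewer than 4 coverage values; returning all samples unfiltered")
    return(metadata$sample_id)
  }
  qs <- stats::quantile(cov[known], c(0.25, 0.75), type = 7, names = FALSE)
  cutoff <- qs[1] - multiplier * (qs[2] - qs[1])
  keep <- !known | cov >= cutoff # samples without coverage are kept
  structure(metadata$sample_id[keep], cutoff = cutoff)
}

#' Ubiquity-abundance curves
#'
#' For each species and each abundance threshold `t`, the percentage of
#' samples whose abundance is at least `t`. Curves are non-increasing in the
#' threshold; crossing curves distinguish widespread low-abundance species
#' from locally dominant ones.
#'
#' @param table species-by-sample abundance matrix.
#' @param thresholds ascending numeric thresholds; by default 50 log10-spaced
#'   steps across the observed positive abundance range.
#' @return a `ubiquity_curves` object: list with `thresholds` and the
#'   species-by-threshold `ubiquity` matrix (percent).
#' @export
ubiquity_abundance_curves <- function(table, thresholds = NULL) {
  table <- check_abundance(table)
  if (is.null(thresholds)) {
    pos <- table[table > 0]
    if (!length(pos)) stopf("abundance table is all zero")
    thresholds <- 10^seq(log10(min(pos)), log10(max(pos)), length.out = 50L)
  }
  if (is.unsorted(thresholds, strictly = FALSE)) stopf("thresholds must be ascending")
  ub <- vapply(thresholds, function(t) 100 * rowMeans(table >= t),
               numeric(nrow(table)))
  ub <- matrix(ub, nrow = nrow(table),
               dimnames = list(rownames(table), NULL))
  structure(list(thresholds = thresholds, ubiquity = ub), class = "ubiquity_curves")
}

#' Plot ubiquity-abundance curves
#'
#' Mirrors the usual presentation: only species reaching
#' `min_ubiquity_display` percent ubiquity at the lowest threshold are drawn,
#' and species above `highlight` percent are coloured.
#'
#' @param curves a [ubiquity_abundance_curves()] result.
#' @param min_ubiquity_display display cutoff in percent (default 50).
#' @param highlight colour cutoff in percent (default 60).
#' @return a ggplot object.
#' @export
plot_ubiquity_curves <- function(curves, min_ubiquity_display = 50, highlight = 60) {
  stopifnot(inherits(curves, "ubiquity_curves"))
  base_ub <- curves$ubiquity[, 1]
  shown <- names(base_ub)[base_ub >= min_ubiquity_display]
  if (!length(shown)) stopf("no species reaches %g%% ubiquity", min_ubiquity_display)
  df <- do.call(rbind, lapply(shown, function(s) data.frame(
    species = s, threshold = curves$thresholds, ubiquity = curves$ubiquity[s, ],
    highlighted = base_ub[[s]] > highlight)))
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$threshold), y = .data$ubiquity,
                                   group = .data$species)) +
    ggplot2::geom_line(ggplot2::aes(colour = ifelse(.data$highlighted, .data$species, NA))) +
    ggplot2::labs(x = "Log10 abundance threshold", y = "Percent ubiquity",
                  colour = sprintf("> %g%% ubiquity", highlight)) +
    ggplot2::theme_minimal()
}

#' Global core species
#'
#' Species present (abundance strictly above `presence_threshold`) in
#' strictly more than `min_ubiquity` of all samples.
#'
#' @param table species-by-sample abundance matrix.
#' @param min_ubiquity fraction in `[0, 1]` (default 0.60).
#' @param presence_threshold abundance above which a species counts as
#'   present (default 0).
#' @return character vector of core species ids.
#' @export
global_core <- function(table, min_ubiquity = 0.60, presence_threshold = 0) {
  table <- check_abundance(table)
  prevalence <- rowMeans(table > presence_threshold)
  rownames(table)[prevalence > min_ubiquity]
}

#' Regional core species ("range-through" rule)
#'
#' Stage 1: within each country, species present in strictly more than
#' `per_country` of that country's samples. Stage 2: within each region, a
#' species is a core member when it passed stage 1 in at least
#' `country_fraction` of the region's countries (boundary inclusive).
#'
#' @param table species-by-sample abundance matrix.
#' @param metadata data.frame mapping every sample to `country` and `region`
#'   (region must be constant within a country).
#' @param per_country per-country ubiquity fraction (default 0.90, strict).
#' @param country_fraction fraction of a region's countries (default 0.80,
#'   inclusive).
#' @param presence_threshold as in [global_core()].
#' @return a `core_report` data.frame: `region`, `species`,
#'   `pct_countries` (percent of the region's countries passing stage 1),
#'   `member`. Species with no passing country in a region are omitted.
#' @export
regional_core <- function(table, metadata, per_country = 0.90,
                          country_fraction = 0.80, presence_threshold = 0) {
  table <- check_abundance(table)
  stopifnot(is.data.frame(metadata))
  idx <- match(colnames(table), metadata$sample_id)
  if (anyNA(idx)) stopf("metadata is missing sample(s): %s",
                        paste(head(colnames(table)[is.na(idx)], 3), collapse = ", "))
  country <- metadata$country[idx]
  region <- metadata$region[idx]
  if (anyNA(country) || anyNA(region)) stopf("every sample needs a country and region")
  if (any(tapply(region, country, function(r) length(unique(r))) > 1))
    stopf("region must be constant within a country")
  listed <- unique(metadata[, c("country", "region")])
  absent <- setdiff(listed$country, unique(country))
  if (length(absent))
    warnf("country with zero samples excluded from denominators: %s",
          paste(absent, collapse = ", "))

  present <- table > presence_threshold
  countries <- unique(country)
  # stage 1: species x country pass matrix (strict > per_country)
  pass <- vapply(countries, function(cn) {
    rowMeans(present[, country == cn, drop = FALSE]) > per_country
  }, logical(nrow(table)))
  pass <- matrix(pass, nrow = nrow(table),
                 dimnames = list(rownames(table), countries))

  country_region <- region[match(countries, country)]
  out <- lapply(unique(country_region), function(rg) {
    cols <- country_region == rg
    pct <- 100 * rowSums(pass[, cols, drop = FALSE]) / sum(cols)
    keep <- pct > 0
    if (!any(keep)) return(NULL)
    data.frame(region = rg, species = rownames(table)[keep],
               pct_countries = unname(pct[keep]),
               member = unname(pct[keep]) >= country_fraction * 100,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, out)
  if (is.null(report))
    report <- data.frame(region = character(), species = character(),
                         pct_countries = numeric(), member = logical())
  structure(report[order(report$region, -report$pct_countries, report$species), ,
                   drop = FALSE],
            class = c("core_report", "data.frame"),
            per_country = per_country, country_fraction = country_fraction)
}

#' Share of samples in which each species is the most abundant
#'
#' A species is credited for a sample only when it is the unique maximum;
#' ties (including all-zero samples, where every species ties at 0) credit
#' no species and are reported with a warning.
#'
#' @param table species-by-sample abundance matrix.
#' @param group sample ids to evaluate (default all samples).
#' @return named numeric vector: percent of the group's samples in which
#'   each species is the unique top species.
#' @export
top_abundance_share <- function(table, group = colnames(table)) {
  table <- check_abundance(table)
  if (!length(group)) stopf("empty sample group")
  unknown <- setdiff(group, colnames(table))
  if (length(unknown)) stopf("unknown sample(s): %s", paste(head(unknown, 3), collapse = ", "))
  credits <- stats::setNames(numeric(nrow(table)), rownames(table))
  ties <- 0L
  for (s in group) {
    x <- table[, s]
    top <- which(x == max(x))
    if (length(top) == 1L) credits[top] <- credits[top] + 1
    else ties <- ties + 1L
  }
  if (ties > 0L) warnf("%d sample(s) had tied maxima; no species credited for them", ties)
  100 * credits / length(group)
}
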