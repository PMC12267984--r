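# VM flavor allocation with escalate-on-out-of-memory retry accounting. An
# assembly attempt on a flavor succeeds iff the flavor's RAM covers the
# dataset's true peak; on failure the next-larger flavor is tried until
# success or the catalog is exhausted. Cost of a dataset is the summed RAM of
# every attempted flavor (failed attempts still occupied the machine).

#' Construct an ordered flavor catalog
#'
#' @param ram_gb numeric vector of flavor RAM sizes in GB (will be sorted;
#'   must be positive and distinct).
#' @param name optional flavor names (default `"<ram>GB"`).
#' @param cpus optional CPU counts, carried through but unused.
#' @return a `flavor_catalog` data.frame ordered by strictly increasing
#'   `ram_gb`.
#' @export
flavor_catalog <- function(ram_gb, name = NULL, cpus = NULL) {
  if (!length(ram_gb)) stopf("flavor catalog must not be empty")
  if (any(ram_gb <= 0)) stopf("flavor RAM sizes must be > 0")
  if (anyDuplicated(ram_gb)) stopf("flavor RAM sizes must be distinct")
  ord <- order(ram_gb)
  df <- data.frame(name = (name %||% sprintf("%gGB", ram_gb))[ord],
                   ram_gb = as.numeric(ram_gb)[ord], stringsAsFactors = FALSE)
  if (!is.null(cpus)) df$cpus <- cpus[ord]
  if (anyDuplicated(df$name)) stopf("flavor names must be unique")
  structure(df, class = c("flavor_catalog", "data.frame"))
}

#' The four-flavor default catalog (14/29/58/113 GB)
#' @return a [flavor_catalog()].
#' @export
default_flavor_catalog <- function() flavor_catalog(c(14, 29, 58, 113))

#' Read a flavor catalog from a YAML config
#'
#' Expects a list of mappings with keys `name` and `ram_gb` (top-level or
#' under a `flavors:` key).
#' @param path YAML file.
#' @return a [flavor_catalog()].
#' @export
read_flavor_catalog <- function(path) {
  cfg <- yaml::read_yaml(path)
  flavors <- cfg$flavors %||% cfg
  flavor_catalog(vapply(flavors, function(f) as.numeric(f$ram_gb), numeric(1)),
                 name = vapply(flavors, function(f) as.character(f$name %||% ""), ""))
}

flavor_index <- function(catalog, flavor) {
  i <- if (is.character(flavor)) match(flavor, catalog$name)
       else match(as.numeric(flavor), catalog$ram_gb)
  if (is.na(i)) stopf("unknown flavor: %s", flavor)
  i
}

#' Predicted RAM requirement of a dataset
#'
#' `max(0, point prediction) + bias_gb` -- the calibrated bias inflates the
#' point prediction so under-allocation is rare.
#'
#' @param bundle a `ram_model_bundle`.
#' @param fv a `feature_vector`, named numeric vector, or data.frame of
#'   feature columns (one row per dataset).
#' @return numeric vector of required GB.
#' @export
predict_required_ram <- function(bundle, fv) {
  stopifnot(inherits(bundle, "ram_model_bundle"))
  predict(bundle, fv, add_bias = TRUE)
}

#' Smallest flavor satisfying a RAM requirement
#'
#' @param catalog a [flavor_catalog()].
#' @param required_gb required RAM (>= 0); a flavor with `ram_gb ==
#'   required_gb` qualifies.
#' @return one-row slice of the catalog.
#' @export
select_flavor <- function(catalog, required_gb) {
  stopifnot(inherits(catalog, "flavor_catalog"))
  assert_scalar_number(required_gb, "required_gb", lower = 0)
  i <- which(catalog$ram_gb >= required_gb)[1L]
  if (is.na(i)) stopf("required RAM (%g GB) exceeds the largest catalog flavor (%g GB)",
                      required_gb, max(catalog$ram_gb))
  catalog[i, , drop = FALSE]
}

#' Next-larger flavor after an out-of-memory failure
#'
#' @param catalog a [flavor_catalog()].
#' @param current a flavor name or RAM size present in the catalog.
#' @return one-row slice of the catalog.
#' @export
escalate <- function(catalog, current) {
  stopifnot(inherits(catalog, "flavor_catalog"))
  i <- flavor_index(catalog, current)
  if (i == nrow(catalog))
    stopf("catalog exhausted: %s is already the largest flavor", catalog$name[i])
  catalog[i + 1L, , drop = FALSE]
}

#' Allocation policies for fleet simulation
#'
#' `policy_fixed(flavor)` starts every dataset on one flavor;
#' `policy_optimum()` starts each dataset on the smallest flavor that covers
#' its true peak (first-try success by construction);
#' `policy_predicted(required_gb)` starts each dataset on the smallest flavor
#' covering its predicted requirement.
#'
#' @param flavor flavor name or RAM size.
#' @param required_gb named numeric vector, one predicted requirement per
#'   dataset id.
#' @return an `allocation_policy` object.
#' @export
policy_fixed <- function(flavor) {
  structure(list(type = "fixed", flavor = flavor,
                 label = sprintf("Selected %s", flavor)), class = "allocation_policy")
}

#' @rdname policy_fixed
#' @export
policy_optimum <- function() {
  structure(list(type = "optimum", label = "Optimum"), class = "allocation_policy")
}

#' @rdname policy_fixed
#' @export
policy_predicted <- function(required_gb) {
  if (is.null(names(required_gb))) stopf("required_gb must be named by dataset id")
  structure(list(type = "predicted", required_gb = required_gb, label = "Predicted"),
            class = "allocation_policy")
}

start_index <- function(policy, catalog, id, peak) {
  switch(policy$type,
    fixed = flavor_index(catalog, policy$flavor),
    optimum = {
      i <- which(catalog$ram_gb >= peak)[1L]
      if (is.na(i)) nrow(catalog) else i # doomed dataset: single failing attempt
    },
    predicted = {
      j <- match(id, names(policy$required_gb))
      if (is.na(j)) stopf("no prediction for dataset '%s'", id)
      req <- policy$required_gb[[j]]
      i <- which(catalog$ram_gb >= req)[1L]
      if (is.na(i)) nrow(catalog) else i
    })
}

#' Simulate one allocation policy over a fleet of datasets
#'
#' @param true_peaks named numeric vector of true peak RAM (GB) per dataset.
#' @param policy an `allocation_policy`.
#' @param catalog a [flavor_catalog()].
#' @return a `fleet_simulation`: per-dataset attempt log, `total_cost_gb`
#'   (summed over successful datasets), `n_exhausted`.
#' @export
simulate_fleet <- function(true_peaks, policy, catalog = default_flavor_catalog()) {
  stopifnot(inherits(policy, "allocation_policy"), inherits(catalog, "flavor_catalog"))
  if (!length(true_peaks)) stopf("empty fleet")
  if (is.null(names(true_peaks))) names(true_peaks) <- sprintf("dataset_%03d", seq_along(true_peaks))
  if (any(true_peaks <= 0)) stopf("true peaks must be > 0")
  ram <- catalog$ram_gb
  logs <- lapply(names(true_peaks), function(id) {
    peak <- true_peaks[[id]]
    i <- start_index(policy, catalog, id, peak)
    attempts <- integer(0)
    repeat {
      attempts <- c(attempts, i)
      if (ram[i] >= peak) return(list(id = id, attempts = attempts, outcome = "success"))
      if (i == length(ram)) return(list(id = id, attempts = attempts, outcome = "exhausted"))
      i <- i + 1L
    }
  })
  per <- data.frame(
    dataset_id = vapply(logs, `[[`, "", "id"),
    n_attempts = vapply(logs, function(l) length(l$attempts), 0L),
    outcome = vapply(logs, `[[`, "", "outcome"),
    first_flavor = vapply(logs, function(l) catalog$name[l$attempts[1]], ""),
    final_flavor = vapply(logs, function(l) catalog$name[l$attempts[length(l$attempts)]], ""),
    cost_gb = vapply(logs, function(l) sum(ram[l$attempts]), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(policy = policy$label, per_dataset = per,
                 attempts = lapply(logs, function(l) catalog$ram_gb[l$attempts]),
                 total_cost_gb = sum(per$cost_gb[per$outcome == "success"]),
                 n_exhausted = sum(per$outcome == "exhausted")),
            class = "fleet_simulation")
}

#' @export
print.fleet_simulation <- function(x, ...) {
  cat(sprintf("fleet simulation [%s]: %d datasets, total %g GB, %d exhausted\n",
              x$policy, nrow(x$per_dataset), x$total_cost_gb, x$n_exhausted))
  invisible(x)
}

#' Compare allocation policies over one fleet
#'
#' Runs every requested fixed-start policy, the optimum policy, and (when
#' predictions are supplied) the predicted policy, and tabulates total RAM
#' cost and savings of the predicted policy over each alternative.
#'
#' @param true_peaks named numeric vector of true peaks (GB).
#' @param predictions named numeric vector of predicted requirements
#'   (`prediction + bias`), or `NULL` to skip the predicted policy.
#' @param catalog a [flavor_catalog()].
#' @param fixed_starts flavors (names or RAM sizes) to use as fixed starts.
#' @return a `policy_comparison`: list of `fleet_simulation`s plus a
#'   `summary` data.frame with `savings_gb = total(policy) -
#'   total(predicted)`.
#' @export
compare_policies <- function(true_peaks, predictions = NULL,
                             catalog = default_flavor_catalog(),
                             fixed_starts = catalog$ram_gb) {
  if (!length(true_peaks)) stopf("empty fleet")
  policies <- lapply(fixed_starts, policy_fixed)
  policies <- c(policies, list(policy_optimum()))
  if (!is.null(predictions)) policies <- c(policies, list(policy_predicted(predictions)))
  sims <- lapply(policies, simulate_fleet, true_peaks = true_peaks, catalog = catalog)
  names(sims) <- vapply(sims, `[[`, "", "policy")
  totals <- vapply(sims, `[[`, numeric(1), "total_cost_gb")
  ref <- if (!is.null(predictions)) totals[["Predicted"]] else totals[["Optimum"]]
  summary <- data.frame(policy = names(sims), total_cost_gb = unname(totals),
                        n_exhausted = vapply(sims, `[[`, 0L, "n_exhausted"),
                        savings_gb = unname(totals - ref), row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(simulations = sims, summary = summary,
                 reference = if (!is.null(predictions)) "Predicted" else "Optimum"),
            class = "policy_comparison")
}

#' @export
print.policy_comparison <- function(x, ...) {
  cat(sprintf("policy comparison (savings relative to %s):\n", x$reference))
  print.data.frame(x$summary, row.names = FALSE)
  invisible(x)
}

#' Bar chart of total RAM cost per policy
#'
#' @param comparison a `policy_comparison`.
#' @return a ggplot object.
#' @export
plot_policy_comparison <- function(comparison) {
  stopifnot(inherits(comparison, "policy_comparison"))
  df <- comparison$summary
  df$policy <- factor(df$policy, levels = df$policy)
  ref_total <- df$total_cost_gb[df$policy == comparison$reference]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$policy, y = .data$total_cost_gb)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = ref_total, colour = "red") +
    ggplot2::labs(x = NULL, y = "Total peak RAM (GB)",
                  title = "RAM cost of allocation policies") +
    ggplot2::theme_minimal()
}
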