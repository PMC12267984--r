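# Peak-RAM model pipeline: correlation screening -> family cross-validation
# -> selection -> grid search -> importance-based pruning -> final fit with
# bias calibration on an untouched holdout. One model is trained per
# assembler parameter setting ("default" or "meta-sensitive"); the wider
# k-mer range of the meta-sensitive setting costs more RAM, so the two
# responses are modelled separately with the same features.

#' Construct a training table
#'
#' @param df data.frame with `dataset_id`, one column per feature, and the
#'   response `observed_peak_ram_gb` (> 0).
#' @param mode assembler parameter setting the peaks were observed under.
#' @return the validated data.frame, classed `training_table` with a
#'   `mode` attribute.
#' @export
training_table <- function(df, mode = c("default", "meta-sensitive")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(df))
  need <- c("dataset_id", "observed_peak_ram_gb")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("training table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$dataset_id)) stopf("duplicated dataset_id in training table")
  if (any(df$observed_peak_ram_gb <= 0)) stopf("observed_peak_ram_gb must be > 0")
  structure(df, class = c("training_table", "data.frame"), mode = mode)
}

#' @rdname training_table
#' @param path TSV file with a header row.
#' @export
read_training_table <- function(path, mode = c("default", "meta-sensitive")) {
  training_table(read_tsv(path), mode)
}

#' @rdname training_table
#' @param table a `training_table`.
#' @export
write_training_table <- function(table, path) write_tsv(table, path)

#' Feature columns of a training table
#' @param table a `training_table` (or compatible data.frame).
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("dataset_id", "observed_peak_ram_gb"))
}

table_xy <- function(table, features = feature_columns(table)) {
  X <- as.matrix(table[, features, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(table$observed_peak_ram_gb), ids = table$dataset_id)
}

#' Screen candidate features by correlation with observed peak RAM
#'
#' Computes the Pearson correlation of every feature with the response and
#' its two-sided P-value (t transform). A feature is retained when `r >
#' r_min` (or `|r| > r_min` with `absolute = TRUE`) and `P < p_max`.
#' Constant features have undefined correlation and are dropped with a
#' warning; features with missing values are screened on complete pairs.
#'
#' @param table a [training_table()] with at least 3 rows.
#' @param r_min correlation threshold (default 0.6).
#' @param p_max P-value threshold (default 0.05).
#' @param absolute screen on `|r|` instead of signed `r`.
#' @return a `screen_report` data.frame: `feature`, `r`, `p_value`,
#'   `retained`.
#' @export
screen_features_by_correlation <- function(table, r_min = 0.6, p_max = 0.05,
                                           absolute = FALSE) {
  if (nrow(table) < 3L) stopf("correlation screening needs >= 3 rows")
  feats <- feature_columns(table)
  if (!length(feats)) stopf("no feature columns in training table")
  y <- as.numeric(table$observed_peak_ram_gb)
  rows <- lapply(feats, function(f) {
    x <- as.numeric(table[[f]])
    ok <- !is.na(x)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warnf("feature '%s' is constant or near-empty; dropped from screening", f)
      return(data.frame(feature = f, r = NA_real_, p_value = NA_real_, retained = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r <- unname(ct$estimate)
    data.frame(feature = f, r = r, p_value = ct$p.value,
               retained = (if (absolute) abs(r) else r) > r_min && ct$p.value < p_max)
  })
  report <- do.call(rbind, rows)
  if (all(is.na(report$r))) stopf("all features were dropped (constant)")
  structure(report, class = c("screen_report", "data.frame"),
            r_min = r_min, p_max = p_max, absolute = absolute)
}

#' @rdname screen_features_by_correlation
#' @param report a `screen_report`.
#' @return for `retained_features()`, the retained feature names.
#' @export
retained_features <- function(report) {
  stopifnot(inherits(report, "screen_report"))
  report$feature[report$retained]
}

make_folds <- function(n, k_folds, seed) {
  if (k_folds > n) stopf("k_folds (%d) exceeds the number of rows (%d)", k_folds, n)
  with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
}

cv_rmse <- function(table, family, params, folds, seed) {
  d <- table_xy(table)
  vapply(sort(unique(folds)), function(fold) {
    test <- folds == fold
    reg <- fit_family(family, d$X[!test, , drop = FALSE], d$y[!test],
                      params = params, seed = seed)
    sqrt(mean((d$y[test] - predict(reg, d$X[test, , drop = FALSE]))^2))
  }, numeric(1))
}

#' Cross-validate regressor families on a training table
#'
#' All families are evaluated on one identical random fold partition so the
#' per-family mean and SD of the fold RMSEs are directly comparable.
#'
#' @param table a [training_table()].
#' @param families character vector of [ram_families()] entries.
#' @param k_folds number of folds (default 10).
#' @param seed seed for the fold partition and the tree builders.
#' @param params optional named list of per-family hyperparameter lists.
#' @return a `cv_report` data.frame (`family`, `mean_rmse_gb`, `sd_rmse_gb`,
#'   `k_folds`, `seed`) with the fold assignment in attribute `folds`.
#' @export
crossvalidate_families <- function(table, families = ram_families(),
                                   k_folds = 10L, seed = 1L, params = list()) {
  if (!length(families)) stopf("no families given")
  families <- vapply(families, match.arg, "", choices = ram_families())
  folds <- make_folds(nrow(table), k_folds, seed)
  rows <- lapply(families, function(fam) {
    rmse <- cv_rmse(table, fam, params[[fam]] %||% list(), folds, seed)
    data.frame(family = fam, mean_rmse_gb = mean(rmse), sd_rmse_gb = stats::sd(rmse),
               k_folds = k_folds, seed = seed)
  })
  structure(do.call(rbind, rows), class = c("cv_report", "data.frame"), folds = folds)
}

#' Select the best family from a cross-validation report
#'
#' Lowest mean RMSE wins; ties break on lowest SD, then on input order.
#'
#' @param report a `cv_report`.
#' @return the selected family id.
#' @export
select_family <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  if (!nrow(report)) stopf("empty cross-validation report")
  report$family[order(report$mean_rmse_gb, report$sd_rmse_gb)][1L]
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates the full Cartesian product of the supplied value lists by
#' cross-validated mean RMSE on one fixed fold partition. Duplicate grid
#' points are evaluated once.
#'
#' @param table a [training_table()].
#' @param family a [ram_families()] entry.
#' @param grid named list of parameter value vectors, e.g.
#'   `list(min_samples_leaf = c(1, 5), n_estimators = c(100, 300))`.
#' @param k_folds,seed as in [crossvalidate_families()].
#' @return list with `params` (best setting), and `results` (per-point mean
#'   RMSE, in evaluation order).
#' @export
grid_search <- function(table, family, grid, k_folds = 10L, seed = 1L) {
  if (!length(grid) || !all(lengths(grid) > 0)) stopf("empty hyperparameter grid")
  pts <- unique(expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  folds <- make_folds(nrow(table), k_folds, seed)
  mean_rmse <- vapply(seq_len(nrow(pts)), function(i) {
    mean(cv_rmse(table, family, as.list(pts[i, , drop = FALSE]), folds, seed))
  }, numeric(1))
  best <- which.min(mean_rmse) # ties: first point in grid order
  list(params = as.list(pts[best, , drop = FALSE]),
       results = cbind(pts, mean_rmse_gb = mean_rmse))
}

#' Reduce the feature set by tree-ensemble importance
#'
#' Ranks features by impurity-based importance of a fit on the full table
#' and keeps either the top `m`, the smallest prefix reaching a cumulative
#' importance, or an explicit override list.
#'
#' @param table a [training_table()].
#' @param family an importance-capable family (`decision_tree`,
#'   `random_forest`, `extra_trees`).
#' @param params hyperparameters for the fit.
#' @param keep one of `list(top_m = m)`, `list(cum_importance = x)` with
#'   `0 < x <= 1`, or `list(override = c("feat", ...))`.
#' @param seed seed for the fit.
#' @return character vector of kept feature names.
#' @export
prune_features_by_importance <- function(table, family, params = list(),
                                         keep = list(top_m = 2L), seed = 1L) {
  feats <- feature_columns(table)
  if (!is.null(keep$override)) {
    unknown <- setdiff(keep$override, feats)
    if (length(unknown)) stopf("override names unknown feature(s): %s",
                               paste(unknown, collapse = ", "))
    return(keep$override)
  }
  d <- table_xy(table)
  imp <- feature_importance(fit_family(family, d$X, d$y, params = params, seed = seed))
  ranked <- sort(imp, decreasing = TRUE)
  if (!is.null(keep$top_m)) return(names(ranked)[seq_len(min(keep$top_m, length(ranked)))])
  if (!is.null(keep$cum_importance)) {
    stopifnot(keep$cum_importance > 0, keep$cum_importance <= 1)
    m <- which(cumsum(ranked) >= keep$cum_importance)[1L]
    return(names(ranked)[seq_len(m)])
  }
  stopf("keep must supply one of top_m, cum_importance or override")
}

#' Calibrate the under-allocation bias on a holdout set
#'
#' The point prediction is deliberately inflated by a bias so that requesting
#' `prediction + bias` GB rarely under-allocates. The bias is the upper
#' endpoint of a seeded bootstrap 95% percentile confidence interval of an
#' error statistic on a holdout disjoint from the training rows:
#' \describe{
#'   \item{`error_quantile` (default)}{the `q` quantile (default 0.9) of the
#'     signed error `observed - predicted`. Guards per-dataset
#'     under-allocation directly: with `q = 0.9` roughly 90% of datasets fit
#'     below `prediction + bias` before the CI safety margin.}
#'   \item{`mean_abs_error`}{the mean absolute error. Its CI upper endpoint
#'     sits near one SD of the error distribution, so per-dataset coverage
#'     is only ~84% for symmetric errors; retained for comparability.}
#' }
#'
#' @param model a `ram_regressor` (with recorded `training_ids`).
#' @param holdout a [training_table()] slice with >= 10 rows, disjoint from
#'   the training rows.
#' @param method see Details.
#' @param q error quantile for `error_quantile`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level of the percentile interval (default 0.95).
#' @param seed bootstrap seed.
#' @return a `bias_calibration` list: `bias_gb` (`max(0, ci[2])`), `ci`,
#'   `method`, `errors`.
#' @export
calibrate_bias <- function(model, holdout, method = c("error_quantile", "mean_abs_error"),
                           q = 0.9, n_boot = 1000L, conf = 0.95, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(model, "ram_regressor"))
  if (nrow(holdout) < 10L) stopf("bias calibration needs >= 10 holdout rows")
  if (!is.null(model$training_ids) && !is.null(holdout$dataset_id)) {
    overlap <- intersect(model$training_ids, holdout$dataset_id)
    if (length(overlap)) stopf("holdout overlaps training rows: %s",
                               paste(head(overlap, 3), collapse = ", "))
  }
  d <- table_xy(holdout, model$features)
  errors <- d$y - predict(model, d$X)
  stat <- switch(method,
    error_quantile = function(e) unname(stats::quantile(e, q, type = 7)),
    mean_abs_error = function(e) mean(abs(e)))
  boot <- with_seed(seed, {
    n <- length(errors)
    vapply(seq_len(n_boot), function(i) stat(errors[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(list(bias_gb = max(0, ci[2]), ci = ci, method = method, q = q,
                 n_boot = n_boot, conf = conf, errors = errors),
            class = "bias_calibration")
}

#' Fit the final model bundle
#'
#' Splits off a random holdout fraction, trains the chosen family on the
#' rest, calibrates the bias on the holdout, and packages everything needed
#' for prediction and persistence.
#'
#' @param table a [training_table()].
#' @param family a [ram_families()] entry.
#' @param params hyperparameters for the family.
#' @param features feature names to train on (subset of the table columns).
#' @param holdout_fraction fraction of rows reserved for bias calibration
#'   (default 0.1; at least 10 rows are required).
#' @param seed seed for the split, fit and bootstrap.
#' @param bias_method passed to [calibrate_bias()].
#' @return a `ram_model_bundle`.
#' @export
fit_final_model <- function(table, family, params = list(), features,
                            holdout_fraction = 0.1, seed = 1L,
                            bias_method = "error_quantile") {
  unknown <- setdiff(features, feature_columns(table))
  if (length(unknown)) stopf("unknown feature(s): %s", paste(unknown, collapse = ", "))
  n <- nrow(table)
  n_hold <- max(10L, ceiling(holdout_fraction * n))
  if (n_hold >= n) stopf("table too small for a %.0f%% holdout of >= 10 rows",
                         100 * holdout_fraction)
  hold_idx <- with_seed(seed, sample.int(n, n_hold))
  train <- table[-hold_idx, , drop = FALSE]
  holdout <- table[hold_idx, , drop = FALSE]
  d <- table_xy(train, features)
  model <- fit_family(family, d$X, d$y, params = params, seed = seed,
                      training_ids = train$dataset_id)
  cal <- calibrate_bias(model, holdout, method = bias_method, seed = seed)
  dh <- table_xy(holdout, features)
  pred_h <- predict(model, dh$X)
  structure(list(
    format_version = 1L,
    family = family, params = params, features = features,
    mode = attr(table, "mode") %||% "default",
    bias_gb = cal$bias_gb, bias_ci = cal$ci, bias_method = cal$method,
    model = model,
    holdout_ids = holdout$dataset_id,
    metadata = list(seed = seed, n_train = nrow(train), n_holdout = n_hold,
                    holdout_rmse_gb = sqrt(mean((dh$y - pred_h)^2)),
                    holdout_mae_gb = mean(abs(dh$y - pred_h)),
                    package_version = as.character(utils::packageVersion("asmram")),
                    r_version = R.version.string)
  ), class = "ram_model_bundle")
}

#' @export
predict.ram_model_bundle <- function(object, newdata, add_bias = FALSE, ...) {
  p <- predict(object$model, newdata)
  if (add_bias) pmax(0, p) + object$bias_gb else p
}

#' @export
print.ram_model_bundle <- function(x, ...) {
  cat(sprintf("peak-RAM model bundle: %s (%s mode)\n", x$family, x$mode))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  bias: %.2f GB (%s, 95%% CI [%.2f, %.2f])\n",
              x$bias_gb, x$bias_method, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  holdout RMSE %.2f GB over %d datasets\n",
              x$metadata$holdout_rmse_gb, x$metadata$n_holdout))
  invisible(x)
}

# --- persistence ------------------------------------------------------------

serialize_fit <- function(family, fit) {
  switch(family,
    linear = list(coef = as.list(fit$coef)),
    voting = list(members = lapply(fit$members, function(m)
      serialize_fit(if (is.null(m$trees)) "linear" else "forest", m))),
    list(trees = fit$trees, importance = fit$importance)) # any forest family
}

rehydrate_fit <- function(family, raw) {
  switch(family,
    linear = list(coef = unlist(raw$coef)),
    voting = {
      fams <- names(raw$members)
      list(members = lapply(stats::setNames(fams, fams), function(f)
        rehydrate_fit(if (f == "linear") "linear" else "forest", raw$members[[f]])))
    },
    {
      trees <- lapply(raw$trees, function(tr) list(
        feature = as.integer(tr$feature),
        threshold = as.numeric(tr$threshold),
        left = as.integer(tr$left), right = as.integer(tr$right),
        value = as.numeric(tr$value)))
      list(trees = trees, importance = as.numeric(raw$importance))
    })
}

#' Save / load a model bundle
#'
#' Bundles are persisted as plain JSON (metadata plus the full regressor
#' state) so that a loaded bundle reproduces the saved bundle's predictions
#' exactly.
#'
#' @param bundle a `ram_model_bundle`.
#' @param path file path (conventionally `.json`).
#' @return `save_bundle()` returns `path` invisibly; `load_bundle()` the
#'   restored bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "ram_model_bundle"))
  payload <- list(
    format_version = bundle$format_version,
    family = bundle$family, params = bundle$params, features = bundle$features,
    mode = bundle$mode, bias_gb = bundle$bias_gb, bias_ci = bundle$bias_ci,
    bias_method = bundle$bias_method, holdout_ids = bundle$holdout_ids,
    metadata = bundle$metadata,
    model = list(family = bundle$model$family, seed = bundle$model$seed,
                 params = bundle$model$params,
                 training_ids = bundle$model$training_ids,
                 fit = serialize_fit(bundle$model$family, bundle$model$fit)))
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, null = "null"),
             path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                                         simplifyMatrix = FALSE),
                      error = function(e) stopf("not a valid model bundle: %s", conditionMessage(e)))
  if (is.null(payload$format_version) || payload$format_version != 1L)
    stopf("unsupported bundle format version: %s", payload$format_version %||% "<absent>")
  model <- structure(list(
    family = payload$model$family,
    fit = rehydrate_fit(payload$model$family, payload$model$fit),
    features = unlist(payload$features), params = payload$model$params,
    seed = payload$model$seed, training_ids = unlist(payload$model$training_ids)),
    class = "ram_regressor")
  structure(list(
    format_version = 1L, family = payload$family, params = payload$params,
    features = unlist(payload$features), mode = payload$mode,
    bias_gb = payload$bias_gb, bias_ci = unlist(payload$bias_ci),
    bias_method = payload$bias_method, model = model,
    holdout_ids = unlist(payload$holdout_ids), metadata = payload$metadata),
    class = "ram_model_bundle")
}
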