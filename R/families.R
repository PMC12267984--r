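# Regressor family registry. Tree ensembles are grown by the package's own
# C++ builder (no tree package assumed present): "decision_tree" is a single
# greedy CART-style tree, "random_forest" adds bootstrap resampling, and
# "extra_trees" (extremely randomized trees) draws the split threshold
# uniformly between the node minimum and maximum of each candidate feature
# instead of optimizing it -- the extra randomization decorrelates trees and
# typically lowers ensemble variance. "voting" averages the linear model and
# both forests. Feature importances are impurity (variance) decreases summed
# per feature and normalized, as in the usual tree-ensemble definition.

.tree_defaults <- list(n_estimators = 100L, min_samples_leaf = 1L, max_features = 1.0)

fit_tree_family <- function(X, y, params, seed, random_threshold, bootstrap, single = FALSE) {
  p <- modifyList(.tree_defaults, params)
  mtry <- max(1L, min(ncol(X), as.integer(ceiling(p$max_features * ncol(X)))))
  n_trees <- if (single) 1L else as.integer(p$n_estimators)
  grow_forest_cpp(X, y, n_trees, mtry, as.integer(p$min_samples_leaf),
                  random_threshold, bootstrap, as.integer(seed))
}

fit_linear <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0 # collinear columns contribute nothing
  list(coef = coefs)
}

predict_linear <- function(fit, X) drop(cbind(1, X) %*% fit$coef)

.family_registry <- list(
  linear = list(
    fit = function(X, y, params, seed) fit_linear(X, y),
    predict = function(fit, X) predict_linear(fit, X),
    importance = NULL),
  decision_tree = list(
    fit = function(X, y, params, seed)
      fit_tree_family(X, y, params, seed, random_threshold = FALSE,
                      bootstrap = FALSE, single = TRUE),
    predict = function(fit, X) predict_forest_cpp(fit$trees, X),
    importance = function(fit) fit$importance),
  random_forest = list(
    fit = function(X, y, params, seed)
      fit_tree_family(X, y, params, seed, random_threshold = FALSE, bootstrap = TRUE),
    predict = function(fit, X) predict_forest_cpp(fit$trees, X),
    importance = function(fit) fit$importance),
  extra_trees = list(
    fit = function(X, y, params, seed)
      fit_tree_family(X, y, params, seed, random_threshold = TRUE, bootstrap = FALSE),
    predict = function(fit, X) predict_forest_cpp(fit$trees, X),
    importance = function(fit) fit$importance),
  voting = list(
    fit = function(X, y, params, seed) {
      members <- c("linear", "random_forest", "extra_trees")
      list(members = lapply(stats::setNames(members, members), function(f)
        .family_registry[[f]]$fit(X, y, params, seed)))
    },
    predict = function(fit, X) {
      preds <- vapply(names(fit$members), function(f)
        .family_registry[[f]]$predict(fit$members[[f]], X), numeric(nrow(X)))
      rowMeans(preds)
    },
    importance = NULL)
)

#' Available regressor families
#'
#' @return character vector of family identifiers.
#' @export
ram_families <- function() names(.family_registry)

#' Fit one regressor family
#'
#' @param family one of [ram_families()].
#' @param X numeric feature matrix (rows = datasets).
#' @param y numeric response (observed peak RAM, GB).
#' @param params named list of hyperparameters. Tree families understand
#'   `n_estimators` (default 100), `min_samples_leaf` (default 1) and
#'   `max_features` (fraction of features per split, default 1.0).
#' @param seed integer seed for the tree builders.
#' @param training_ids optional dataset ids of the training rows; recorded so
#'   bias calibration can verify holdout disjointness.
#' @return a `ram_regressor` object with a [predict()] method.
#' @export
fit_family <- function(family, X, y, params = list(), seed = 1L, training_ids = NULL) {
  fam <- .family_registry[[match.arg(family, ram_families())]]
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stopf("feature matrix contains missing values")
  structure(list(family = family, fit = fam$fit(X, y, params, seed),
                 features = colnames(X), params = params, seed = seed,
                 training_ids = training_ids),
            class = "ram_regressor")
}

#' @export
predict.ram_regressor <- function(object, newdata, ...) {
  X <- regressor_matrix(newdata, object$features)
  .family_registry[[object$family]]$predict(object$fit, X)
}

#' Impurity-based feature importances of a fitted regressor
#'
#' @param object a `ram_regressor`.
#' @return named numeric vector summing to 1, or an error for families
#'   without importances (linear, voting).
#' @export
feature_importance <- function(object) {
  stopifnot(inherits(object, "ram_regressor"))
  getter <- .family_registry[[object$family]]$importance
  if (is.null(getter))
    stopf("family '%s' does not expose feature importances; use keep = list(override = ...)",
          object$family)
  stats::setNames(getter(object$fit), object$features)
}

# Coerce newdata (data.frame, matrix, feature_vector or named numeric) into
# the column order the regressor was trained with; errors name any feature
# that is absent.
regressor_matrix <- function(newdata, features) {
  if (inherits(newdata, "feature_vector"))
    newdata <- as.data.frame(t(newdata$values))
  if (is.numeric(newdata) && !is.matrix(newdata))
    newdata <- as.data.frame(t(newdata))
  newdata <- as.data.frame(newdata)
  miss <- setdiff(features, names(newdata))
  if (length(miss)) stopf("missing feature(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, features, drop = FALSE])
  storage.mode(X) <- "double"
  X
}
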