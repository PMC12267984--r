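make_screen_table <- function(n = 20, seed = 5) {
  withr::with_seed(seed, {
    y <- runif(n, 10, 100)
    training_table(data.frame(
      dataset_id = sprintf("d%02d", 1:n),
      noisy_copy = y + rnorm(n, 0, 2),    # strongly correlated with the target
      pure_noise = rnorm(n),              # independent
      constant = 1,
      observed_peak_ram_gb = y), "default")
  })
}

test_that("correlation screening retains signal, drops noise and constants", {
  tab <- make_screen_table()
  expect_warning(report <- screen_features_by_correlation(tab), "constant")
  expect_true(report$retained[report$feature == "noisy_copy"])
  expect_false(report$retained[report$feature == "pure_noise"])
  expect_false(report$retained[report$feature == "constant"])
  expect_identical(retained_features(report), "noisy_copy")

  # r and P match the textbook formulas
  o <- oracle_pearson(tab$noisy_copy, tab$observed_peak_ram_gb)
  expect_equal(report$r[report$feature == "noisy_copy"], o$r, tolerance = 1e-12)
  expect_equal(report$p_value[report$feature == "noisy_copy"], o$p, tolerance = 1e-12)

  # a feature identical to the target has r = 1 and is retained
  tab$noisy_copy <- tab$observed_peak_ram_gb
  rep2 <- suppressWarnings(screen_features_by_correlation(tab))
  expect_equal(rep2$r[rep2$feature == "noisy_copy"], 1)
  expect_true(rep2$retained[rep2$feature == "noisy_copy"])

  expect_error(screen_features_by_correlation(tab[1:2, ]), ">= 3 rows")
  all_const <- training_table(data.frame(dataset_id = c("a", "b", "c"), f = 1,
                                         observed_peak_ram_gb = 1:3), "default")
  expect_error(suppressWarnings(screen_features_by_correlation(all_const)),
               "all features were dropped")
})

test_that("cross-validation is deterministic, shares folds, and nails linear data", {
  tab <- withr::with_seed(2, {
    x1 <- runif(60, 0, 5); x2 <- runif(60, 0, 5)
    training_table(data.frame(dataset_id = sprintf("d%03d", 1:60), x1 = x1, x2 = x2,
                              observed_peak_ram_gb = 10 + 3 * x1 + 2 * x2),
                   "default") # noise-free linear response
  })

  rep1 <- crossvalidate_families(tab, c("linear", "decision_tree"), seed = 4)
  rep2 <- crossvalidate_families(tab, c("linear", "decision_tree"), seed = 4)
  expect_identical(rep1, rep2)
  expect_identical(attr(rep1, "folds"), attr(rep2, "folds"))
  expect_lt(rep1$mean_rmse_gb[rep1$family == "linear"], 1e-6 * mean(tab$observed_peak_ram_gb))

  expect_error(crossvalidate_families(tab[1:5, ], "linear", k_folds = 10), "exceeds")
  expect_error(crossvalidate_families(tab, character()), "no families")
})

test_that("extremely randomized trees beat a single greedy tree on nonlinear data", {
  # ensemble variance reduction shows up on noisy nonlinear data; compare the
  # families across a few independent worlds rather than one lucky draw
  mean_rmse <- vapply(1:3, function(s) {
    tab <- nonlinear_table(n = 150, seed = s, noise_sd = 2)
    rep <- crossvalidate_families(tab, c("decision_tree", "extra_trees"), seed = s)
    rep$mean_rmse_gb
  }, numeric(2))
  expect_lte(mean(mean_rmse[2, ]), mean(mean_rmse[1, ]))
})

test_that("family selection uses lowest mean, then lowest SD, then input order", {
  rep <- structure(data.frame(family = c("a", "b", "c"),
                              mean_rmse_gb = c(2, 1, 1),
                              sd_rmse_gb = c(0.1, 0.5, 0.2)),
                   class = c("cv_report", "data.frame"))
  expect_identical(select_family(rep), "c")
  rep$sd_rmse_gb <- c(0.1, 0.2, 0.2)
  expect_identical(select_family(rep), "b") # full tie: input order
  expect_identical(select_family(rep[1, , drop = FALSE]), "a")
  expect_error(select_family(rep[0, , drop = FALSE]), "empty")
})

test_that("grid search is exhaustive, deduplicated and deterministic", {
  tab <- nonlinear_table(n = 80, seed = 12)
  single <- grid_search(tab, "extra_trees",
                        list(min_samples_leaf = 2L, n_estimators = 50L),
                        k_folds = 5, seed = 12)
  expect_equal(single$params$min_samples_leaf, 2L)
  expect_equal(nrow(single$results), 1L)

  # min_samples_leaf = n forces a constant (root-leaf) predictor and must lose
  gs <- grid_search(tab, "extra_trees",
                    list(min_samples_leaf = c(1L, nrow(tab)), n_estimators = 50L),
                    k_folds = 5, seed = 12)
  expect_equal(gs$params$min_samples_leaf, 1L)
  expect_equal(nrow(gs$results), 2L)

  dup <- grid_search(tab, "extra_trees",
                     list(min_samples_leaf = c(2L, 2L), n_estimators = 50L),
                     k_folds = 5, seed = 12)
  expect_equal(nrow(dup$results), 1L)

  expect_error(grid_search(tab, "extra_trees", list()), "empty hyperparameter grid")
})

test_that("importance pruning recovers planted predictors or honours overrides", {
  # response driven by x2 only: x2 must rank first
  tab <- nonlinear_table(n = 150, seed = 3)
  tab$observed_peak_ram_gb <- 20 + 10 * (tab$x2 > 5) + tab$x2
  expect_identical(
    prune_features_by_importance(tab, "extra_trees", keep = list(top_m = 1L), seed = 3),
    "x2")

  # planted two-feature response: top-2 recovers the pair
  tab2 <- withr::with_seed(6, {
    a <- runif(200); b <- runif(200); c <- runif(200); d <- runif(200)
    training_table(data.frame(
      dataset_id = sprintf("d%03d", 1:200), a = a, b = b, c = c, d = d,
      observed_peak_ram_gb = 5 + 40 * a + 25 * c + rnorm(200, 0, 0.5)), "default")
  })
  expect_setequal(
    prune_features_by_importance(tab2, "extra_trees", keep = list(top_m = 2L), seed = 6),
    c("a", "c"))

  # explicit override (the final-model route) returns exactly that set
  override <- c("distinct_kmers_21", "distinct_kmers_71", "nonpareil_diversity", "gc_content")
  syn <- synth_training_table(30, seed = 4)
  expect_identical(
    prune_features_by_importance(syn$table, "extra_trees",
                                 keep = list(override = override)),
    override)
  expect_error(
    prune_features_by_importance(syn$table, "extra_trees",
                                 keep = list(override = "no_such_feature")),
    "unknown feature")

  # families without importances point to the override escape hatch
  expect_error(prune_features_by_importance(tab, "linear", keep = list(top_m = 1L)),
               "override")
})

test_that("bias calibration guards under-allocation and matches a re-coded bootstrap", {
  syn <- synth_training_table(120, seed = 9)
  feats <- c("distinct_kmers_21", "distinct_kmers_71")
  train <- syn$table[1:90, ]
  hold <- syn$table[91:120, ]
  d <- list(X = as.matrix(train[, feats]), y = train$observed_peak_ram_gb)
  model <- fit_family("linear", d$X, d$y, training_ids = train$dataset_id)

  cal <- calibrate_bias(model, hold, seed = 31)
  cal2 <- calibrate_bias(model, hold, seed = 31)
  expect_identical(cal$bias_gb, cal2$bias_gb)

  # independent bootstrap re-implementation (same RNG contract)
  errors <- hold$observed_peak_ram_gb - predict(model, hold[, feats])
  boot <- withr::with_seed(31, replicate(1000, {
    e <- sample(errors, replace = TRUE)
    unname(stats::quantile(e, 0.9, type = 7))
  }))
  expect_equal(cal$ci, unname(stats::quantile(boot, c(0.025, 0.975), type = 7)),
               tolerance = 1e-12)
  expect_equal(cal$bias_gb, max(0, cal$ci[2]))

  # the mean-absolute-error variant against its own oracle
  calm <- calibrate_bias(model, hold, method = "mean_abs_error", seed = 31)
  bootm <- withr::with_seed(31, replicate(1000, mean(abs(sample(errors, replace = TRUE)))))
  expect_equal(calm$ci, unname(stats::quantile(bootm, c(0.025, 0.975), type = 7)),
               tolerance = 1e-12)

  # perfect predictions give zero bias: a regressor whose single feature is
  # the holdout response itself predicts it exactly
  exact <- fit_family("linear", cbind(z = hold$observed_peak_ram_gb),
                      hold$observed_peak_ram_gb)
  hold_z <- hold; hold_z$z <- hold$observed_peak_ram_gb
  expect_equal(calibrate_bias(exact, hold_z, seed = 1)$bias_gb, 0, tolerance = 1e-8)

  # holdout must be disjoint from training rows
  expect_error(calibrate_bias(model, train[1:10, ], seed = 1), "overlaps")
  expect_error(calibrate_bias(model, hold[1:5, ], seed = 1), ">= 10")
})

test_that("final model fits deterministically and degenerates gracefully", {
  # noise-free single-feature response: near-zero holdout error and bias
  tab <- withr::with_seed(13, {
    x <- runif(80, 1, 50)
    training_table(data.frame(dataset_id = sprintf("d%03d", 1:80), x = x,
                              observed_peak_ram_gb = 2 + 1.5 * x), "default")
  })
  b <- fit_final_model(tab, "linear", features = "x", seed = 5)
  expect_lt(b$metadata$holdout_mae_gb, 1e-8)
  expect_lt(b$bias_gb, 1e-8)

  syn <- synth_training_table(100, seed = 14)
  feats <- c("distinct_kmers_21", "distinct_kmers_71")
  b1 <- fit_final_model(syn$table, "extra_trees", features = feats, seed = 14)
  b2 <- fit_final_model(syn$table, "extra_trees", features = feats, seed = 14)
  nd <- syn$table[1:20, ]
  expect_identical(predict(b1, nd), predict(b2, nd))
  expect_identical(b1$bias_gb, b2$bias_gb)

  expect_error(fit_final_model(syn$table, "extra_trees", features = "nope", seed = 1),
               "unknown feature")
  expect_error(predict(b1, nd[, "distinct_kmers_21", drop = FALSE]),
               "distinct_kmers_71")
})

test_that("bundles survive a save/load round trip and reject corrupt files", {
  syn <- synth_training_table(60, seed = 2)
  nd <- syn$table[1:10, ]
  for (family in c("extra_trees", "random_forest", "linear", "voting")) {
    b <- fit_final_model(syn$table, family,
                         features = c("distinct_kmers_21", "distinct_kmers_71"),
                         params = list(n_estimators = 30L), seed = 2)
    f <- withr::local_tempfile(fileext = ".json")
    save_bundle(b, f)
    b2 <- load_bundle(f)
    expect_identical(predict(b, nd), predict(b2, nd))
    expect_identical(predict(b, nd, add_bias = TRUE), predict(b2, nd, add_bias = TRUE))
    expect_identical(b2$bias_gb, b$bias_gb)
  }

  f <- withr::local_tempfile(lines = "this is not json {")
  expect_error(load_bundle(f), "not a valid model bundle")
  f2 <- withr::local_tempfile(lines = '{"format_version": 99}')
  expect_error(load_bundle(f2), "format version")
})

test_that("more training data does not hurt cross-validated accuracy", {
  big <- synth_training_table(300, seed = 17)$table
  small <- synth_training_table(50, seed = 17)$table
  feats <- c("dataset_id", "distinct_kmers_21", "distinct_kmers_71", "observed_peak_ram_gb")
  rep_big <- crossvalidate_families(training_table(big[, feats], "default"),
                                    "extra_trees", seed = 17)
  rep_small <- crossvalidate_families(training_table(small[, feats], "default"),
                                      "extra_trees", seed = 17)
  expect_lte(rep_big$mean_rmse_gb, rep_small$mean_rmse_gb)
})
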