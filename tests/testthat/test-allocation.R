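test_that("flavor catalogs validate and order their tiers", {
  cat4 <- default_flavor_catalog()
  expect_equal(cat4$ram_gb, c(14, 29, 58, 113))
  expect_error(flavor_catalog(numeric()), "empty")
  expect_error(flavor_catalog(c(14, 14)), "distinct")
  expect_error(flavor_catalog(c(-1, 5)), "> 0")
  expect_error(flavor_catalog(c(14, 29), name = c("a", "a")), "unique")
  # unsorted input is ordered
  expect_equal(flavor_catalog(c(58, 14, 29))$ram_gb, c(14, 29, 58))
})

test_that("flavor catalogs load from YAML config", {
  f <- withr::local_tempfile(lines = c(
    "flavors:",
    "  - name: small", "    ram_gb: 14",
    "  - name: medium", "    ram_gb: 29"))
  cat2 <- read_flavor_catalog(f)
  expect_equal(cat2$ram_gb, c(14, 29))
  expect_equal(cat2$name, c("small", "medium"))
})

test_that("select_flavor picks the smallest sufficient tier", {
  cat4 <- default_flavor_catalog()
  expect_equal(select_flavor(cat4, 20)$ram_gb, 29)
  expect_equal(select_flavor(cat4, 14)$ram_gb, 14)  # boundary inclusive
  expect_equal(select_flavor(cat4, 0)$ram_gb, 14)
  expect_error(select_flavor(cat4, 120), "exceeds")
})

test_that("escalation walks the catalog exactly once and then exhausts", {
  cat4 <- default_flavor_catalog()
  expect_equal(escalate(cat4, 29)$ram_gb, 58)
  expect_error(escalate(cat4, 113), "exhausted")
  expect_error(escalate(cat4, 99), "unknown flavor")
  # the chain from the smallest flavor visits every tier exactly once
  chain <- cat4$ram_gb[1]
  current <- cat4$ram_gb[1]
  repeat {
    nxt <- tryCatch(escalate(cat4, current)$ram_gb, error = function(e) NULL)
    if (is.null(nxt)) break
    chain <- c(chain, nxt); current <- nxt
  }
  expect_equal(chain, cat4$ram_gb)
})

test_that("predict_required_ram is point prediction plus bias", {
  syn <- synth_training_table(80, seed = 6)
  feats <- c("distinct_kmers_21", "distinct_kmers_71")
  bundle <- fit_final_model(syn$table, "extra_trees", features = feats, seed = 6)
  nd <- syn$table[1:20, ]
  expect_equal(predict_required_ram(bundle, nd),
               pmax(0, predict(bundle, nd)) + bundle$bias_gb)
  # forced by the formula: prediction 24, bias 5 -> 29 (and bias 0 -> p)
  tab <- training_table(data.frame(dataset_id = sprintf("d%02d", 1:40),
                                   x = seq(1, 40), observed_peak_ram_gb = seq(1, 40)),
                        "default")
  ident <- fit_final_model(tab, "linear", features = "x", seed = 1)
  expect_equal(ident$bias_gb, 0, tolerance = 1e-8)
  expect_equal(predict_required_ram(ident, c(x = 24)), 24, tolerance = 1e-8)
  ident$bias_gb <- 5
  expect_equal(predict_required_ram(ident, c(x = 24)), 29, tolerance = 1e-8)

  expect_error(predict_required_ram(bundle, nd[, "distinct_kmers_21", drop = FALSE]),
               "distinct_kmers_71")
})

test_that("fleet simulation reproduces hand-enumerated attempt logs", {
  cat2 <- flavor_catalog(c(14, 29))
  peaks <- c(A = 10, B = 20)

  fixed <- simulate_fleet(peaks, policy_fixed(14), cat2)
  expect_equal(fixed$per_dataset$cost_gb, c(14, 14 + 29))
  expect_equal(fixed$total_cost_gb, 57)
  expect_equal(fixed$per_dataset$n_attempts, c(1L, 2L))

  opt <- simulate_fleet(peaks, policy_optimum(), cat2)
  expect_equal(opt$total_cost_gb, 43)
  expect_true(all(opt$per_dataset$n_attempts == 1L))

  # all peaks below the smallest flavor: fixed(smallest) equals optimum
  low <- c(a = 5, b = 9, c = 2)
  expect_equal(simulate_fleet(low, policy_fixed(14), cat2)$total_cost_gb,
               simulate_fleet(low, policy_optimum(), cat2)$total_cost_gb)

  # datasets above the largest flavor are exhausted and excluded from totals
  over <- simulate_fleet(c(A = 10, Z = 1000), policy_fixed(14), cat2)
  expect_equal(over$n_exhausted, 1L)
  expect_equal(over$total_cost_gb, 14)
  expect_equal(over$per_dataset$outcome, c("success", "exhausted"))

  expect_error(simulate_fleet(numeric(), policy_optimum(), cat2), "empty fleet")
  expect_error(simulate_fleet(c(A = -1), policy_optimum(), cat2), "> 0")
  expect_error(simulate_fleet(peaks, policy_predicted(c(A = 10)), cat2),
               "no prediction for dataset 'B'")
})

test_that("perfect predictions with zero bias reproduce the optimum policy", {
  withr::with_seed(44, {
    for (i in 1:20) {
      peaks <- stats::setNames(runif(30, 2, 120), sprintf("d%02d", 1:30))
      opt <- simulate_fleet(peaks, policy_optimum())
      pred <- simulate_fleet(peaks, policy_predicted(peaks))
      expect_identical(pred$per_dataset$cost_gb, opt$per_dataset$cost_gb)
      expect_identical(pred$total_cost_gb, opt$total_cost_gb)
    }
  })
})

test_that("optimum dominates every policy and all datasets terminate", {
  catalog <- default_flavor_catalog()
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(5:40, 1)
      peaks <- stats::setNames(runif(n, 1, 150), sprintf("d%03d", 1:n))
      noisy_pred <- pmax(0.1, peaks + rnorm(n, 0, 15))
      names(noisy_pred) <- names(peaks)
      cmp <- compare_policies(peaks, predictions = noisy_pred, catalog = catalog)
      totals <- cmp$summary$total_cost_gb
      opt_total <- cmp$summary$total_cost_gb[cmp$summary$policy == "Optimum"]
      expect_true(all(totals >= opt_total - 1e-9))
      for (sim in cmp$simulations) {
        expect_true(all(sim$per_dataset$n_attempts <= nrow(catalog)))
        expect_true(all(sim$per_dataset$outcome %in% c("success", "exhausted")))
      }
      # per-dataset monotone cost in the start flavor once the start covers
      # the optimum tier
      sims <- cmp$simulations[paste("Selected", catalog$ram_gb)]
      opt_start <- vapply(names(peaks), function(id) {
        i <- which(catalog$ram_gb >= peaks[[id]])[1]
        if (is.na(i)) nrow(catalog) else i
      }, 0L)
      costs <- vapply(sims, function(s) s$per_dataset$cost_gb, numeric(n))
      for (d in seq_len(n)) {
        above <- which(seq_len(nrow(catalog)) >= opt_start[d])
        expect_true(all(diff(costs[d, above]) >= 0))
      }
    }
  })
})

test_that("policy comparison reports savings relative to the predicted mode", {
  peaks <- c(A = 10, B = 20)
  cmp <- compare_policies(peaks, predictions = peaks, catalog = flavor_catalog(c(14, 29)),
                          fixed_starts = c(14, 29))
  s <- cmp$summary
  expect_equal(s$savings_gb[s$policy == "Predicted"], 0)
  expect_equal(s$total_cost_gb[s$policy == "Predicted"],
               s$total_cost_gb[s$policy == "Optimum"])
  expect_equal(s$savings_gb[s$policy == "Selected 14"], 57 - 43)
  expect_error(compare_policies(numeric()), "empty fleet")

  # single dataset, single sufficient flavor: all policies equal
  one <- compare_policies(c(A = 5), predictions = c(A = 5),
                          catalog = flavor_catalog(10), fixed_starts = 10)
  expect_true(all(one$summary$total_cost_gb == 10))
})
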