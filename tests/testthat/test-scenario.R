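test_that("scenario rules rewrite exactly the target column", {
  p <- generate_panel(synthetic_config(n_dmus = 6, n_periods = 2, seed = 9))

  best <- apply_scenario(p, scenario_spec("Q4", "best", "eps"))
  expect_true(all(best$values[, , "Q4"] == 1e-6))
  worst <- apply_scenario(p, scenario_spec("Q4", "worst", "E7"))
  expect_identical(worst$values[, , "Q4"], p$values[, , "E7"])

  for (v in setdiff(p$variable_ids, "Q4")) {
    expect_identical(best$values[, , v], p$values[, , v])
    expect_identical(worst$values[, , v], p$values[, , v])
  }

  capped <- apply_scenario(p, scenario_spec("A3", "worst",
                                            list(max_of = "A3", factor = 2)))
  expect_true(all(capped$values[, , "A3"] == 2 * max(p$values[, , "A3"])))
})

test_that("scenario application is idempotent", {
  p <- generate_panel(synthetic_config(n_dmus = 5, n_periods = 1, seed = 10))
  sc <- scenario_spec("Q5", "best", "eps")
  once <- apply_scenario(p, sc)
  twice <- apply_scenario(once, sc)
  expect_identical(twice$values, once$values)
})

test_that("degenerate rules raise errors", {
  p <- generate_panel(synthetic_config(n_dmus = 5, n_periods = 1, seed = 11))
  expect_error(apply_scenario(p, scenario_spec("Q4", "worst", "nope")),
               "not in panel")
  zero <- p
  zero$values[, , "E7"] <- 0
  expect_error(apply_scenario(zero, scenario_spec("Q4", "worst", "E7")),
               "all-zero")
  expect_error(scenario_spec("Q4", "worst", 42), "rule must be")
})

test_that("a no-op scenario yields unit ratios and zero impacts", {
  p <- generate_panel(synthetic_config(n_dmus = 6, n_periods = 1, seed = 12))
  noop <- scenario_spec("Q4", "worst", "Q4")   # replace the column by itself
  res <- impact_analysis(p, model = "B", scenarios = list(noop), rts = "vrs")
  expect_equal(unname(res$impacts[[1]]$per_dmu_ratio),
               rep(1, 6), tolerance = 1e-9)
  expect_equal(res$impacts[[1]]$max_impact, 0, tolerance = 1e-9)
  expect_equal(res$impacts[[1]]$mean_impact, 0, tolerance = 1e-9)
})

test_that("best-casing an already-floored column changes nothing", {
  cfg <- synthetic_config(n_dmus = 6, n_periods = 1,
                          event_rates = c(Q4 = 0), seed = 13)
  p <- generate_panel(cfg)
  expect_true(all(p$values[, , "Q4"] == 1e-6))
  res <- impact_analysis(p, model = "B",
                         scenarios = list(scenario_spec("Q4", "best", "eps")),
                         rts = "vrs")
  expect_equal(unname(res$impacts[[1]]$per_dmu_ratio), rep(1, 6),
               tolerance = 1e-9)
})

test_that("impact summaries follow from the per-DMU ratios", {
  p <- generate_panel(synthetic_config(n_dmus = 8, n_periods = 1, seed = 14))
  res <- impact_analysis(p, model = "B",
                         scenarios = list(scenario_spec("Q4", "worst", "E7")),
                         rts = "vrs")
  imp <- res$impacts[[1]]
  expect_true(all(imp$per_dmu_ratio > 0))
  expect_equal(imp$max_impact, max(imp$per_dmu_ratio - 1), tolerance = 1e-12)
  expect_equal(imp$mean_impact, mean(imp$per_dmu_ratio - 1), tolerance = 1e-12)
  grp <- tapply(abs(imp$per_dmu_ratio - 1), p$groups[names(imp$per_dmu_ratio)],
                mean)
  expect_equal(imp$group_mean_abs[names(grp)], grp, tolerance = 1e-12)
  # the summary table carries the same numbers
  expect_equal(res$summary$max_impact, imp$max_impact, tolerance = 1e-12)
})

test_that("group aggregation is invariant to relabeling within groups", {
  p <- generate_panel(synthetic_config(n_dmus = 6, n_periods = 1, seed = 15))
  res <- impact_analysis(p, model = "B",
                         scenarios = list(scenario_spec("A2", "worst", "E8")),
                         rts = "vrs")
  # permute DMU ids within each group: group means must not move
  imp <- res$impacts[[1]]
  ratios <- imp$per_dmu_ratio
  g <- p$groups[names(ratios)]
  permuted <- unlist(lapply(split(ratios, g),
                            function(x) x[sample.int(length(x))]))
  expect_equal(sort(unname(tapply(abs(permuted - 1),
                                  sort(g), mean))),
               sort(unname(imp$group_mean_abs)), tolerance = 1e-12)
})

test_that("the default rule table covers every quality and access variable", {
  rules <- default_scenario_rules()
  expect_length(rules, 20)
  tab <- table(vapply(rules, `[[`, "", "variable_id"))
  expect_setequal(names(tab), c(paste0("Q", 1:7), paste0("A", 1:3)))
  expect_true(all(tab == 2))
})
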