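test_that("pearson_matrix reproduces closed-form correlations", {
  vals <- array(c(1, 2, 3, 2, 4, 6, 3, 2, 1, 1, 2, 4), c(3, 1, 4))
  p <- tiny_panel(vals, c("x", "dbl", "neg", "y"))
  r <- pearson_matrix(p)
  expect_equal(r["x", "dbl"], 1)
  expect_equal(r["x", "neg"], -1)
  # x = (1,2,3), y = (1,2,4): r = sqrt(27/28)
  expect_equal(r["x", "y"], sqrt(27 / 28), tolerance = 1e-12)
  expect_identical(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
})

test_that("correlation is invariant to positive affine rescaling", {
  p <- generate_panel(synthetic_config(n_dmus = 10, n_periods = 2, seed = 5))
  r0 <- pearson_matrix(p, c("E1", "E7", "Q1"))
  p2 <- p
  p2$values[, , "E1"] <- 3.7 * p$values[, , "E1"] + 11
  r1 <- pearson_matrix(p2, c("E1", "E7", "Q1"))
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("zero-variance columns are reported missing and never cluster", {
  vals <- array(c(1, 2, 3, 5, 5, 5, 2, 4, 6), c(3, 1, 3))
  p <- tiny_panel(vals, c("x1", "flat", "x2"))
  r <- pearson_matrix(p)
  expect_true(is.na(r["flat", "flat"]))
  sp <- single_div_spec(c("x1", "flat", "x2"), character())
  cl <- find_clusters(r, sp, threshold = 0.95)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$variables, c("x1", "x2"))
})

test_that("clusters form within one (division, role) context only", {
  set.seed(8)
  base <- runif(40, 1, 10)
  vals <- array(c(base, base * 1.01 + rnorm(40, 0, 0.01),
                  base * 2.02 + rnorm(40, 0, 0.02), runif(40, 1, 10)),
                c(40, 1, 4))
  p <- tiny_panel(vals, c("a", "b", "c", "noise"))
  r <- pearson_matrix(p)
  expect_true(all(r[c("a", "b", "c"), c("a", "b", "c")] > 0.99))

  # all three share the input role: one 3-member cluster
  sp_same <- single_div_spec(c("a", "b", "c"), "noise")
  cl <- find_clusters(r, sp_same, threshold = 0.95)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$variables, c("a", "b", "c"))
  expect_identical(cl[[1]]$role, "input")
  expect_true(all(cl[[1]]$pairwise_r$r >= 0.95))

  # same correlation but different roles: no cluster
  sp_diff <- network_spec("k1", inputs = list(k1 = "a"),
                          desirable_outputs = list(k1 = c("b", "noise")),
                          undesirable_outputs = list(k1 = "c"))
  expect_length(find_clusters(r, sp_diff, threshold = 0.95), 0)

  # weakly correlated variables never cluster
  sp_noise <- single_div_spec(c("a", "noise"), character())
  expect_length(find_clusters(r, sp_noise, threshold = 0.95), 0)
})

test_that("clustering is threshold-monotone", {
  p <- generate_panel(synthetic_config(n_dmus = 25, n_periods = 2, seed = 6))
  r <- pearson_matrix(p)
  sp <- model_spec("A")
  sizes <- vapply(c(0.8, 0.9, 0.95, 0.999),
                  function(th) sum(lengths(lapply(find_clusters(r, sp, th),
                                                  `[[`, "variables"))),
                  0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("merging sums cellwise, conserves totals, and refuses collisions", {
  p <- generate_panel(synthetic_config(n_dmus = 6, n_periods = 2, seed = 7))
  merged <- merge_variables(p, c("E2", "E3"), "clinical_staff")
  expect_true("clinical_staff" %in% merged$variable_ids)
  expect_false(any(c("E2", "E3") %in% merged$variable_ids))
  expect_equal(merged$values[, , "clinical_staff"],
               p$values[, , "E2"] + p$values[, , "E3"], tolerance = 0)
  # untouched columns are bit-identical, original panel unchanged
  expect_identical(merged$values[, , "E1"], p$values[, , "E1"])
  expect_true(all(c("E2", "E3") %in% p$variable_ids))
  expect_error(merge_variables(p, c("E2", "E3"), "E4"), "already exists")
  # singleton merge is a rename
  ren <- merge_variables(p, "E2", "doctors")
  expect_equal(ren$values[, , "doctors"], p$values[, , "E2"], tolerance = 0)
})
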