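test_that("a lone DMU benchmarks itself: scores 1, zero slacks", {
  p <- tiny_panel(matrix(c(3, 6), 1), c("x", "v"))
  res <- solve_dmu(bind_divisions(p, single_div_spec("x", "v"), "1"), "d1")
  expect_identical(res$overall, 1)
  sol <- res$divisional$k1
  expect_identical(sol$score, 1)
  expect_equal(unname(sol$input_slacks), 0)
  expect_equal(sol$phi, 1)
  expect_equal(sol$mu, 0)
})

test_that("hand fixtures: dominated DMU scores 0.5 on either orientation", {
  # input side: DMU2 (x=2, v=2) against DMU1 (x=1, v=2) -> slack 1, 1 - 1/2
  p_in <- tiny_panel(matrix(c(1, 2, 2, 2), 2), c("x", "v"))
  s_in <- solve_division(bind_divisions(p_in, single_div_spec("x", "v"), "1"),
                         "d2", "k1")
  expect_equal(s_in$score, 0.5, tolerance = 1e-3)
  expect_equal(unname(s_in$input_slacks), 1, tolerance = 1e-6)
  # output side: B (x=1, v=2) against A (x=1, v=4) -> shortfall 2, 1/(1+1)
  p_out <- tiny_panel(matrix(c(1, 1, 4, 2), 2), c("x", "v"))
  sp_out <- single_div_spec("x", "v", orientation = "output")
  s_out <- solve_division(bind_divisions(p_out, sp_out, "1"), "d2", "k1")
  expect_equal(s_out$score, 0.5, tolerance = 1e-3)
  expect_equal(unname(s_out$output_slacks), 2, tolerance = 1e-6)
  # both agree with the exhaustive grid oracle
  expect_equal(s_in$score,
               sbm_grid_oracle(matrix(c(1, 2), 2), matrix(c(2, 2), 2), 2),
               tolerance = 1e-3)
  expect_equal(s_out$score,
               sbm_grid_oracle(matrix(c(1, 1), 2), matrix(c(4, 2), 2), 2,
                               orientation = "output"),
               tolerance = 1e-3)
})

test_that("overall score is the weighted mean of divisional scores", {
  p <- rand_multi_panel(11)
  b <- bind_divisions(p, two_div_spec(), "1")
  for (d in p$dmu_ids[1:3]) {
    res <- solve_dmu(b, d)
    expect_equal(res$overall,
                 mean(vapply(res$divisional, `[[`, 0, "score")),
                 tolerance = 1e-12)
  }
  # explicit weights
  res_w <- solve_dmu(b, "d1", weights = c(3, 1))
  sc <- vapply(res_w$divisional, `[[`, 0, "score")
  expect_equal(res_w$overall, sum(c(0.75, 0.25) * sc), tolerance = 1e-12)
  # K = 1: overall is the single divisional score
  p1 <- tiny_panel(matrix(c(1, 2, 2, 2), 2), c("x", "v"))
  r1 <- solve_dmu(bind_divisions(p1, single_div_spec("x", "v"), "1"), "d2")
  expect_identical(r1$overall, r1$divisional$k1$score)
})

test_that("division solutions respect the abatement decomposition", {
  p <- rand_multi_panel(21)
  b <- bind_divisions(p, two_div_spec(), "1")
  for (d in c("d1", "d4")) {
    res <- solve_dmu(b, d)
    for (sol in res$divisional) {
      expect_true(sol$score > 0 && sol$score <= 1 + 1e-9)
      expect_true(all(sol$mu >= -1e-9))
      expect_true(all(sol$phi >= -1e-9))
      expect_true(all(sol$input_slacks >= -1e-9))
      expect_true(all(sol$output_slacks >= -1e-9))
      defined <- !is.na(sol$theta)
      expect_true(all(sol$theta[defined] >= -1e-9 & sol$theta[defined] <= 1 + 1e-9))
      expect_equal(sol$lambda, sol$mu + sol$phi, tolerance = 1e-12)
    }
  }
})

test_that("cross-period averaging matches recomputation from period scores", {
  # identical periods: average equals the single-period score
  one <- generate_panel(synthetic_config(n_dmus = 5, n_periods = 1, seed = 2))
  dup_vals <- array(NA_real_, c(5, 2, length(one$variable_ids)))
  dup_vals[, 1, ] <- one$values[, 1, ]
  dup_vals[, 2, ] <- one$values[, 1, ]
  dup <- dea_panel(dup_vals, one$dmu_ids, c("1", "2"), one$variable_ids,
                   one$groups)
  f_one <- netdea(one, "B", rts = "vrs")
  f_dup <- netdea(dup, "B", rts = "vrs")
  expect_equal(fitted(f_dup), fitted(f_one), tolerance = 1e-9)

  # two distinct periods: summary mean equals the mean of period overalls
  p2 <- generate_panel(synthetic_config(n_dmus = 5, n_periods = 2, seed = 4))
  fit <- netdea(p2, "B", rts = "vrs")
  manual <- tapply(fit$overall$overall, fit$overall$dmu, mean)[fit$dmu_ids]
  expect_equal(fitted(fit), stats::setNames(as.numeric(manual), fit$dmu_ids),
               tolerance = 1e-12)
})

test_that("scale efficiency is the CRS/VRS ratio and lies in (0, 1]", {
  p <- rand_multi_panel(31)
  vrs <- netdea(p, two_div_spec(), rts = "vrs")
  crs <- netdea(p, two_div_spec(), rts = "crs")
  se <- scale_efficiency(vrs, crs)
  expect_equal(se$scale_efficiency, se$crs / se$vrs, tolerance = 1e-12)
  expect_true(all(se$scale_efficiency > 0 &
                    se$scale_efficiency <= 1 + 1e-6))
  expect_error(scale_efficiency(crs, vrs), "VRS fit and a CRS fit")
})

test_that("frontier classification includes the boundary", {
  p <- rand_multi_panel(41)
  fit <- netdea(p, two_div_spec(), rts = "vrs")
  # synthetic score table exercising the threshold arithmetic
  fit$summary$overall <- c(1, 0.5, 1 - fit$tol / 2, 1 - 2 * fit$tol,
                           rep(0.9, 2))
  expect_identical(frontier(fit), c("d1", "d3"))
  fit$summary$overall <- rep(1, 6)
  expect_identical(frontier(fit), p$dmu_ids)
})

test_that("unit invariance: rescaling any column leaves scores unchanged", {
  p <- rand_multi_panel(51)
  f0 <- fitted(netdea(p, two_div_spec(), rts = "vrs"))
  set.seed(99)
  scl <- runif(length(p$variable_ids), 0.01, 100)
  p2 <- p
  for (j in seq_along(p$variable_ids)) p2$values[, , j] <- p$values[, , j] * scl[j]
  f1 <- fitted(netdea(p2, two_div_spec(), rts = "vrs"))
  expect_equal(f1, f0, tolerance = 1e-6)
})

test_that("dropping undesirable outputs reduces to the plain slack measure", {
  # with no undesirable outputs the weak-disposability split is inert and
  # the optimum matches the closed-form oracle of the standard measure
  for (s in c(3, 17)) {
    inst <- rand_single_instance(s)
    expect_equal(lp_single_score(inst),
                 sbm_grid_oracle(inst$X, inst$V, inst$o, inst$orientation),
                 tolerance = 1e-3)
  }
})

test_that("a division with no inputs under input orientation scores 1", {
  p <- tiny_panel(matrix(c(1, 2, 3, 4), 2), c("v", "u"))
  sp <- network_spec("k1", desirable_outputs = list(k1 = "v"),
                     undesirable_outputs = list(k1 = "u"),
                     orientation = c(k1 = "input"))
  b <- bind_divisions(p, sp, "1")
  expect_warning(s <- solve_division(b, "d1", "k1"), "score defined as 1")
  expect_identical(s$score, 1)
})

test_that("free links enlarge the benchmark set, so scores cannot rise", {
  for (s in c(7, 13, 29)) {
    p <- rand_multi_panel(s)
    fixed <- fitted(netdea(p, two_div_spec(), rts = "vrs"))
    free <- fitted(netdea(p, two_div_spec(), rts = "vrs", free_links = TRUE))
    expect_true(all(free <= fixed + 1e-6))
  }
})

test_that("weak-disposability optimum matches a joint (phi, mu) grid search", {
  # n = 2, one input, one desirable and one undesirable output, VRS.
  # u_o = U phi fixes phi to a segment; grid phi1 and the split of the
  # remaining intensity mass into mu, with slacks in closed form.
  set.seed(5)
  for (rep in 1:3) {
    X <- matrix(runif(2, 0.5, 2), 2)
    V <- matrix(runif(2, 0.5, 2), 2)
    U <- matrix(runif(2, 0.5, 2), 2)
    o <- sample(2, 1)
    h <- 1e-3
    phi1 <- seq(0, min(1, U[o, 1] / U[1, 1]), by = h)
    phi2 <- (U[o, 1] - U[1, 1] * phi1) / U[2, 1]
    ok <- phi2 >= 0 & phi1 + phi2 <= 1
    phi1 <- phi1[ok]; phi2 <- phi2[ok]
    best <- -Inf
    frac <- seq(0, 1, by = h)
    for (i in seq_along(phi1)) {
      M <- 1 - phi1[i] - phi2[i]
      mu1 <- frac * M; mu2 <- M - mu1
      l1 <- mu1 + phi1[i]; l2 <- mu2 + phi2[i]
      sm <- X[o, 1] - (X[1, 1] * l1 + X[2, 1] * l2)
      sp <- V[1, 1] * phi1[i] + V[2, 1] * phi2[i] - V[o, 1]
      feas <- sm >= -1e-12 & sp >= -1e-12
      if (any(feas)) best <- max(best, max(sm[feas]) / X[o, 1])
    }
    grid_score <- 1 - best
    p <- tiny_panel(cbind(X, V, U), c("x", "v", "u"))
    sp_ <- single_div_spec("x", "v", undesirable = "u")
    lp <- solve_division(bind_divisions(p, sp_, "1"), o, "k1")$score
    expect_equal(lp, grid_score, tolerance = 2e-3)
  }
})
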