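# Shared fixtures: tiny panels, random instances, and the brute-force
# simplex-grid oracle used to cross-check the LP solver.

# panel from an n x v matrix (one period) or n x v x p array
tiny_panel <- function(values, vars, dmu_ids = NULL, periods = NULL,
                       groups = "G") {
  if (length(dim(values)) == 2L)
    values <- array(values, c(nrow(values), 1L, ncol(values)))
  n <- dim(values)[1]
  if (is.null(dmu_ids)) dmu_ids <- paste0("d", seq_len(n))
  if (is.null(periods)) periods <- as.character(seq_len(dim(values)[2]))
  if (length(groups) == 1L) groups <- stats::setNames(rep(groups, n), dmu_ids)
  dea_panel(aperm(values, c(1L, 2L, 3L)), dmu_ids, periods, vars, groups)
}

single_div_spec <- function(inputs, outputs, undesirable = character(),
                            orientation = "input") {
  network_spec("k1", inputs = list(k1 = inputs),
               desirable_outputs = list(k1 = outputs),
               undesirable_outputs =
                 if (length(undesirable)) list(k1 = undesirable) else list(),
               orientation = c(k1 = orientation))
}

# two linked divisions with an undesirable output in the second
two_div_spec <- function() {
  network_spec(c("k1", "k2"),
               inputs = list(k1 = c("x1", "x2")),
               desirable_outputs = list(k1 = "v1", k2 = "v2"),
               undesirable_outputs = list(k2 = "u1"),
               links = data.frame(from = "k1", to = "k2", variable = "z1"))
}

rand_multi_panel <- function(seed, n = 6) {
  set.seed(seed)
  vars <- c("x1", "x2", "z1", "v1", "u1", "v2")
  arr <- array(stats::runif(n * length(vars), 0.5, 2), c(n, 1L, length(vars)))
  tiny_panel(arr, vars)
}

# random single-division instance without undesirable outputs (the regime
# in which slacks are closed-form given the intensity vector)
rand_single_instance <- function(seed) {
  set.seed(seed)
  n <- sample(2:3, 1)
  m <- sample(1:2, 1)
  r <- sample(1:2, 1)
  list(X = matrix(stats::runif(n * m, 0.5, 2), n),
       V = matrix(stats::runif(n * r, 0.5, 2), n),
       orientation = sample(c("input", "output"), 1),
       o = sample(n, 1))
}

# exhaustive grid over the VRS intensity simplex; slacks in closed form
sbm_grid_oracle <- function(X, V, o, orientation = "input", resolution = 1e-3) {
  n <- nrow(X)
  lam <- if (n == 1L) matrix(1, 1, 1) else if (n == 2L) {
    t1 <- seq(0, 1, by = resolution)
    rbind(t1, 1 - t1)
  } else {
    t1 <- seq(0, 1, by = resolution)
    g <- expand.grid(l1 = t1, l2 = t1)
    g <- g[g$l1 + g$l2 <= 1 + 1e-12, ]
    rbind(g$l1, g$l2, pmax(1 - g$l1 - g$l2, 0))
  }
  sm <- X[o, ] - t(X) %*% lam
  sp <- t(V) %*% lam - V[o, ]
  feas <- colSums(sm < -1e-12) == 0 & colSums(sp < -1e-12) == 0
  if (orientation == "input") {
    1 - max(colMeans(sm[, feas, drop = FALSE] / X[o, ]))
  } else {
    1 / (1 + max(colMeans(sp[, feas, drop = FALSE] / V[o, ])))
  }
}

# LP score for a rand_single_instance via the package surface
lp_single_score <- function(inst, rts = "vrs") {
  xs <- paste0("x", seq_len(ncol(inst$X)))
  vs <- paste0("v", seq_len(ncol(inst$V)))
  p <- tiny_panel(cbind(inst$X, inst$V), c(xs, vs))
  sp <- single_div_spec(xs, vs, orientation = inst$orientation)
  solve_division(bind_divisions(p, sp, "1"), inst$o, "k1", rts = rts)$score
}
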