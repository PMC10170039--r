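# Internal dense linear-programming backend.
#
# The frontier programs are small (tens of equality rows, a few hundred
# nonnegative variables) but routinely degenerate: link constraints have a
# zero right-hand side, scenario edits can duplicate whole columns, and the
# self-benchmark is always feasible, so many basic variables sit at zero.
# A classical tableau accumulates roundoff over long degenerate pivot
# sequences, so this is a revised simplex that refactorises the basis from
# the original data at every iteration.  Linearly dependent equality rows
# are dropped up front (and the final solution is checked against them);
# pivoting is Dantzig (most negative reduced cost) with largest-pivot tie
# breaking, falling back to a full Bland's-rule restart if a basis ever
# turns singular, which guarantees termination under degeneracy.

# maximise obj'x  s.t.  A x = b, x >= 0.
# Returns list(status, x, value); status one of "optimal", "infeasible",
# "unbounded", "iterlimit".
lp_solve_max <- function(obj, A, b, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n)
  if (is.null(max_iter)) max_iter <- 200L * (m + n)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  # drop linearly dependent rows; their consistency is verified on the
  # final solution so an inconsistent system still reports infeasible
  dropped_A <- NULL; dropped_b <- NULL
  qrA <- qr(t(A))
  if (qrA$rank < m) {
    keep <- sort(qrA$pivot[seq_len(qrA$rank)])
    drop <- setdiff(seq_len(m), keep)
    dropped_A <- A[drop, , drop = FALSE]; dropped_b <- b[drop]
    A <- A[keep, , drop = FALSE]; b <- b[keep]
    m <- nrow(A)
  }

  sol <- lp_two_phase(obj, A, b, tol, max_iter, bland = FALSE)
  if (sol$status == "singular")
    sol <- lp_two_phase(obj, A, b, tol, max_iter, bland = TRUE)
  if (sol$status == "optimal" && !is.null(dropped_A)) {
    resid <- abs(dropped_A %*% sol$x - dropped_b)
    if (any(resid > 1e-6 * (1 + abs(dropped_b))))
      return(list(status = "infeasible"))
  }
  sol
}

lp_two_phase <- function(obj, A, b, tol, max_iter, bland = FALSE) {
  m <- nrow(A); n <- ncol(A)
  # phase 1: artificial columns, minimise their sum
  A1 <- cbind(A, diag(m), deparse.level = 0)
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- revised_simplex(A1, b, cost1, basis = n + seq_len(m),
                         tol = tol, max_iter = max_iter, bland = bland)
  if (ph1$status != "optimal") return(list(status = ph1$status))
  if (ph1$objective > 1e-7) return(list(status = "infeasible"))
  basis <- ph1$basis

  # drive leftover zero-level artificials out of the basis; a row admitting
  # no replacement column is linearly dependent and is dropped
  repeat {
    art <- which(basis > n)
    if (!length(art)) break
    r <- art[1L]
    Binv_A <- solve(A1[, basis, drop = FALSE], A)
    j <- which(abs(Binv_A[r, ]) > 1e-7 & !(seq_len(n) %in% basis))
    if (length(j)) {
      basis[r] <- j[1L]
    } else {
      A <- A[-r, , drop = FALSE]
      A1 <- A1[-r, , drop = FALSE]
      b <- b[-r]
      basis <- basis[-r]
    }
  }

  ph2 <- revised_simplex(A, b, -obj, basis = basis, tol = tol,
                         max_iter = max_iter, bland = bland)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  x <- numeric(n)
  x[ph2$basis] <- pmax(ph2$x_basic, 0)
  list(status = "optimal", x = x, value = sum(obj * x))
}

# minimise cost'x s.t. A x = b, x >= 0 from a starting basis.
revised_simplex <- function(A, b, cost, basis, tol = 1e-9, max_iter = 10000L,
                            bland = FALSE) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L)
    return(list(status = "optimal", basis = basis, x_basic = numeric(0),
                objective = 0))
  stall <- 0L
  last_obj <- Inf
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    qrB <- qr(B, tol = 1e-12)      # only near-exact singularity is fatal
    if (qrB$rank < m) return(list(status = "singular"))
    xB <- pmax(solve(qrB, b), 0)
    objective <- sum(cost[basis] * xB)
    if (objective < last_obj - tol) { stall <- 0L; last_obj <- objective }
    else stall <- stall + 1L
    if (!bland && stall > 2L * m + 20L) bland <- TRUE
    y <- tryCatch(solve(t(B), cost[basis]),
                  error = function(e) NULL)
    if (is.null(y)) return(list(status = "singular"))
    red <- cost - as.vector(crossprod(A, y))
    red[basis] <- 0
    entering <- which(red < -tol)
    if (!length(entering))
      return(list(status = "optimal", basis = basis, x_basic = xB,
                  objective = objective))
    j <- if (bland) entering[1L] else entering[which.min(red[entering])]
    d <- solve(qrB, A[, j])
    pos <- which(d > 1e-8)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- xB[pos] / d[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
    # among ties prefer the largest pivot element (keeps the basis well
    # conditioned); Bland's smallest-index rule only when anti-cycling
    r <- if (bland) cand[which.min(basis[cand])] else cand[which.max(d[cand])]
    basis[r] <- j
  }
  list(status = "iterlimit")
}
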