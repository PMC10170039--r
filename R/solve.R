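# Build the full coupled constraint system for one evaluated DMU.
#
# Decision variables, in column order:
#   mu^1..mu^K (K blocks of n), phi^1..phi^K (K blocks of n),
#   s^{1-}..s^{K-} (input slacks), s^{1+}..s^{K+} (desirable-output slacks).
# Constraints (all equalities, rhs >= 0):
#   x_o^k  = X^k (mu^k + phi^k) + s^{k-}          for every division k
#   v_o^k  = V^k phi^k - s^{k+}                   for every division k
#   u_o^k  = U^k phi^k                            for every division k
#   Z_l (mu^h + phi^h) = Z_l (mu^k + phi^k)       for every link l: k -> h
#   sum_j (mu_j^k + phi_j^k) = 1                  for every k, under VRS only
# Every variable column is rescaled by its mean (unit invariance makes the
# scores independent of measurement units, so this only conditions the LP).
build_lp <- function(bound, o, rts = c("vrs", "crs"), free_links = FALSE,
                     abatement = TRUE) {
  rts <- match.arg(rts)
  spec <- bound$spec
  K <- length(spec$divisions)
  n <- length(bound$dmu_ids)
  scale_cols <- function(m) {
    if (!ncol(m)) return(m)
    sweep(m, 2L, colMeans(m), "/")
  }
  Xs <- lapply(bound$X, scale_cols)
  Vs <- lapply(bound$V, scale_cols)
  Us <- lapply(bound$U, scale_cols)
  Zs <- lapply(bound$Z, function(z) z / mean(z))
  m_k <- vapply(Xs, ncol, 0L)
  r_k <- vapply(Vs, ncol, 0L)
  w_k <- vapply(Us, ncol, 0L)
  n_links <- if (free_links) 0L else nrow(spec$links)
  n_mu_phi <- 2L * K * n
  n_cols <- n_mu_phi + sum(m_k) + sum(r_k)
  n_rows <- sum(m_k) + sum(r_k) + sum(w_k) + n_links +
    (if (rts == "vrs") K else 0L) + (if (abatement) 0L else K)
  mu_idx <- lapply(seq_len(K), function(k) (k - 1L) * n + seq_len(n))
  phi_idx <- lapply(seq_len(K), function(k) K * n + (k - 1L) * n + seq_len(n))
  sm_off <- n_mu_phi + c(0L, cumsum(m_k))[seq_len(K)]
  sp_off <- n_mu_phi + sum(m_k) + c(0L, cumsum(r_k))[seq_len(K)]
  sm_idx <- lapply(seq_len(K), function(k) sm_off[k] + seq_len(m_k[k]))
  sp_idx <- lapply(seq_len(K), function(k) sp_off[k] + seq_len(r_k[k]))

  A <- matrix(0, n_rows, n_cols)
  b <- numeric(n_rows)
  row <- 0L
  for (k in seq_len(K)) {
    if (m_k[k]) {
      rows <- row + seq_len(m_k[k])
      A[rows, mu_idx[[k]]] <- t(Xs[[k]])
      A[rows, phi_idx[[k]]] <- t(Xs[[k]])
      A[cbind(rows, sm_idx[[k]])] <- 1
      b[rows] <- Xs[[k]][o, ]
      row <- row + m_k[k]
    }
  }
  for (k in seq_len(K)) {
    if (r_k[k]) {
      rows <- row + seq_len(r_k[k])
      A[rows, phi_idx[[k]]] <- t(Vs[[k]])
      A[cbind(rows, sp_idx[[k]])] <- -1
      b[rows] <- Vs[[k]][o, ]
      row <- row + r_k[k]
    }
  }
  for (k in seq_len(K)) {
    if (w_k[k]) {
      rows <- row + seq_len(w_k[k])
      A[rows, phi_idx[[k]]] <- t(Us[[k]])
      b[rows] <- Us[[k]][o, ]
      row <- row + w_k[k]
    }
  }
  if (n_links) {
    div_no <- stats::setNames(seq_len(K), spec$divisions)
    for (l in seq_len(n_links)) {
      row <- row + 1L
      kf <- div_no[[spec$links$from[l]]]
      kt <- div_no[[spec$links$to[l]]]
      A[row, mu_idx[[kt]]] <- Zs[[l]]
      A[row, phi_idx[[kt]]] <- Zs[[l]]
      A[row, mu_idx[[kf]]] <- A[row, mu_idx[[kf]]] - Zs[[l]]
      A[row, phi_idx[[kf]]] <- A[row, phi_idx[[kf]]] - Zs[[l]]
      b[row] <- 0
    }
  }
  if (rts == "vrs") {
    for (k in seq_len(K)) {
      row <- row + 1L
      A[row, c(mu_idx[[k]], phi_idx[[k]])] <- 1
      b[row] <- 1
    }
  }
  if (!abatement) {
    # strong disposability: mu >= 0 plus sum(mu^k) = 0 pins every mu at 0,
    # so theta is identically 1
    for (k in seq_len(K)) {
      row <- row + 1L
      A[row, mu_idx[[k]]] <- 1
      b[row] <- 0
    }
  }
  list(A = A, b = b, o = o, rts = rts, spec = spec, n = n, K = K,
       m_k = m_k, r_k = r_k,
       mu_idx = mu_idx, phi_idx = phi_idx, sm_idx = sm_idx, sp_idx = sp_idx,
       Xs = Xs, Vs = Vs,
       x_scale = lapply(bound$X, colMeans), v_scale = lapply(bound$V, colMeans),
       n_cols = n_cols)
}

solve_lp_for_division <- function(lp, k) {
  spec <- lp$spec
  div <- spec$divisions[k]
  orient <- spec$orientation[[div]]
  if (orient == "input" && lp$m_k[k] == 0L ||
      orient == "output" && lp$r_k[k] == 0L) {
    warning(sprintf(
      "division '%s' has no %s under %s orientation; score defined as 1",
      div, if (orient == "input") "inputs" else "desirable outputs", orient),
      call. = FALSE)
    n <- lp$n
    return(structure(list(
      division = div, score = 1, objective = 0,
      input_slacks = stats::setNames(numeric(lp$m_k[k]), colnames(lp$Xs[[k]])),
      output_slacks = stats::setNames(numeric(lp$r_k[k]), colnames(lp$Vs[[k]])),
      mu = numeric(n), phi = as.numeric(seq_len(n) == lp$o),
      theta = ifelse(seq_len(n) == lp$o, 1, NA_real_),
      lambda = as.numeric(seq_len(n) == lp$o), status = "trivial"),
      class = "division_solution"))
  }
  a <- numeric(lp$n_cols)
  if (orient == "input") {
    a[lp$sm_idx[[k]]] <- 1 / (lp$m_k[k] * lp$Xs[[k]][lp$o, ])
  } else {
    a[lp$sp_idx[[k]]] <- 1 / (lp$r_k[k] * lp$Vs[[k]][lp$o, ])
  }
  sol <- lp_solve_max(a, lp$A, lp$b)
  if (sol$status == "infeasible")
    stop(sprintf("LP infeasible for division '%s' (DMU index %d); %s",
                 div, lp$o,
                 "observed data always admit the self-benchmark, so check for edited inputs"),
         call. = FALSE)
  if (sol$status != "optimal")
    stop(sprintf("LP did not converge for division '%s' (DMU index %d): %s",
                 div, lp$o, sol$status), call. = FALSE)
  x <- sol$x
  objective <- max(0, sol$value)
  if (objective < 1e-9) objective <- 0   # numerically zero: on the frontier
  score <- if (orient == "input") 1 - objective else 1 / (1 + objective)
  mu <- unname(x[lp$mu_idx[[k]]])
  phi <- unname(x[lp$phi_idx[[k]]])
  lambda <- mu + phi
  theta <- ifelse(lambda > 0, phi / lambda, NA_real_)
  # slacks back on the original measurement scale
  s_in <- x[lp$sm_idx[[k]]] * lp$x_scale[[k]]
  s_out <- x[lp$sp_idx[[k]]] * lp$v_scale[[k]]
  structure(list(division = div, score = score, objective = objective,
                 input_slacks = stats::setNames(unname(s_in), colnames(lp$Xs[[k]])),
                 output_slacks = stats::setNames(unname(s_out), colnames(lp$Vs[[k]])),
                 mu = mu, phi = phi, theta = theta, lambda = lambda,
                 status = "optimal"),
            class = "division_solution")
}

#' Solve one division's slack-based efficiency program
#'
#' Solves the linear program for the stated division of the evaluated DMU,
#' carrying the full coupled constraint system of the network (all
#' divisions' balance constraints, link equalities and, under VRS, the
#' convexity constraint per division).  Undesirable outputs are weakly
#' disposable: the intensity vector is split as `lambda = mu + phi`, only
#' `phi` produces outputs, and the implied per-peer abatement factor is
#' `theta = phi / (mu + phi)`.
#'
#' Input-oriented divisions maximise the mean relative input slack and
#' score `1 - optimum`; output-oriented divisions maximise the mean
#' relative shortfall of desirable outputs and score `1 / (1 + optimum)`.
#'
#' @param bound a [bind_divisions()] result.
#' @param dmu DMU id or index.
#' @param division division id or index.
#' @param rts `"vrs"` (convexity constraint active, default) or `"crs"`.
#' @param free_links drop the inter-division link equalities (default
#'   `FALSE`, the fixed-link model).
#' @param abatement allow weak-disposability abatement (default `TRUE`);
#'   `FALSE` forces `mu = 0`, i.e. strong disposability with `theta`
#'   identically 1.
#' @return A `division_solution`: list with `score` in (0, 1], `objective`,
#'   `input_slacks`, `output_slacks`, `mu`, `phi`, `theta`, `lambda`,
#'   `status`.
#' @export
solve_division <- function(bound, dmu, division, rts = c("vrs", "crs"),
                           free_links = FALSE, abatement = TRUE) {
  stopifnot(inherits(bound, "division_data"))
  rts <- match.arg(rts)
  o <- if (is.character(dmu)) match(dmu, bound$dmu_ids) else as.integer(dmu)
  if (is.na(o) || o < 1L || o > length(bound$dmu_ids))
    stop("unknown dmu: ", dmu, call. = FALSE)
  k <- if (is.character(division)) match(division, bound$spec$divisions)
       else as.integer(division)
  if (is.na(k)) stop("unknown division: ", division, call. = FALSE)
  lp <- build_lp(bound, o, rts, free_links, abatement)
  solve_lp_for_division(lp, k)
}

#' Solve every division of one DMU and average
#'
#' Runs [solve_division()] for each division (sharing one constraint
#' system) and aggregates the divisional scores into the overall score as
#' their weighted arithmetic mean (equal weights by default).
#'
#' @inheritParams solve_division
#' @param weights optional nonnegative division weights; normalised to sum
#'   to one.  Default: equal.
#' @return A `dmu_result`: list with `dmu_id`, `rts`, `divisional` (named
#'   list of `division_solution`s) and `overall`.
#' @export
solve_dmu <- function(bound, dmu, rts = c("vrs", "crs"), free_links = FALSE,
                      weights = NULL, abatement = TRUE) {
  stopifnot(inherits(bound, "division_data"))
  rts <- match.arg(rts)
  o <- if (is.character(dmu)) match(dmu, bound$dmu_ids) else as.integer(dmu)
  if (is.na(o) || o < 1L || o > length(bound$dmu_ids))
    stop("unknown dmu: ", dmu, call. = FALSE)
  spec <- bound$spec
  K <- length(spec$divisions)
  w <- if (is.null(weights)) rep(1 / K, K) else {
    if (length(weights) != K || any(weights < 0) || sum(weights) == 0)
      stop("weights must be nonnegative, one per division", call. = FALSE)
    weights / sum(weights)
  }
  lp <- build_lp(bound, o, rts, free_links, abatement)
  divisional <- stats::setNames(vector("list", K), spec$divisions)
  for (k in seq_len(K)) {
    divisional[[k]] <- tryCatch(solve_lp_for_division(lp, k),
      error = function(e) stop(sprintf("[division %s] %s",
                                       spec$divisions[k], conditionMessage(e)),
                               call. = FALSE))
  }
  scores <- vapply(divisional, `[[`, 0, "score")
  structure(list(dmu_id = bound$dmu_ids[o], rts = rts, divisional = divisional,
                 overall = sum(w * scores)),
            class = "dmu_result")
}

#' @export
print.dmu_result <- function(x, ...) {
  cat(sprintf("DMU '%s' (%s): overall %.4f\n", x$dmu_id, toupper(x$rts), x$overall))
  for (d in x$divisional)
    cat(sprintf("  %-14s %.4f\n", d$division, d$score))
  invisible(x)
}

#' Fit a network slack-based efficiency model
#'
#' The main fitting function: evaluates every DMU in every period of the
#' panel against the frontier spanned by all DMUs of the same period, under
#' the given network structure and returns-to-scale regime.  Each period is
#' solved independently; the cross-period summary averages each DMU's
#' overall score over the periods.
#'
#' @param panel a [dea_panel()].
#' @param model a [network_spec()], the name of a shipped model
#'   (`"A"`..`"D"`), or a path to a YAML/JSON model file.
#' @param rts `"vrs"` (default) or `"crs"`.
#' @param periods subset of `panel$periods` to evaluate (default all).
#' @param eps_frac zero-replacement fraction passed to [bind_divisions()].
#' @param free_links drop link equalities (default `FALSE`).
#' @param weights optional division weights for the overall score.
#' @param abatement allow weak-disposability abatement (default `TRUE`);
#'   `FALSE` evaluates the strong-disposability variant.
#' @param tol frontier tolerance used by [frontier()] and `summary()`.
#' @return An object of class `netdea` with components `scores` (long
#'   data.frame: dmu, period, division, score), `overall` (dmu, period,
#'   overall), `summary` (per-DMU cross-period means plus group),
#'   `solutions` (nested list of `dmu_result`s), `spec`, `rts`, `groups`.
#' @examples
#' panel <- generate_panel(synthetic_config(n_dmus = 8, n_periods = 2, seed = 1))
#' fit <- netdea(panel, model = "B", rts = "vrs")
#' print(fit)
#' head(fitted(fit))
#' @export
netdea <- function(panel, model = "A", rts = c("vrs", "crs"),
                   periods = panel$periods, eps_frac = 1e-6,
                   free_links = FALSE, weights = NULL, abatement = TRUE,
                   tol = 1e-6) {
  stopifnot(inherits(panel, "dea_panel"))
  rts <- match.arg(rts)
  spec <- if (inherits(model, "network_spec")) model
          else if (is.character(model) && model %in% c("A", "B", "C", "D"))
            model_spec(model)
          else if (is.character(model)) read_model_spec(model)
          else stop("model must be a network_spec, a shipped model name, or a path",
                    call. = FALSE)
  periods <- as.character(periods)
  if (!all(periods %in% panel$periods))
    stop("unknown period(s): ",
         paste(setdiff(periods, panel$periods), collapse = ", "), call. = FALSE)
  solutions <- stats::setNames(vector("list", length(periods)), periods)
  rows <- list()
  for (p in periods) {
    bound <- bind_divisions(panel, spec, p, eps_frac)
    per <- stats::setNames(vector("list", length(panel$dmu_ids)), panel$dmu_ids)
    for (d in panel$dmu_ids) {
      res <- solve_dmu(bound, d, rts, free_links, weights, abatement)
      per[[d]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        dmu = d, period = p,
        division = spec$divisions,
        score = vapply(res$divisional, `[[`, 0, "score"),
        overall = res$overall, row.names = NULL)
    }
    solutions[[p]] <- per
  }
  scores <- do.call(rbind, rows)
  overall <- unique(scores[, c("dmu", "period", "overall")])
  mean_overall <- tapply(overall$overall, overall$dmu, mean)[panel$dmu_ids]
  div_means <- sapply(spec$divisions, function(k) {
    s <- scores[scores$division == k, ]
    tapply(s$score, s$dmu, mean)[panel$dmu_ids]
  })
  if (is.null(dim(div_means)))
    div_means <- matrix(div_means, nrow = length(panel$dmu_ids),
                        dimnames = list(panel$dmu_ids, spec$divisions))
  summary_df <- data.frame(dmu = panel$dmu_ids,
                           group = unname(panel$groups[panel$dmu_ids]),
                           overall = as.numeric(mean_overall),
                           div_means, check.names = FALSE, row.names = NULL)
  structure(list(call = match.call(), spec = spec, rts = rts,
                 periods = periods, dmu_ids = panel$dmu_ids,
                 groups = panel$groups, scores = scores, overall = overall,
                 summary = summary_df, solutions = solutions, tol = tol),
            class = "netdea")
}

#' @export
print.netdea <- function(x, digits = 4, ...) {
  cat(sprintf("Network SBM efficiency fit (model '%s', %s, %d DMUs, %d period(s))\n",
              x$spec$name, toupper(x$rts), length(x$dmu_ids), length(x$periods)))
  eff <- frontier(x)
  cat(sprintf("Cross-period mean overall score: %.*f (min %.*f); %d DMU(s) on the frontier\n",
              digits, mean(x$summary$overall), digits, min(x$summary$overall),
              length(eff)))
  cat("\nPer-DMU cross-period averages:\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.netdea <- function(object, ...) {
  eff <- frontier(object)
  grp <- tapply(object$summary$overall, object$summary$group, mean)
  out <- list(spec_name = object$spec$name, rts = object$rts,
              n_dmus = length(object$dmu_ids), periods = object$periods,
              mean_overall = mean(object$summary$overall),
              frontier = eff, group_means = grp, table = object$summary)
  class(out) <- "summary.netdea"
  out
}

#' @export
print.summary.netdea <- function(x, digits = 4, ...) {
  cat(sprintf("Network SBM model '%s', %s, %d DMUs, period(s) %s\n",
              x$spec_name, toupper(x$rts), x$n_dmus,
              paste(x$periods, collapse = ", ")))
  cat(sprintf("Mean overall efficiency: %.*f\n", digits, x$mean_overall))
  cat(sprintf("Frontier (%d): %s\n", length(x$frontier),
              paste(x$frontier, collapse = ", ")))
  cat("Group means:\n")
  print(round(x$group_means, digits))
  cat("\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
fitted.netdea <- function(object, ...) {
  stats::setNames(object$summary$overall, object$summary$dmu)
}

#' @export
as.data.frame.netdea <- function(x, ...) x$scores

#' @export
plot.netdea <- function(x, ...) {
  ord <- order(x$summary$overall, decreasing = TRUE)
  graphics::barplot(x$summary$overall[ord], names.arg = x$summary$dmu[ord],
                    las = 2, ylim = c(0, 1.05),
                    ylab = "mean overall efficiency",
                    main = sprintf("Network SBM scores (model '%s', %s)",
                                   x$spec$name, toupper(x$rts)), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Scale efficiency
#'
#' Ratio of the CRS to the VRS overall score per DMU, isolating the share
#' of inefficiency attributable to operating away from the most productive
#' scale.  Values lie in (0, 1] up to solver tolerance.
#'
#' @param vrs,crs two [netdea()] fits of the same panel and model under
#'   `rts = "vrs"` and `rts = "crs"` respectively.
#' @return data.frame with columns `dmu`, `vrs`, `crs`, `scale_efficiency`.
#' @export
scale_efficiency <- function(vrs, crs) {
  stopifnot(inherits(vrs, "netdea"), inherits(crs, "netdea"))
  if (vrs$rts != "vrs" || crs$rts != "crs")
    stop("arguments must be a VRS fit and a CRS fit, in that order", call. = FALSE)
  if (!identical(vrs$dmu_ids, crs$dmu_ids))
    stop("fits evaluate different DMU sets", call. = FALSE)
  data.frame(dmu = vrs$summary$dmu, vrs = vrs$summary$overall,
             crs = crs$summary$overall,
             scale_efficiency = crs$summary$overall / vrs$summary$overall,
             row.names = NULL)
}

#' Efficient DMUs
#'
#' DMUs whose cross-period mean overall score is within `tol` of 1.
#'
#' @param x a [netdea()] fit.
#' @param tol frontier tolerance (default the fit's `tol`, itself 1e-6).
#' @return Character vector of efficient DMU ids.
#' @export
frontier <- function(x, tol = x$tol) {
  stopifnot(inherits(x, "netdea"))
  x$summary$dmu[x$summary$overall >= 1 - tol]
}
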