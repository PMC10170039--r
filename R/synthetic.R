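#' Configuration for the synthetic hospital panel generator
#'
#' Describes a panel of hospital-like DMUs: a latent size per DMU drives
#' capacity (beds E1), labour (doctor/nurse hours E2, E3), costs (E4-E6)
#' and, damped by a per-DMU inefficiency factor, the patient volumes
#' (inpatients E7, outpatient visits E8, surgeries E9).  Quality and
#' access counts are binomial draws at configured rates, bounded by their
#' volume columns (Q1, Q2, Q4, Q5 by E7; Q3, Q6, Q7, A1 by E9; A2 by E8);
#' surgical waiting time A3 is positive days.  All noise is multiplicative
#' lognormal, keeping every value strictly positive.
#'
#' @param n_dmus number of DMUs (default 27).
#' @param n_periods number of periods (default 4).
#' @param group_labels group labels cycled over the DMUs in order of
#'   increasing size (default `"B"`..`"F"`).
#' @param size_spread multiplicative range of hospital scale between the
#'   smallest and largest DMU (default 10).
#' @param noise_cv coefficient of variation of the lognormal noise
#'   (default 0.08).
#' @param event_rates named vector of per-volume rates for Q1-Q7, A1, A2,
#'   all in `[0, 1]`.
#' @param inefficiency per-DMU multiplicative excess of resources over
#'   volumes, `>= 1`; a scalar is recycled, `NULL` draws
#'   `1 + |N(0, 0.15)|` per DMU.  Inefficient DMUs also see their
#'   undesirable event rates inflated by the same factor.
#' @param correlation_targets named vector of target correlations for
#'   forced-collinear pairs, names like `"E2-E3"` (default `c("E2-E3" =
#'   0.99)`).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_dmus = 27, n_periods = 4,
                             group_labels = c("B", "C", "D", "E", "F"),
                             size_spread = 10, noise_cv = 0.08,
                             event_rates = c(Q1 = 0.92, Q2 = 0.95, Q3 = 0.60,
                                             Q4 = 0.015, Q5 = 0.008,
                                             Q6 = 0.004, Q7 = 0.006,
                                             A1 = 0.45, A2 = 0.15),
                             inefficiency = NULL,
                             correlation_targets = c("E2-E3" = 0.99),
                             seed = 1L) {
  defaults <- c(Q1 = 0.92, Q2 = 0.95, Q3 = 0.60, Q4 = 0.015, Q5 = 0.008,
                Q6 = 0.004, Q7 = 0.006, A1 = 0.45, A2 = 0.15)
  full <- defaults
  full[names(event_rates)] <- event_rates
  if (any(full < 0) || any(full > 1))
    stop("event rates must lie in [0, 1]", call. = FALSE)
  if (!is.null(inefficiency)) {
    if (any(inefficiency < 1))
      stop("inefficiency factors must be >= 1", call. = FALSE)
    if (!length(inefficiency) %in% c(1L, n_dmus))
      stop("inefficiency must be scalar or one value per DMU", call. = FALSE)
  }
  if (is.null(seed) || is.na(seed))
    stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_dmus >= 1, n_periods >= 1, size_spread >= 1, noise_cv >= 0)
  structure(list(n_dmus = as.integer(n_dmus), n_periods = as.integer(n_periods),
                 group_labels = group_labels, size_spread = size_spread,
                 noise_cv = noise_cv, event_rates = full,
                 inefficiency = inefficiency,
                 correlation_targets = correlation_targets,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic hospital panel
#'
#' Draws a [dea_panel()] with variables E1-E9, Q1-Q7, A1-A3 under the
#' structure described in [synthetic_config()].  The same configuration
#' (including seed) always yields a bit-identical panel; the generator
#' saves and restores the caller's RNG state.
#'
#' @param config a [synthetic_config()].
#' @param eps_floor absolute floor applied to every value so the panel
#'   stays strictly positive (default `1e-6`).
#' @return A [dea_panel()].
#' @export
generate_panel <- function(config = synthetic_config(), eps_floor = 1e-6) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n_dmus
  P <- config$n_periods
  cv <- config$noise_cv
  sdl <- sqrt(log(1 + cv^2))
  lnoise <- function(len, s = sdl) exp(stats::rnorm(len, -s^2 / 2, s))

  scale <- config$size_spread^stats::runif(n)
  ineff <- config$inefficiency
  if (is.null(ineff)) ineff <- 1 + abs(stats::rnorm(n, 0, 0.15))
  if (length(ineff) == 1L) ineff <- rep(ineff, n)

  dmu_ids <- sprintf("H%02d", seq_len(n))
  periods <- as.character(seq_len(P))
  vars <- c(paste0("E", 1:9), paste0("Q", 1:7), paste0("A", 1:3))
  values <- array(NA_real_, c(n, P, length(vars)),
                  dimnames = list(dmu_ids, periods, vars))

  rho <- unname(config$correlation_targets["E2-E3"])
  if (is.na(rho)) rho <- 0.99
  rates <- config$event_rates
  for (p in seq_len(P)) {
    E1 <- 300 * scale * lnoise(n)
    # size the staff columns' idiosyncratic noise against the realised
    # spread of log(beds) so their pooled correlation hits the target
    s2 <- if (n > 1) stats::var(log(E1)) else sdl^2
    tau <- sqrt(max(s2 * (1 - rho) / max(rho, 1e-6), 0))
    E2 <- 3500 * E1 * exp(stats::rnorm(n, -tau^2 / 2, tau))
    E3 <- 5200 * E1 * exp(stats::rnorm(n, -tau^2 / 2, tau))
    E4 <- 55 * (E2 + E3) * lnoise(n)
    E5 <- 42 * (E2 + E3) * lnoise(n)
    E6 <- 0.18 * E4 * lnoise(n)
    E7 <- 45 * E1 / ineff * lnoise(n)
    E8 <- 320 * E1 / ineff * lnoise(n)
    E9 <- 28 * E1 / ineff * lnoise(n)
    draw <- function(vol, rate, bad = FALSE) {
      pr <- if (bad) pmin(1, rate * ineff) else rep(rate, n)
      stats::rbinom(n, floor(vol), pr)
    }
    Q1 <- draw(E7, rates["Q1"]); Q2 <- draw(E7, rates["Q2"])
    Q3 <- draw(E9, rates["Q3"])
    Q4 <- draw(E7, rates["Q4"], bad = TRUE)
    Q5 <- draw(E7, rates["Q5"], bad = TRUE)
    Q6 <- draw(E9, rates["Q6"], bad = TRUE)
    Q7 <- draw(E9, rates["Q7"], bad = TRUE)
    A1 <- draw(E9, rates["A1"])
    A2 <- draw(E8, rates["A2"], bad = TRUE)
    A3 <- 40 * ineff * lnoise(n)
    values[, p, ] <- pmax(cbind(E1, E2, E3, E4, E5, E6, E7, E8, E9,
                                Q1, Q2, Q3, Q4, Q5, Q6, Q7, A1, A2, A3),
                          eps_floor)
  }
  labels <- config$group_labels
  size_rank <- rank(scale, ties.method = "first")
  groups <- stats::setNames(labels[((size_rank - 1L) %% length(labels)) + 1L],
                            dmu_ids)
  dea_panel(values, dmu_ids, periods, vars, groups)
}
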