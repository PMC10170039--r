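#' Bind a panel to a network model for one period
#'
#' Extracts, for every division, the input matrix `X` (n x m_k), desirable
#' output matrix `V` (n x r_k) and undesirable output matrix `U` (n x w_k),
#' plus one n-vector per link, all ordered by `panel$dmu_ids`.  Exact zeros
#' are replaced by `eps_frac` times the column mean over the DMUs of the
#' same period: the frontier LPs divide by the evaluated unit's own values,
#' so a literal zero would be degenerate.
#'
#' @param panel a [dea_panel()].
#' @param spec a [network_spec()]; every referenced variable must exist in
#'   the panel.
#' @param period one of `panel$periods`.
#' @param eps_frac zero-replacement fraction of the period column mean
#'   (default `1e-6`).
#' @return An object of class `division_data`: list with `spec`, `period`,
#'   `dmu_ids`, `X`, `V`, `U` (named lists of matrices per division) and
#'   `Z` (list of n-vectors, one per row of `spec$links`).
#' @export
bind_divisions <- function(panel, spec, period, eps_frac = 1e-6) {
  stopifnot(inherits(panel, "dea_panel"), inherits(spec, "network_spec"))
  period <- as.character(period)
  if (!period %in% panel$periods)
    stop(sprintf("period '%s' not present in panel", period), call. = FALSE)
  missing_vars <- setdiff(spec_variables(spec), panel$variable_ids)
  if (length(missing_vars))
    stop("panel lacks variable(s) required by the model: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  slab <- panel$values[, period, , drop = FALSE]
  dim(slab) <- dim(panel$values)[c(1L, 3L)]
  dimnames(slab) <- list(panel$dmu_ids, panel$variable_ids)
  pull <- function(vars) {
    m <- slab[, vars, drop = FALSE]
    for (j in seq_along(vars)) {
      col <- m[, j]
      if (any(col == 0)) {
        eps <- eps_frac * mean(col)
        if (eps == 0) eps <- eps_frac  # all-zero column: absolute floor
        col[col == 0] <- eps
        m[, j] <- col
      }
    }
    m
  }
  X <- lapply(spec$inputs, pull)
  V <- lapply(spec$desirable_outputs, pull)
  U <- lapply(spec$undesirable_outputs, pull)
  Z <- if (nrow(spec$links))
    lapply(spec$links$variable, function(v) pull(v)[, 1L]) else list()
  structure(list(spec = spec, period = period, dmu_ids = panel$dmu_ids,
                 X = X, V = V, U = U, Z = Z),
            class = "division_data")
}
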