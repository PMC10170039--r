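#' Panel of decision-making-unit observations
#'
#' A `dea_panel` holds one nonnegative observation per (DMU, period,
#' variable) plus a group label per DMU.  It is the data container consumed
#' by [netdea()], the screening tools and the scenario engine.
#'
#' @param values numeric array of dimension `n_dmus x n_periods x n_vars`,
#'   all entries finite and `>= 0`.  Dimnames, if present, are overridden
#'   by the id arguments.
#' @param dmu_ids character vector of unique DMU identifiers (length
#'   `n_dmus`).
#' @param periods character or numeric vector of unique period labels
#'   (length `n_periods`).
#' @param variable_ids character vector of unique variable names
#'   (length `n_vars`).
#' @param groups named character vector mapping every `dmu_id` to a group
#'   label.  Unnamed scalars are recycled.
#'
#' @return An object of class `dea_panel`: a list with elements `values`
#'   (the named 3-d array), `dmu_ids`, `periods`, `variable_ids`, `groups`.
#' @seealso [read_panel()], [write_panel()], [generate_panel()]
#' @export
dea_panel <- function(values, dmu_ids, periods, variable_ids, groups) {
  dmu_ids <- as.character(dmu_ids)
  periods <- as.character(periods)
  variable_ids <- as.character(variable_ids)
  if (anyDuplicated(dmu_ids)) stop("duplicated dmu_ids", call. = FALSE)
  if (anyDuplicated(periods)) stop("duplicated periods", call. = FALSE)
  if (anyDuplicated(variable_ids)) stop("duplicated variable_ids", call. = FALSE)
  values <- as.array(values)
  dims <- c(length(dmu_ids), length(periods), length(variable_ids))
  if (!identical(dim(values), as.integer(dims)))
    stop(sprintf("values must be a %d x %d x %d array", dims[1], dims[2], dims[3]),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("panel values must be finite and non-missing", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at dmu '%s', period '%s', variable '%s'",
                 dmu_ids[bad[1]], periods[bad[2]], variable_ids[bad[3]]),
         call. = FALSE)
  }
  if (length(groups) == 1L && is.null(names(groups)))
    groups <- stats::setNames(rep(as.character(groups), length(dmu_ids)), dmu_ids)
  groups <- stats::setNames(as.character(groups), names(groups))
  if (!setequal(names(groups), dmu_ids) || length(groups) != length(dmu_ids))
    stop("groups must map every dmu_id to exactly one label", call. = FALSE)
  groups <- groups[dmu_ids]
  dimnames(values) <- list(dmu_ids, periods, variable_ids)
  structure(list(values = values, dmu_ids = dmu_ids, periods = periods,
                 variable_ids = variable_ids, groups = groups),
            class = "dea_panel")
}

#' Read a DMU panel from a delimited text file
#'
#' Long-format CSV with header `dmu,period,group,<var1>,...,<varJ>`, one row
#' per (DMU, period).  Values must be nonnegative; every DMU must carry one
#' group label.  Ratio or percentage columns are rejected by default: the
#' frontier model expects absolute volumes (counts, hours, monetary costs,
#' days), whose magnitudes the slack normalisation handles, not bounded
#' ratios.
#'
#' @param path path to the CSV file.
#' @param schema optional declaration of the expected variables: either a
#'   character vector of variable names that must all be present, or a
#'   data.frame with columns `variable` and `kind` (`"count"` or `"ratio"`).
#' @param counts_only logical; when `TRUE` (default) any column declared as
#'   `"ratio"` in `schema` is rejected.
#' @return A [dea_panel()].
#' @export
read_panel <- function(path, schema = NULL, counts_only = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("dmu", "period", "group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("panel file is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  vars <- setdiff(names(df), required)
  if (!length(vars)) stop("panel file has no variable columns", call. = FALSE)
  if (!is.null(schema)) {
    if (is.data.frame(schema)) {
      miss <- setdiff(schema$variable, vars)
      if (length(miss))
        stop("panel file is missing declared variable(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      if (counts_only && any(schema$kind == "ratio")) {
        bad <- schema$variable[schema$kind == "ratio"]
        stop("ratio/percentage variables are not accepted (counts_only = TRUE): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    } else {
      miss <- setdiff(as.character(schema), vars)
      if (length(miss))
        stop("panel file is missing declared variable(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  key <- paste(df$dmu, df$period, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("dmu", "period")][1, ]
    stop(sprintf("duplicated (dmu, period) key: ('%s', '%s')", dup$dmu, dup$period),
         call. = FALSE)
  }
  for (v in vars) {
    col <- df[[v]]
    if (!is.numeric(col))
      stop(sprintf("variable column '%s' is not numeric", v), call. = FALSE)
    if (anyNA(col))
      stop(sprintf("missing value in column '%s' at row %d", v, which(is.na(col))[1]),
           call. = FALSE)
    if (any(col < 0))
      stop(sprintf("negative value in column '%s' at row %d", v, which(col < 0)[1]),
           call. = FALSE)
  }
  dmu_ids <- unique(as.character(df$dmu))
  periods <- unique(as.character(df$period))
  # each DMU must have one consistent group label
  grp <- tapply(as.character(df$group), as.character(df$dmu),
                function(g) unique(g))
  if (any(lengths(grp) != 1L))
    stop("inconsistent group label for dmu(s): ",
         paste(names(grp)[lengths(grp) != 1L], collapse = ", "), call. = FALSE)
  groups <- stats::setNames(vapply(grp, identity, ""), names(grp))[dmu_ids]
  values <- array(NA_real_, c(length(dmu_ids), length(periods), length(vars)),
                  dimnames = list(dmu_ids, periods, vars))
  for (r in seq_len(nrow(df)))
    values[as.character(df$dmu[r]), as.character(df$period[r]), ] <-
      as.numeric(df[r, vars])
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("panel is not complete: no row for dmu '%s', period '%s'",
                 dmu_ids[bad[1]], periods[bad[2]]), call. = FALSE)
  }
  dea_panel(values, dmu_ids, periods, vars, groups)
}

#' Write a DMU panel to CSV
#'
#' Inverse of [read_panel()]: emits the long format
#' `dmu,period,group,<vars...>` so that a write/read round trip reproduces
#' the panel exactly.
#'
#' @param panel a [dea_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "dea_panel"))
  df <- as.data.frame(panel)
  # 17 significant digits keep the write/read round trip bit-exact
  for (v in panel$variable_ids) df[[v]] <- sprintf("%.17g", df[[v]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.dea_panel <- function(x, ...) {
  rows <- expand.grid(period = x$periods, dmu = x$dmu_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("dmu", "period")]
  vals <- t(apply(rows, 1L, function(r) x$values[r[["dmu"]], r[["period"]], ]))
  colnames(vals) <- x$variable_ids
  data.frame(dmu = rows$dmu, period = rows$period,
             group = unname(x$groups[rows$dmu]), vals,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.dea_panel <- function(x, ...) {
  cat(sprintf("DMU panel: %d DMUs x %d periods x %d variables\n",
              length(x$dmu_ids), length(x$periods), length(x$variable_ids)))
  cat("  periods:  ", paste(x$periods, collapse = ", "), "\n")
  cat("  groups:   ", paste(sprintf("%s(%d)", names(table(x$groups)),
                                    table(x$groups)), collapse = " "), "\n")
  cat("  variables:", paste(utils::head(x$variable_ids, 10), collapse = ", "),
      if (length(x$variable_ids) > 10) "..." else "", "\n")
  invisible(x)
}

# pooled (dmu, period) observation matrix, rows = dmu x period, cols = vars
panel_obs_matrix <- function(panel, variables = panel$variable_ids) {
  m <- apply(panel$values[, , variables, drop = FALSE], 3L, as.vector)
  if (is.null(dim(m))) m <- matrix(m, ncol = length(variables))
  colnames(m) <- variables
  m
}
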