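#' Pearson correlation matrix over pooled panel observations
#'
#' Product-moment correlations computed over all (DMU, period) observations
#' pooled together, as used to detect near-collinear variables before
#' frontier estimation.  Zero-variance columns yield `NA` entries and are
#' skipped by [find_clusters()].
#'
#' @param panel a [dea_panel()].
#' @param variables subset of variables (default all).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(panel, variables = panel$variable_ids) {
  stopifnot(inherits(panel, "dea_panel"))
  miss <- setdiff(variables, panel$variable_ids)
  if (length(miss))
    stop("unknown variable(s): ", paste(miss, collapse = ", "), call. = FALSE)
  m <- panel_obs_matrix(panel, variables)
  if (nrow(m) < 3L)
    stop("need at least 3 pooled observations per variable", call. = FALSE)
  suppressWarnings(r <- stats::cor(m, method = "pearson"))
  diag(r) <- ifelse(apply(m, 2L, stats::sd) > 0, 1, NA_real_)
  r
}

#' Clusters of highly correlated same-role variables
#'
#' Builds, within every (division, role) context of the model, a graph
#' whose edges join variable pairs with correlation at or above the
#' threshold, and returns each connected component of two or more
#' variables.  Only variables sharing a role in the same division are
#' eligible to cluster, because only those are interchangeable in the
#' frontier model.  A variable may appear in clusters of different
#' contexts.
#'
#' @param matrix correlation matrix from [pearson_matrix()].
#' @param spec a [network_spec()].
#' @param threshold minimum correlation (default 0.95).
#' @return List of `correlation_cluster` objects: each has `variables`,
#'   `division`, `role` and `pairwise_r` (data.frame `var1,var2,r`).
#' @export
find_clusters <- function(matrix, spec, threshold = 0.95) {
  stopifnot(inherits(spec, "network_spec"))
  contexts <- list()
  for (d in spec$divisions) {
    contexts[[length(contexts) + 1L]] <- list(d = d, role = "input",
                                              vars = spec$inputs[[d]])
    contexts[[length(contexts) + 1L]] <- list(d = d, role = "desirable_output",
                                              vars = spec$desirable_outputs[[d]])
    contexts[[length(contexts) + 1L]] <- list(d = d, role = "undesirable_output",
                                              vars = spec$undesirable_outputs[[d]])
  }
  # links are a role of their own, shared between the two endpoint divisions
  if (nrow(spec$links)) {
    pairs <- unique(spec$links[, c("from", "to")])
    for (i in seq_len(nrow(pairs))) {
      sel <- spec$links$from == pairs$from[i] & spec$links$to == pairs$to[i]
      contexts[[length(contexts) + 1L]] <- list(
        d = sprintf("%s->%s", pairs$from[i], pairs$to[i]), role = "link",
        vars = spec$links$variable[sel])
    }
  }
  clusters <- list()
  for (ctx in contexts) {
    vars <- intersect(ctx$vars, rownames(matrix))
    vars <- vars[!is.na(diag(matrix[vars, vars, drop = FALSE]))]
    if (length(vars) < 2L) next
    r <- matrix[vars, vars, drop = FALSE]
    adj <- !is.na(r) & r >= threshold
    diag(adj) <- FALSE
    comp <- connected_components(adj)
    for (members in comp) {
      if (length(members) < 2L) next
      idx <- t(utils::combn(members, 2L))
      pr <- data.frame(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
                       r = r[idx], row.names = NULL)
      clusters[[length(clusters) + 1L]] <- structure(
        list(variables = vars[members], division = ctx$d, role = ctx$role,
             pairwise_r = pr),
        class = "correlation_cluster")
    }
  }
  clusters
}

# connected components of a symmetric logical adjacency matrix
connected_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    stack <- i
    members <- integer()
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      stack <- c(stack, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' @export
print.correlation_cluster <- function(x, ...) {
  cat(sprintf("Correlation cluster in division '%s' (%s): %s\n",
              x$division, x$role, paste(x$variables, collapse = ", ")))
  cat(sprintf("  min pairwise r = %.4f\n", min(x$pairwise_r$r)))
  invisible(x)
}

#' Merge clustered variables into one column
#'
#' Replaces the cluster members by their cellwise sum under a new name
#' (e.g. doctors' plus nurses' hours into a single clinical-staff column).
#' Summation is the only supported merge: the members must be measured in
#' the same unit for the merged column to stay meaningful.
#'
#' @param panel a [dea_panel()].
#' @param cluster a `correlation_cluster` or a character vector of variable
#'   ids to merge.
#' @param new_id name of the merged column.
#' @param method merge method; only `"sum"` is supported.
#' @return A new [dea_panel()]; the input panel is not modified.
#' @export
merge_variables <- function(panel, cluster, new_id, method = "sum") {
  stopifnot(inherits(panel, "dea_panel"))
  method <- match.arg(method, "sum")
  vars <- if (inherits(cluster, "correlation_cluster")) cluster$variables
          else as.character(cluster)
  miss <- setdiff(vars, panel$variable_ids)
  if (length(miss))
    stop("variable(s) not in panel: ", paste(miss, collapse = ", "), call. = FALSE)
  if (new_id %in% setdiff(panel$variable_ids, vars))
    stop(sprintf("variable '%s' already exists in the panel", new_id), call. = FALSE)
  keep <- setdiff(panel$variable_ids, vars)
  merged <- apply(panel$values[, , vars, drop = FALSE], c(1L, 2L), sum)
  new_vars <- c(keep, new_id)
  values <- array(NA_real_,
                  c(length(panel$dmu_ids), length(panel$periods), length(new_vars)),
                  dimnames = list(panel$dmu_ids, panel$periods, new_vars))
  if (length(keep)) values[, , keep] <- panel$values[, , keep, drop = FALSE]
  values[, , new_id] <- merged
  dea_panel(values, panel$dmu_ids, panel$periods, new_vars, panel$groups)
}
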