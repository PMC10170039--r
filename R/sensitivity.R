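#' Enumerate model variants from correlation clusters
#'
#' Highly correlated same-role variables are interchangeable in the model,
#' so each cluster induces a choice of a single representative.  The
#' variants are the Cartesian product of those choices over all clusters
#' that intersect the model: each variant keeps exactly one member of each
#' cluster in its role slot and drops the others.
#'
#' @param spec a [network_spec()].
#' @param clusters list of `correlation_cluster`s (see [find_clusters()]).
#' @return List of [network_spec()]s; with no applicable clusters, a list
#'   holding the original spec.
#' @export
enumerate_variants <- function(spec, clusters) {
  stopifnot(inherits(spec, "network_spec"))
  present <- spec_variables(spec)
  usable <- list()
  for (cl in clusters) {
    inside <- cl$variables %in% present
    if (!any(inside)) next
    if (!all(inside))
      stop(sprintf("cluster member(s) absent from the model: %s",
                   paste(cl$variables[!inside], collapse = ", ")), call. = FALSE)
    usable[[length(usable) + 1L]] <- cl
  }
  if (!length(usable)) return(list(spec))
  choice_grid <- expand.grid(lapply(usable, function(cl) cl$variables),
                             stringsAsFactors = FALSE)
  variants <- vector("list", nrow(choice_grid))
  for (i in seq_len(nrow(choice_grid))) {
    v <- spec
    for (j in seq_along(usable)) {
      cl <- usable[[j]]
      keep <- choice_grid[i, j]
      drop <- setdiff(cl$variables, keep)
      v <- drop_spec_variables(v, cl, drop)
    }
    v$name <- sprintf("%s[%s]", spec$name,
                      paste(unlist(choice_grid[i, ]), collapse = "+"))
    variants[[i]] <- v
  }
  variants
}

# remove `drop` variables from the cluster's (division, role) slot
drop_spec_variables <- function(spec, cluster, drop) {
  if (!length(drop)) return(spec)
  role <- cluster$role
  if (role == "link") {
    spec$links <- spec$links[!spec$links$variable %in% drop, , drop = FALSE]
  } else {
    slot <- switch(role, input = "inputs",
                   desirable_output = "desirable_outputs",
                   undesirable_output = "undesirable_outputs")
    d <- cluster$division
    spec[[slot]][[d]] <- setdiff(spec[[slot]][[d]], drop)
  }
  spec
}

#' Compare efficiency scores across model variants
#'
#' Fits every variant and reports, per DMU, the spread of its cross-period
#' mean overall score across variants: the maximum absolute pairwise
#' difference by default, or the maximum absolute difference to a
#' designated baseline variant.  DMUs whose spread exceeds the threshold
#' are flagged as sensitive to the variable choice.
#'
#' @param panel a [dea_panel()].
#' @param variants list of [network_spec()]s (see [enumerate_variants()]).
#' @param rts returns-to-scale regime (default `"vrs"`).
#' @param threshold flagging threshold on the score spread, in score units
#'   (default 0.05, i.e. five percentage points).
#' @param baseline optional index of a baseline variant; when given, the
#'   spread is measured against that variant only.
#' @param ... passed to [netdea()].
#' @return An object of class `variant_report`: list with `scores` (DMU x
#'   variant matrix of mean overall scores), `per_dmu_range` (named
#'   vector), `flagged` (character vector), `threshold`, `variant_names`.
#' @export
compare_variants <- function(panel, variants, rts = "vrs", threshold = 0.05,
                             baseline = NULL, ...) {
  stopifnot(inherits(panel, "dea_panel"), length(variants) >= 1L)
  fits <- lapply(variants, function(v) netdea(panel, v, rts = rts, ...))
  scores <- vapply(fits, fitted, numeric(length(panel$dmu_ids)))
  if (is.null(dim(scores)))
    scores <- matrix(scores, nrow = length(panel$dmu_ids))
  rownames(scores) <- panel$dmu_ids
  colnames(scores) <- vapply(variants, function(v) v$name, "")
  per_dmu_range <- if (is.null(baseline)) {
    apply(scores, 1L, function(s) max(s) - min(s))
  } else {
    stopifnot(baseline >= 1, baseline <= ncol(scores))
    apply(abs(scores - scores[, baseline]), 1L, max)
  }
  structure(list(scores = scores, per_dmu_range = per_dmu_range,
                 flagged = names(per_dmu_range)[per_dmu_range > threshold],
                 threshold = threshold, variant_names = colnames(scores),
                 rts = rts),
            class = "variant_report")
}

#' @export
print.variant_report <- function(x, digits = 4, ...) {
  cat(sprintf("Sensitivity over %d model variant(s) (%s)\n",
              length(x$variant_names), toupper(x$rts)))
  cat(sprintf("Max per-DMU score spread: %.*f; %d DMU(s) above %.0f%%\n",
              digits, max(x$per_dmu_range), length(x$flagged),
              100 * x$threshold))
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
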