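#' Counterfactual scenario for one quality/access variable
#'
#' A scenario replaces one panel column by its hypothetical best- or
#' worst-case level: the small constant `eps` (an adverse-event count of
#' "essentially zero"), another column (e.g. every inpatient developing a
#' pressure ulcer makes the ulcer count equal the inpatient count), or a
#' multiple of the column's observed maximum (for unbounded quantities
#' such as waiting days).
#'
#' @param variable_id panel column the scenario edits.
#' @param mode `"best"` or `"worst"`.
#' @param rule one of: the string `"eps"`; the name of another panel
#'   column; or `list(max_of = <variable>, factor = <k>)` for `k` times the
#'   observed maximum of `<variable>`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(variable_id, mode = c("best", "worst"), rule) {
  mode <- match.arg(mode)
  if (!(identical(rule, "eps") || (is.character(rule) && length(rule) == 1L) ||
        (is.list(rule) && !is.null(rule$max_of))))
    stop("rule must be \"eps\", a column name, or list(max_of=, factor=)",
         call. = FALSE)
  structure(list(variable_id = as.character(variable_id), mode = mode,
                 rule = rule),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  rule <- if (identical(x$rule, "eps")) "eps"
          else if (is.character(x$rule)) paste0("column ", x$rule)
          else sprintf("%g * max(%s)", x$rule$factor %||% 1, x$rule$max_of)
  cat(sprintf("Scenario: %s (%s) <- %s\n", x$variable_id, x$mode, rule))
  invisible(x)
}

#' Default best/worst scenario rules for the hospital variables
#'
#' One best-case and one worst-case rule for each quality (Q1-Q7) and
#' access (A1-A3) variable.  Undesirable event counts are best at
#' essentially zero (`eps`) and worst at their bounding volume (pressure
#' ulcers and catheter infections at the inpatient count E7; septicaemia
#' and embolism/thrombosis cases at the surgery count E9; delayed first
#' appointments at the outpatient count E8).  Desirable counts are best at
#' their bounding volume and worst at `eps`.  Waiting days (A3) are best at
#' `eps` and worst at a configurable multiple of the observed maximum.
#' Only the zero/volume construction for the undesirable inpatient events
#' is canonical; the remaining bounds are this package's documented
#' defaults and can be overridden.
#'
#' @param a1_best column bounding the timely hip-fracture surgeries from
#'   above (default `"E9"`).
#' @param a3_worst_factor multiple of the observed maximum waiting time
#'   used as the worst case (default 2).
#' @return List of [scenario_spec()]s (two per variable).
#' @export
default_scenario_rules <- function(a1_best = "E9", a3_worst_factor = 2) {
  rules <- list(
    scenario_spec("Q1", "best", "E7"), scenario_spec("Q1", "worst", "eps"),
    scenario_spec("Q2", "best", "E7"), scenario_spec("Q2", "worst", "eps"),
    scenario_spec("Q3", "best", "E9"), scenario_spec("Q3", "worst", "eps"),
    scenario_spec("Q4", "best", "eps"), scenario_spec("Q4", "worst", "E7"),
    scenario_spec("Q5", "best", "eps"), scenario_spec("Q5", "worst", "E7"),
    scenario_spec("Q6", "best", "eps"), scenario_spec("Q6", "worst", "E9"),
    scenario_spec("Q7", "best", "eps"), scenario_spec("Q7", "worst", "E9"),
    scenario_spec("A1", "best", a1_best), scenario_spec("A1", "worst", "eps"),
    scenario_spec("A2", "best", "eps"), scenario_spec("A2", "worst", "E8"),
    scenario_spec("A3", "best", "eps"),
    scenario_spec("A3", "worst", list(max_of = "A3", factor = a3_worst_factor)))
  rules
}

#' Apply a scenario to a panel
#'
#' Returns a copy of the panel in which exactly the target column has been
#' replaced according to the rule; all other columns are untouched.
#' Applying the same scenario twice is a no-op the second time.
#'
#' @param panel a [dea_panel()].
#' @param scenario a [scenario_spec()].
#' @param eps the small positive constant standing in for zero (default
#'   `1e-6`).
#' @return A new [dea_panel()].
#' @export
apply_scenario <- function(panel, scenario, eps = 1e-6) {
  stopifnot(inherits(panel, "dea_panel"), inherits(scenario, "scenario_spec"))
  v <- scenario$variable_id
  if (!v %in% panel$variable_ids)
    stop(sprintf("scenario variable '%s' not in panel", v), call. = FALSE)
  rule <- scenario$rule
  values <- panel$values
  if (identical(rule, "eps")) {
    values[, , v] <- eps
  } else if (is.character(rule)) {
    if (!rule %in% panel$variable_ids)
      stop(sprintf("rule column '%s' not in panel", rule), call. = FALSE)
    repl <- panel$values[, , rule]
    if (any(repl < 0))
      stop("rule produces a negative column", call. = FALSE)
    if (all(repl == 0))
      stop("rule produces an all-zero column", call. = FALSE)
    values[, , v] <- repl
  } else {
    src <- rule$max_of
    if (!src %in% panel$variable_ids)
      stop(sprintf("rule column '%s' not in panel", src), call. = FALSE)
    factor <- rule$factor %||% 1
    if (factor <= 0) stop("rule factor must be positive", call. = FALSE)
    top <- factor * max(panel$values[, , src])
    if (top <= 0) stop("rule produces an all-zero column", call. = FALSE)
    values[, , v] <- top
  }
  dea_panel(values, panel$dmu_ids, panel$periods, panel$variable_ids,
            panel$groups)
}

#' Impact of counterfactual scenarios on overall efficiency
#'
#' For every scenario, rebuilds the panel with [apply_scenario()], refits
#' the model, and compares each DMU's cross-period mean overall score with
#' the baseline.  The per-DMU impact is `ratio - 1` where
#' `ratio = scenario score / baseline score`: positive when the edit makes
#' the DMU look more efficient.  Group impacts aggregate `|ratio - 1|`
#' within each DMU group.
#'
#' @param panel a [dea_panel()].
#' @param model model passed to [netdea()] (default shipped model `"A"`).
#' @param scenarios list of [scenario_spec()]s (default
#'   [default_scenario_rules()] restricted to panel columns).
#' @param rts returns-to-scale regime (default `"vrs"`).
#' @param baseline optional precomputed baseline [netdea()] fit on the same
#'   panel/model/rts.
#' @param eps scenario zero stand-in (default `1e-6`).
#' @param ... further arguments passed to [netdea()].
#' @return An object of class `scenario_impact_set`: list with `impacts`
#'   (one `scenario_impact` per scenario), `ratios` (long data.frame
#'   `variable,mode,dmu,group,ratio,impact`) and `summary` (data.frame
#'   `variable,mode,max_impact,mean_impact` plus one `group_mean_abs`
#'   column per group).
#' @export
impact_analysis <- function(panel, model = "A", scenarios = NULL,
                            rts = "vrs", baseline = NULL, eps = 1e-6, ...) {
  stopifnot(inherits(panel, "dea_panel"))
  if (is.null(scenarios)) {
    scenarios <- Filter(function(s) s$variable_id %in% panel$variable_ids,
                        default_scenario_rules())
  }
  if (is.null(baseline)) baseline <- netdea(panel, model, rts = rts, ...)
  base_scores <- fitted(baseline)
  groups <- panel$groups
  impacts <- list()
  ratio_rows <- list()
  for (sc in scenarios) {
    edited <- apply_scenario(panel, sc, eps = eps)
    fit <- tryCatch(netdea(edited, model, rts = rts, ...),
      error = function(e) stop(sprintf("[scenario %s/%s] %s", sc$variable_id,
                                       sc$mode, conditionMessage(e)),
                               call. = FALSE))
    ratio <- fitted(fit) / base_scores
    impact <- ratio - 1
    grp_abs <- tapply(abs(impact), groups[names(ratio)], mean)
    rec <- structure(list(variable_id = sc$variable_id, mode = sc$mode,
                          per_dmu_ratio = ratio,
                          max_impact = max(impact), mean_impact = mean(impact),
                          group_mean_abs = grp_abs),
                     class = "scenario_impact")
    impacts[[length(impacts) + 1L]] <- rec
    ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
      variable = sc$variable_id, mode = sc$mode, dmu = names(ratio),
      group = unname(groups[names(ratio)]), ratio = unname(ratio),
      impact = unname(impact), row.names = NULL)
  }
  ratios <- do.call(rbind, ratio_rows)
  grp_levels <- sort(unique(unname(groups)))
  summary_df <- do.call(rbind, lapply(impacts, function(r) {
    g <- r$group_mean_abs[grp_levels]
    names(g) <- paste0("group_mean_abs.", grp_levels)
    cbind(data.frame(variable = r$variable_id, mode = r$mode,
                     max_impact = r$max_impact, mean_impact = r$mean_impact),
          as.data.frame(as.list(g)))
  }))
  structure(list(impacts = impacts, ratios = ratios, summary = summary_df,
                 rts = rts),
            class = "scenario_impact_set")
}

#' @export
print.scenario_impact <- function(x, ...) {
  cat(sprintf("Scenario impact %s (%s): max %+0.2f%%, mean %+0.2f%%\n",
              x$variable_id, x$mode, 100 * x$max_impact, 100 * x$mean_impact))
  invisible(x)
}

#' @export
print.scenario_impact_set <- function(x, digits = 3, ...) {
  cat(sprintf("Scenario impact analysis (%s): %d scenario(s)\n",
              toupper(x$rts), length(x$impacts)))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
plot.scenario_impact_set <- function(x, ...) {
  s <- x$summary
  lbl <- paste(s$variable, s$mode, sep = "\n")
  graphics::barplot(rbind(100 * s$max_impact, 100 * s$mean_impact),
                    beside = TRUE, names.arg = lbl, las = 2,
                    legend.text = c("max", "mean"),
                    ylab = "impact on overall efficiency (%)",
                    main = "Best-/worst-case scenario impacts", ...)
  graphics::abline(h = 0)
  invisible(x)
}
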