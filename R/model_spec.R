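#' Network model specification
#'
#' A `network_spec` describes how a DMU decomposes into divisions: which
#' panel variables each division consumes as external inputs, emits as
#' desirable or undesirable outputs, and which variables flow between
#' divisions as links (intermediate products produced by one division and
#' consumed by another).
#'
#' @param divisions character vector of division ids, in evaluation order.
#' @param inputs named list: division id -> character vector of input
#'   variable ids (may omit divisions with no external inputs).
#' @param desirable_outputs named list: division -> desirable output ids.
#' @param undesirable_outputs named list: division -> undesirable output ids.
#' @param links data.frame with columns `from`, `to`, `variable` (one row
#'   per linked variable), or a list of 3-element vectors.
#' @param orientation named character vector division -> `"input"` or
#'   `"output"`.  Default: the first division is input oriented, all others
#'   output oriented.
#' @param name optional model label.
#'
#' @return An object of class `network_spec`.
#' @seealso [read_model_spec()], [model_spec()]
#' @export
network_spec <- function(divisions, inputs = list(), desirable_outputs = list(),
                         undesirable_outputs = list(), links = NULL,
                         orientation = NULL, name = NULL) {
  divisions <- as.character(divisions)
  if (!length(divisions) || anyDuplicated(divisions))
    stop("divisions must be a non-empty set of unique ids", call. = FALSE)
  norm_role <- function(role, what) {
    role <- lapply(role, as.character)
    extra <- setdiff(names(role), divisions)
    if (length(extra))
      stop(sprintf("%s refer to unknown division(s): %s", what,
                   paste(extra, collapse = ", ")), call. = FALSE)
    out <- stats::setNames(vector("list", length(divisions)), divisions)
    for (d in divisions) out[[d]] <- if (is.null(role[[d]])) character() else role[[d]]
    out
  }
  inputs <- norm_role(inputs, "inputs")
  desirable_outputs <- norm_role(desirable_outputs, "desirable_outputs")
  undesirable_outputs <- norm_role(undesirable_outputs, "undesirable_outputs")
  if (is.null(links)) links <- data.frame(from = character(), to = character(),
                                          variable = character())
  if (!is.data.frame(links))
    links <- do.call(rbind, lapply(links, function(l)
      data.frame(from = l[[1]], to = l[[2]], variable = l[[3]])))
  links[] <- lapply(links, as.character)
  if (nrow(links)) {
    bad <- !(links$from %in% divisions) | !(links$to %in% divisions)
    if (any(bad))
      stop("link references unknown division: ",
           paste(unique(c(links$from[bad], links$to[bad])), collapse = ", "),
           call. = FALSE)
    if (any(links$from == links$to))
      stop("links must connect two distinct divisions", call. = FALSE)
  }
  # within one division a variable takes exactly one role; links count as a
  # role for both endpoints
  for (d in divisions) {
    roles <- c(inputs[[d]], desirable_outputs[[d]], undesirable_outputs[[d]],
               links$variable[links$from == d | links$to == d])
    if (anyDuplicated(roles))
      stop(sprintf("variable '%s' has more than one role in division '%s'",
                   roles[duplicated(roles)][1], d), call. = FALSE)
  }
  if (is.null(orientation)) {
    orientation <- stats::setNames(
      c("input", rep("output", length(divisions) - 1L)), divisions)
  } else {
    orientation <- stats::setNames(as.character(orientation), names(orientation))
    if (!setequal(names(orientation), divisions))
      stop("orientation must name every division", call. = FALSE)
    if (!all(orientation %in% c("input", "output")))
      stop("orientation values must be 'input' or 'output'", call. = FALSE)
    orientation <- orientation[divisions]
  }
  structure(list(divisions = divisions, inputs = inputs,
                 desirable_outputs = desirable_outputs,
                 undesirable_outputs = undesirable_outputs,
                 links = links, orientation = orientation,
                 name = if (is.null(name)) "custom" else as.character(name)),
            class = "network_spec")
}

#' All variables referenced by a network spec
#'
#' @param spec a [network_spec()].
#' @return Character vector of the distinct variable ids used in any role.
#' @export
spec_variables <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  unique(c(unlist(spec$inputs, use.names = FALSE),
           unlist(spec$desirable_outputs, use.names = FALSE),
           unlist(spec$undesirable_outputs, use.names = FALSE),
           spec$links$variable))
}

#' Read a network model specification from YAML or JSON
#'
#' The file carries keys `divisions`, `inputs`, `desirable_outputs`,
#' `undesirable_outputs`, `links` (list of `[from, to, variable]` triples)
#' and optionally `orientation` and `name`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [network_spec()].
#' @export
read_model_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$divisions)) stop("model spec has no 'divisions' key", call. = FALSE)
  links <- cfg$links
  if (!is.null(links) && length(links) && !is.data.frame(links)) {
    links <- do.call(rbind, lapply(links, function(l) {
      l <- unlist(l, use.names = FALSE)
      if (length(l) != 3L)
        stop("each link must be a [from, to, variable] triple", call. = FALSE)
      data.frame(from = l[1], to = l[2], variable = l[3])
    }))
  }
  orientation <- cfg$orientation
  if (!is.null(orientation)) orientation <- unlist(orientation)
  network_spec(divisions = unlist(cfg$divisions),
               inputs = cfg$inputs %||% list(),
               desirable_outputs = cfg$desirable_outputs %||% list(),
               undesirable_outputs = cfg$undesirable_outputs %||% list(),
               links = links, orientation = orientation, name = cfg$name)
}

#' Shipped hospital network models
#'
#' Four ready-made network structures for a hospital panel with variables
#' E1-E9 (capacity, labour, costs, patient volumes), Q1-Q7 (quality) and
#' A1-A3 (access).  `"A"` uses four divisions (operations plus inpatient,
#' outpatient and surgical services), `"B"` three (efficiency, quality,
#' access); `"C"`/`"D"` replace staff hours (E2, E3) by personnel costs
#' (E5) and add outsourcing costs (E6).  The variable-to-division wiring is
#' a documented reconstruction of the field's usual hospital production
#' layout and can be overridden with a user YAML file.
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A [network_spec()].
#' @export
model_spec <- function(name = c("A", "B", "C", "D")) {
  name <- match.arg(name)
  path <- system.file("extdata", sprintf("model%s.yaml", name),
                      package = "netdea", mustWork = TRUE)
  read_model_spec(path)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("Network model '%s': %d division(s), %d link(s)\n",
              x$name, length(x$divisions), nrow(x$links)))
  for (d in x$divisions) {
    cat(sprintf("  [%s] (%s oriented)\n", d, x$orientation[[d]]))
    role_line <- function(lbl, v) if (length(v))
      cat(sprintf("    %-12s %s\n", lbl, paste(v, collapse = ", ")))
    role_line("inputs:", x$inputs[[d]])
    role_line("desirable:", x$desirable_outputs[[d]])
    role_line("undesirable:", x$undesirable_outputs[[d]])
    inl <- x$links[x$links$to == d, ]
    outl <- x$links[x$links$from == d, ]
    if (nrow(inl))
      cat(sprintf("    %-12s %s\n", "links in:",
                  paste(sprintf("%s (from %s)", inl$variable, inl$from), collapse = ", ")))
    if (nrow(outl))
      cat(sprintf("    %-12s %s\n", "links out:",
                  paste(sprintf("%s (to %s)", outl$variable, outl$to), collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
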