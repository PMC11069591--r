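#' Read a panel from CSV
#'
#' Expects the tidy schema `state, county, week, <condition...>`, with weeks
#' as 0-based contiguous integers per county (an ISO-date `week` column is
#' accepted and converted to the 0-based index of its sorted unique dates)
#' and missing cells empty. Validates that every county belongs to exactly
#' one state, weeks are contiguous within county, and observed frequencies
#' are finite and nonnegative.
#'
#' @param path CSV file path.
#' @return A validated panel tibble.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_panel(panel)
  if (inherits(panel$week, "Date") || is.character(panel$week)) {
    dates <- tryCatch(as.Date(panel$week), error = function(e) NA)
    if (anyNA(dates)) abort("`week` column is neither integer nor ISO dates")
    panel$week <- match(dates, sort(unique(dates))) - 1L
  }
  if (!is.numeric(panel$week) || any(panel$week != floor(panel$week))) {
    abort("`week` must be integer (or ISO dates)")
  }
  panel$week <- as.integer(panel$week)
  validate_panel(panel)
}

validate_panel <- function(panel) {
  check_panel(panel)
  states_per_county <- tapply(panel$state, panel$county,
                              function(s) length(unique(s)))
  if (any(states_per_county > 1)) {
    bad <- names(states_per_county)[states_per_county > 1][1]
    abort(paste0("county ", bad, " appears in more than one state"))
  }
  by_cty <- split(panel$week, panel$county)
  for (cc in names(by_cty)) {
    wk <- sort(by_cty[[cc]])
    if (anyDuplicated(wk) || !all(diff(wk) == 1)) {
      abort(paste0("weeks are not a contiguous unduplicated range in county ", cc))
    }
  }
  for (cond in panel_conditions(panel)) {
    x <- panel[[cond]]
    if (!is.numeric(x)) {
      abort(paste0("condition column ", cond, " is not numeric"))
    }
    bad <- which(!is.na(x) & (!is.finite(x) | x < 0))
    if (length(bad)) {
      abort(paste0(
        "condition ", cond, " has a non-finite or negative value at row ",
        bad[1]
      ))
    }
  }
  dplyr::arrange(panel, .data$state, .data$county, .data$week)
}

#' Write a panel to CSV
#'
#' @param panel A panel tibble.
#' @param path Output CSV path; missing cells are written empty.
#' @export
write_panel <- function(panel, path) {
  check_panel(panel)
  readr::write_csv(panel, path, na = "")
  invisible(path)
}

#' Write a graph as an edge-list CSV
#'
#' Two-slice DAGs are written as `source_condition, target_condition, lag`
#' (lag 1); folded graphs additionally carry the arc class; strength tables
#' their strengths, sorted by decreasing strength.
#'
#' @param x A `two_slice_dag`, `folded_graph`, `static_dag` or
#'   `arc_strength_table`.
#' @param path Output CSV path.
#' @export
write_arcs_csv <- function(x, path) {
  df <- if (inherits(x, "two_slice_dag")) {
    tibble::tibble(source_condition = x$arcs$from,
                   target_condition = x$arcs$to, lag = 1L)
  } else if (inherits(x, "folded_graph")) {
    tibble::tibble(source_condition = x$arcs$from,
                   target_condition = x$arcs$to, class = x$arcs$class)
  } else if (inherits(x, "static_dag")) {
    tibble::tibble(source_condition = x$arcs$from,
                   target_condition = x$arcs$to)
  } else if (inherits(x, "arc_strength_table")) {
    tibble::tibble(source = x$from, target = x$to, strength = x$strength)
  } else {
    abort("unsupported graph object")
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Write a folded graph as GraphML and DOT
#'
#' GraphML for machine consumption and DOT for rendering; feedback loops
#' are emitted in both directions so renderers draw them bidirectional,
#' with the arc class as an edge attribute.
#'
#' @param folded A `folded_graph`.
#' @param stem Output path without extension; writes `<stem>.graphml` and
#'   `<stem>.dot`.
#' @export
write_graph_files <- function(folded, stem) {
  g <- folded_as_igraph(folded)
  igraph::write_graph(g, paste0(stem, ".graphml"), format = "graphml")
  igraph::write_graph(g, paste0(stem, ".dot"), format = "dot")
  invisible(c(paste0(stem, ".graphml"), paste0(stem, ".dot")))
}

#' Serialize / restore a ground truth
#'
#' Structured-text (JSON) round trip of a [make_ground_truth()] object, for
#' fixtures and provenance.
#'
#' @param gt A `ground_truth`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  obj <- list(
    conditions = gt$conditions,
    arcs = gt$dag$arcs,
    coefficients = tidy(gt),
    intercepts = as.list(gt$intercepts),
    residual_sd = as.list(gt$residual_sd),
    state_sd = gt$state_sd,
    county_sd = gt$county_sd,
    n_feedback = gt$n_feedback,
    n_unidirectional = gt$n_unidirectional,
    seed = gt$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conds <- obj$conditions
  p <- length(conds)
  B <- matrix(0, p, p, dimnames = list(conds, conds))
  cf <- obj$coefficients
  B[cbind(match(cf$to, conds), match(cf$from, conds))] <- cf$coefficient
  residual_sd <- unlist(obj$residual_sd)[conds]
  structure(
    list(
      conditions = conds,
      dag = two_slice_dag(conds, obj$arcs),
      coefficients = B,
      intercepts = unlist(obj$intercepts)[conds],
      residual_sd = residual_sd,
      state_sd = obj$state_sd,
      county_sd = obj$county_sd,
      stationary_cov = stationary_cov(B, residual_sd),
      n_feedback = obj$n_feedback,
      n_unidirectional = obj$n_unidirectional,
      seed = obj$seed
    ),
    class = "ground_truth"
  )
}
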