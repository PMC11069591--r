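#' Two-slice directed acyclic graph
#'
#' Constructs the bipartite graph over conditions measured at two consecutive
#' time points. Every arc points forward in time, from a condition at the
#' earlier slice (`t0`) to a condition at the later slice (`t1`), so the graph
#' is acyclic by construction; self-arcs (`X@t0 -> X@t1`) express
#' autocorrelation and are permitted.
#'
#' @param conditions Character vector of condition names (node labels).
#' @param arcs A data frame with columns `from` and `to`, both condition
#'   names; each row is the arc `from@t0 -> to@t1`.
#' @return An object of class `two_slice_dag`: a list with elements
#'   `conditions` and `arcs` (a tibble sorted by `(to, from)`).
#' @export
#' @examples
#' two_slice_dag(c("ANX", "DER"), data.frame(from = "ANX", to = "DER"))
two_slice_dag <- function(conditions, arcs = NULL) {
  stopifnot(is.character(conditions), length(conditions) >= 1)
  if (anyDuplicated(conditions)) abort("duplicated condition names")
  if (is.null(arcs) || nrow(arcs) == 0) {
    arcs <- tibble::tibble(from = character(), to = character())
  }
  arcs <- tibble::as_tibble(arcs[, c("from", "to")])
  bad <- !(arcs$from %in% conditions) | !(arcs$to %in% conditions)
  if (any(bad)) {
    abort(paste0(
      "arc endpoints not among conditions: ",
      paste(unique(c(arcs$from[bad], arcs$to[bad])), collapse = ", ")
    ))
  }
  if (anyDuplicated(paste(arcs$from, arcs$to))) abort("duplicated arcs")
  arcs <- dplyr::arrange(
    arcs,
    match(.data$to, conditions), match(.data$from, conditions)
  )
  structure(
    list(conditions = conditions, arcs = arcs),
    class = "two_slice_dag"
  )
}

#' @export
print.two_slice_dag <- function(x, ...) {
  cat(
    "<two_slice_dag> ", length(x$conditions), " conditions, ",
    nrow(x$arcs), " arcs (t0 -> t1), of which ",
    sum(x$arcs$from == x$arcs$to), " self-arcs\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.two_slice_dag <- function(x, ...) {
  dplyr::mutate(x$arcs, lag = 1L)
}

# Parent sets as a named list of character vectors, one per t1 node.
dag_parents <- function(dag) {
  split(dag$arcs$from, factor(dag$arcs$to, levels = dag$conditions))
}

n_arcs <- function(dag) nrow(dag$arcs)

#' Fold a two-slice DAG into a cyclic condition graph
#'
#' Collapses the two copies of each condition into a single node. A pair of
#' cross arcs `X@t0 -> Y@t1` and `Y@t0 -> X@t1` becomes a feedback loop
#' `X <-> Y`; a lone cross arc becomes a unidirectional arc; a self-arc
#' becomes an autoloop recording the condition's autocorrelation.
#'
#' @param dag A [two_slice_dag()].
#' @return An object of class `folded_graph`: list with `conditions` and
#'   `arcs`, a tibble with columns `from`, `to`, `class` (one of `"feedback"`,
#'   `"unidirectional"`, `"autoloop"`). Feedback loops appear once, with
#'   `from` preceding `to` in condition order.
#' @export
#' @examples
#' dag <- two_slice_dag(
#'   c("A", "B"),
#'   data.frame(from = c("A", "B", "A"), to = c("B", "A", "A"))
#' )
#' fold(dag)$arcs
fold <- function(dag) {
  stopifnot(inherits(dag, "two_slice_dag"))
  conds <- dag$conditions
  arcs <- dag$arcs
  key <- paste(arcs$from, arcs$to, sep = "\r")
  has <- function(a, b) paste(a, b, sep = "\r") %in% key
  out <- list()
  for (i in seq_along(conds)) {
    if (has(conds[i], conds[i])) {
      out[[length(out) + 1L]] <-
        tibble::tibble(from = conds[i], to = conds[i], class = "autoloop")
    }
    for (j in seq_along(conds)) {
      if (i == j) next
      fwd <- has(conds[i], conds[j])
      bwd <- has(conds[j], conds[i])
      if (fwd && bwd && i < j) {
        out[[length(out) + 1L]] <-
          tibble::tibble(from = conds[i], to = conds[j], class = "feedback")
      } else if (fwd && !bwd) {
        out[[length(out) + 1L]] <-
          tibble::tibble(from = conds[i], to = conds[j], class = "unidirectional")
      }
    }
  }
  arcs_out <- if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(from = character(), to = character(), class = character())
  }
  structure(
    list(conditions = conds, arcs = arcs_out),
    class = "folded_graph"
  )
}

#' Unfold a cyclic condition graph back into a two-slice DAG
#'
#' Inverse of [fold()]: feedback loops expand into both cross arcs,
#' unidirectional arcs into one cross arc, autoloops into self-arcs.
#'
#' @param folded A `folded_graph`.
#' @return A [two_slice_dag()].
#' @export
unfold <- function(folded) {
  stopifnot(inherits(folded, "folded_graph"))
  a <- folded$arcs
  fb <- a[a$class == "feedback", ]
  parts <- dplyr::bind_rows(
    a[a$class != "feedback", c("from", "to")],
    fb[c("from", "to")],
    tibble::tibble(from = fb$to, to = fb$from)
  )
  two_slice_dag(folded$conditions, parts)
}

#' @export
print.folded_graph <- function(x, ...) {
  tab <- table(factor(x$arcs$class,
    levels = c("feedback", "unidirectional", "autoloop")
  ))
  cat(
    "<folded_graph> ", length(x$conditions), " conditions: ",
    tab[["feedback"]], " feedback, ", tab[["unidirectional"]],
    " unidirectional, ", tab[["autoloop"]], " autoloops\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.folded_graph <- function(x, ...) x$arcs

#' Plot a folded condition graph
#'
#' Draws conditions on a circle; feedback loops as double-headed curved
#' edges, unidirectional arcs as single arrows; nodes with an autoloop are
#' drawn filled.
#'
#' @param object A `folded_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.folded_graph <- function(object, ...) {
  conds <- object$conditions
  p <- length(conds)
  ang <- seq(0, 2 * pi, length.out = p + 1)[seq_len(p)]
  layout <- tibble::tibble(
    condition = conds, x = cos(ang), y = sin(ang),
    autoloop = conds %in% object$arcs$from[object$arcs$class == "autoloop"]
  )
  cross <- dplyr::filter(object$arcs, .data$class != "autoloop")
  seg <- dplyr::mutate(
    cross,
    x = layout$x[match(.data$from, conds)],
    y = layout$y[match(.data$from, conds)],
    xend = layout$x[match(.data$to, conds)],
    yend = layout$y[match(.data$to, conds)]
  )
  # shrink segments so arrows stop short of the node label
  shrink <- 0.12
  seg <- dplyr::mutate(seg,
    dx = .data$xend - .data$x, dy = .data$yend - .data$y,
    len = sqrt(.data$dx^2 + .data$dy^2),
    x = .data$x + shrink * .data$dx / .data$len,
    y = .data$y + shrink * .data$dy / .data$len,
    xend = .data$xend - shrink * .data$dx / .data$len,
    yend = .data$yend - shrink * .data$dy / .data$len
  )
  gg <- ggplot2::ggplot()
  if (nrow(seg) > 0) {
    gg <- gg + ggplot2::geom_curve(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        colour = .data$class
      ),
      curvature = 0.08,
      arrow = ggplot2::arrow(
        length = ggplot2::unit(6, "pt"),
        ends = ifelse(seg$class == "feedback", "both", "last")
      )
    )
  }
  gg +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$autoloop),
      size = 3
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = 1.18 * .data$x, y = 1.18 * .data$y, label = .data$condition),
      size = 3
    ) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1),
      name = "autoloop"
    ) +
    ggplot2::coord_equal(xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "arc class")
}

# igraph view of a folded graph (feedback loops expanded to both directions
# so renderers show them bidirectional).
folded_as_igraph <- function(folded) {
  a <- folded$arcs
  both <- dplyr::bind_rows(
    a,
    with(
      a[a$class == "feedback", ],
      tibble::tibble(from = to, to = from, class = class)
    )
  )
  g <- igraph::graph_from_data_frame(
    both[both$class != "autoloop", ],
    directed = TRUE,
    vertices = data.frame(
      name = folded$conditions,
      # character, not logical: the DOT writer only handles string attributes
      autoloop = ifelse(
        folded$conditions %in% a$from[a$class == "autoloop"], "yes", "no"
      )
    )
  )
  g
}
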