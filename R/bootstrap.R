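#' Bootstrap arc-strength estimation
#'
#' Model averaging for the two-slice DBN: draws `B` bootstrap resamples of
#' the lagged rows (with replacement, reduced to a fraction of the original
#' size), randomises the condition order in each resample (so tie-breaking
#' patterns cannot systematically favour any arc), learns a structure per
#' resample with [hill_climb()], and reports for every candidate arc the
#' fraction of resamples containing it — its strength, in `[0, 1]`. Each
#' resample uses an independent derived seed, so results are identical
#' regardless of execution order and the operation is parallelizable in
#' principle.
#'
#' @param lag_pairs A [build_lag_pairs()] design.
#' @param w Penalty coefficient (typically the tuned value).
#' @param B Number of bootstrap resamples (the reference analysis uses 500).
#' @param fraction Resample size as a fraction of `n` (default 0.75).
#' @param seed Integer seed.
#' @param replace Draw with replacement (default) or without.
#' @param penalty_unit,include_t0 See [score_dag()].
#' @return A tibble of class `arc_strength_table` covering all `p^2`
#'   candidate arcs (`from`, `to`, `strength`), sorted by decreasing
#'   strength; attributes `B`, `fraction`, `seed`, `conditions`.
#' @export
bootstrap_strengths <- function(lag_pairs, w, B = 500, fraction = 0.75,
                                seed = 1L, replace = TRUE,
                                penalty_unit = c("bic", "literal"),
                                include_t0 = TRUE) {
  stopifnot(B >= 1, fraction > 0, fraction <= 1)
  penalty_unit <- match.arg(penalty_unit)
  seed <- check_seed(seed)
  conds <- lag_conditions(lag_pairs)
  p <- length(conds)
  X <- lag_matrix(lag_pairs)
  n <- nrow(X)
  m <- ceiling(fraction * n)
  sub_seeds <- derive_seeds(seed, B)
  counts <- matrix(0L, p, p, dimnames = list(conds, conds)) # [from, to]
  for (b in seq_len(B)) {
    res <- withr::with_seed(sub_seeds[b], {
      rows <- sample.int(n, m, replace = replace)
      ord <- sample.int(p)
      list(rows = rows, ord = ord)
    })
    perm_conds <- conds[res$ord]
    Xb <- X[res$rows, c(res$ord, p + res$ord), drop = FALSE]
    df <- tibble::as_tibble(
      setNames(
        as.data.frame(Xb),
        c(paste0(perm_conds, "_t0"), paste0(perm_conds, "_t1"))
      )
    )
    dag <- hill_climb(new_lag_pairs(df, perm_conds), w,
                      penalty_unit = penalty_unit, include_t0 = include_t0)
    if (nrow(dag$arcs) > 0) {
      ij <- cbind(match(dag$arcs$from, conds), match(dag$arcs$to, conds))
      counts[ij] <- counts[ij] + 1L
    }
  }
  out <- tibble::tibble(
    from = conds[as.vector(row(counts))],
    to = conds[as.vector(col(counts))],
    strength = as.vector(counts) / B
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$strength),
                        match(.data$to, conds), match(.data$from, conds))
  attr(out, "B") <- B
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- seed
  attr(out, "conditions") <- conds
  class(out) <- c("arc_strength_table", class(out))
  out
}

#' @export
autoplot.arc_strength_table <- function(object, threshold = NULL, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    arc = factor(paste(.data$from, "→", .data$to),
                 levels = paste(.data$from, "→", .data$to)[order(.data$strength)])
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$strength, .data$arc)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "bootstrap inclusion frequency", y = NULL,
      title = "Arc strengths"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  }
  gg
}

# Length-weighted intervals of the strength ECDF over [0, 1]:
# F(x) = mean(strength <= x), piecewise constant.
strength_ecdf_steps <- function(s) {
  u <- sort(unique(s))
  knots <- unique(c(0, u, 1))
  lo <- knots[-length(knots)]
  hi <- knots[-1]
  f <- vapply(lo, function(x) mean(s <= x), 0)
  keep <- hi > lo
  list(value = f[keep], length = (hi - lo)[keep])
}

#' Data-driven significance threshold for arc strengths
#'
#' Estimates the strength above which arcs are considered significant by
#' comparing the empirical cumulative distribution of the strengths with the
#' ideal configuration in which noise arcs have strength 0 and significant
#' arcs strength 1 (whose CDF is flat at the noise fraction `t`). The noise
#' fraction minimizing the L1 distance to the empirical CDF is its
#' length-weighted median over `[0, 1]`; the threshold is the empirical
#' strength quantile at that level. Because any cut inside a gap of the
#' strength distribution selects the same arcs, the returned threshold is
#' the midpoint between that quantile and the next distinct strength.
#'
#' @param strengths An `arc_strength_table` (or any data frame with a
#'   `strength` column, or a bare numeric vector).
#' @param fallback Value returned (with a warning) when all strengths are
#'   identical and no separation exists.
#' @return A single threshold in `(0, 1)`; arcs with strength strictly
#'   greater than it are significant. The estimated noise fraction is
#'   attached as the `noise_fraction` attribute.
#' @export
#' @examples
#' estimate_threshold(c(0, 0, 0, 1, 1, 1))
estimate_threshold <- function(strengths, fallback = 0.5) {
  s <- if (is.numeric(strengths)) strengths else strengths$strength
  if (length(s) < 2) abort("need at least 2 strength values")
  if (any(s < 0 | s > 1)) abort("strengths must lie in [0, 1]")
  if (length(unique(s)) == 1) {
    warn("all strengths identical; no separation, returning fallback threshold")
    return(structure(fallback, noise_fraction = NA_real_))
  }
  steps <- strength_ecdf_steps(s)
  # weighted median of the ECDF values, weights = interval lengths
  ord <- order(steps$value)
  v <- steps$value[ord]
  cw <- cumsum(steps$length[ord])
  t_hat <- v[which(cw >= sum(steps$length) / 2)[1]]
  threshold_from_noise_fraction(s, t_hat)
}

threshold_from_noise_fraction <- function(s, t_hat) {
  # order statistic at the noise fraction, with an epsilon guard so that
  # t_hat * n landing on an integer is not pushed up by rounding error
  sorted <- sort(s)
  k <- floor(t_hat * length(s) + 1e-9)
  q <- if (k < 1) 0 else sorted[k]
  above <- sorted[sorted > q]
  upper <- if (length(above)) min(above) else 1
  structure((q + upper) / 2, noise_fraction = t_hat)
}

#' Grid-search cross-check for the threshold estimator
#'
#' Minimizes the L1 distance between the empirical strength CDF and the
#' ideal two-point CDF by brute force over a fine grid of noise fractions.
#' Serves as an independent check of the closed-form weighted-median
#' solution in [estimate_threshold()].
#'
#' @inheritParams estimate_threshold
#' @param grid Candidate noise fractions.
#' @return A threshold as in [estimate_threshold()].
#' @export
estimate_threshold_grid <- function(strengths,
                                    grid = seq(0, 1, by = 0.001)) {
  s <- if (is.numeric(strengths)) strengths else strengths$strength
  steps <- strength_ecdf_steps(s)
  l1 <- vapply(grid, function(t) sum(steps$length * abs(steps$value - t)), 0)
  t_hat <- grid[which.min(l1)]
  threshold_from_noise_fraction(s, t_hat)
}

#' Assemble the consensus graph from arc strengths
#'
#' Inserts arcs with strength strictly greater than the threshold in
#' decreasing order of strength (ties broken lexicographically), discarding
#' any arc that would introduce a directed cycle. For two-slice arcs, which
#' always point forward in time, the cycle rule can never fire — both
#' directions of a feedback pair survive, becoming a feedback loop after
#' folding — but it is enforced uniformly so the same routine serves the
#' static (single-slice) consensus, where opposite arcs do collide.
#'
#' @param strengths An `arc_strength_table` (two-slice) or a tibble of
#'   `from`/`to`/`strength` rows (static mode).
#' @param threshold Significance threshold in `(0, 1)`, usually from
#'   [estimate_threshold()].
#' @param mode `"two_slice"` (default) or `"static"`.
#' @param conditions Node set; defaults to the `conditions` attribute of
#'   `strengths` or the names appearing in it.
#' @return A [two_slice_dag()] in two-slice mode; in static mode a
#'   `static_dag` (list of `conditions` and `arcs`). Discarded cycle-forming
#'   arcs are recorded in the `discarded` attribute.
#' @export
consensus_dag <- function(strengths, threshold,
                          mode = c("two_slice", "static"),
                          conditions = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie in (0, 1)")
  }
  conds <- conditions %||% attr(strengths, "conditions") %||%
    sort(unique(c(strengths$from, strengths$to)))
  keep <- dplyr::filter(tibble::as_tibble(strengths), .data$strength > threshold)
  keep <- dplyr::arrange(keep, dplyr::desc(.data$strength),
                         match(.data$from, conds), match(.data$to, conds))
  p <- length(conds)
  # nodes: in two-slice mode arcs run t0 -> t1 between disjoint node copies
  adj <- matrix(FALSE, 2 * p, 2 * p)
  node_id <- function(cond, slice) match(cond, conds) + (slice == "t1") * p
  reaches <- function(a, b) {
    seen <- rep(FALSE, nrow(adj))
    stack <- a
    while (length(stack)) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (v == b) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(which(adj[v, ]), stack)
    }
    FALSE
  }
  kept <- rep(TRUE, nrow(keep))
  for (r in seq_len(nrow(keep))) {
    if (mode == "two_slice") {
      u <- node_id(keep$from[r], "t0")
      v <- node_id(keep$to[r], "t1")
    } else {
      u <- node_id(keep$from[r], "t0")
      v <- node_id(keep$to[r], "t0")
    }
    if (u == v || reaches(v, u)) {
      # a self-arc in static mode is itself a cycle; two-slice self-arcs
      # connect distinct node copies and never reach here
      kept[r] <- FALSE
    } else {
      adj[u, v] <- TRUE
    }
  }
  arcs <- keep[kept, c("from", "to")]
  discarded <- keep[!kept, ]
  if (mode == "two_slice") {
    out <- two_slice_dag(conds, arcs)
  } else {
    out <- structure(
      list(conditions = conds, arcs = tibble::as_tibble(arcs)),
      class = "static_dag"
    )
  }
  attr(out, "discarded") <- discarded
  out
}
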