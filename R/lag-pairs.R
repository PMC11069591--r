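#' Build the lagged two-slice design from a panel
#'
#' Pairs each county-week with the same county's next week, producing one
#' row per (county, consecutive week pair) with every condition observed at
#' the earlier slice (`*_t0` columns) and at the later slice (`*_t1`).
#' Under stationarity these rows are exchangeable observations of the
#' generic two-slice model, so a complete panel of `C` counties and `T`
#' weeks yields `C * (T - 1)` rows. Rows containing any missing value are
#' excluded.
#'
#' @param panel A panel tibble (post-imputation).
#' @return A tibble of class `lag_pairs` with columns `county`, `week`
#'   (the t0 week) and `<condition>_t0`, `<condition>_t1`; attribute
#'   `conditions` stores the condition order.
#' @export
build_lag_pairs <- function(panel) {
  check_panel(panel)
  conds <- panel_conditions(panel)
  panel <- dplyr::arrange(panel, .data$state, .data$county, .data$week)
  n <- nrow(panel)
  i0 <- seq_len(n - 1)
  keep <- panel$county[i0] == panel$county[i0 + 1] &
    panel$week[i0 + 1] == panel$week[i0] + 1
  i0 <- i0[keep]
  vals <- as.matrix(panel[conds])
  ok <- complete.cases(vals[i0, , drop = FALSE]) &
    complete.cases(vals[i0 + 1, , drop = FALSE])
  i0 <- i0[ok]
  if (length(i0) == 0) {
    abort("no county contributes a complete pair of consecutive weeks")
  }
  out <- tibble::tibble(county = panel$county[i0], week = panel$week[i0])
  for (j in seq_along(conds)) {
    out[[paste0(conds[j], "_t0")]] <- unname(vals[i0, j])
    out[[paste0(conds[j], "_t1")]] <- unname(vals[i0 + 1, j])
  }
  new_lag_pairs(out, conds)
}

#' Centre each county's series at its own mean
#'
#' Removes the time-constant county (and hence state) baseline from every
#' condition by subtracting the county-level mean, the two-slice analogue of
#' removing the random intercepts of the mixed-effects model. Recommended
#' before structure learning on spatially structured panels: the baseline
#' otherwise attenuates cross-condition effects and leaks spurious partial
#' dependence past the self-arc.
#'
#' @param panel A complete panel tibble.
#' @return The panel with county-centred condition columns.
#' @export
center_counties <- function(panel) {
  check_panel(panel)
  conds <- panel_conditions(panel)
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(panel, .data$county),
    dplyr::across(dplyr::all_of(conds), ~ .x - mean(.x))
  ))
}

new_lag_pairs <- function(df, conditions) {
  attr(df, "conditions") <- conditions
  class(df) <- c("lag_pairs", class(df))
  df
}

lag_conditions <- function(lag_pairs) {
  attr(lag_pairs, "conditions") %||%
    unique(sub("_t[01]$", "", grep("_t[01]$", names(lag_pairs), value = TRUE)))
}

# Numeric matrix [t0 columns, t1 columns] in condition order.
lag_matrix <- function(lag_pairs) {
  conds <- lag_conditions(lag_pairs)
  as.matrix(lag_pairs[c(paste0(conds, "_t0"), paste0(conds, "_t1"))])
}

# Augmented Gram matrix crossprod(cbind(1, t0, t1)) plus bookkeeping.
lag_gram <- function(lag_pairs) {
  X <- lag_matrix(lag_pairs)
  A <- cbind(1, X)
  list(
    G = crossprod(A),
    n = nrow(X),
    p = length(lag_conditions(lag_pairs)),
    conditions = lag_conditions(lag_pairs)
  )
}

# Gaussian profile log-likelihood of the OLS regression of t1 node `target`
# (index) on t0 nodes `parents` (indices), from the Gram matrix alone.
local_loglik <- function(gram, target, parents) {
  G <- gram$G
  n <- gram$n
  y <- 1L + gram$p + target
  idx <- c(1L, 1L + parents)
  R <- tryCatch(chol(G[idx, idx, drop = FALSE]), error = function(e) NULL)
  # a near-zero pivot means a rank-deficient (collinear) design that plain
  # chol() may numerically scrape through
  if (is.null(R) || min(diag(R)) <= sqrt(.Machine$double.eps) * max(diag(R))) {
    abort(
      paste0(
        "singular design for node ", gram$conditions[target],
        " with parents {",
        paste(gram$conditions[parents], collapse = ", "), "}"
      ),
      class = "dbnpanel_degenerate"
    )
  }
  z <- backsolve(R, G[idx, y], transpose = TRUE)
  rss <- max(G[y, y] - sum(z^2), n * 1e-300)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

# Marginal Gaussian log-likelihood of a t0 root node (index).
t0_loglik <- function(gram, i) {
  G <- gram$G
  n <- gram$n
  k <- 1L + i
  rss <- max(G[k, k] - G[1, k]^2 / n, n * 1e-300)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

penalty_per_param <- function(n, penalty_unit = c("bic", "literal")) {
  penalty_unit <- match.arg(penalty_unit)
  if (penalty_unit == "bic") log(n) / 2 else log(n)
}
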