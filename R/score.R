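#' Penalized log-likelihood score of a two-slice DAG
#'
#' Scores a candidate structure by the penalized Gaussian log-likelihood
#' `PL(D, w) = log L(D) - w * u(n) * p`, where `log L` sums each t1 node's
#' profile log-likelihood under its local OLS fit (plus, by default, the
#' marginal Gaussian fit of each t0 root node, a structure-independent
#' constant), `p` counts parameters (coefficients + intercept + residual
#' variance per node) and the penalty unit `u(n)` is `log(n)/2` so that
#' `w = 1` is the Bayesian Information Criterion
#' (`penalty_unit = "literal"` uses `log(n)` instead). The score decomposes
#' over nodes: changing one node's parent set changes only that node's term.
#'
#' @param dag A [two_slice_dag()] whose conditions match `lag_pairs`.
#' @param lag_pairs A [build_lag_pairs()] design.
#' @param w Penalty coefficient (`w >= 0`).
#' @param penalty_unit `"bic"` (default) or `"literal"`.
#' @param include_t0 Include the t0 marginal fits in the log-likelihood.
#' @return A list of class `dbn_score`: `loglik`, `n_params`, `n`, `w`,
#'   `penalized`, and `per_node` (tibble of local terms).
#' @export
score_dag <- function(dag, lag_pairs, w = 1,
                      penalty_unit = c("bic", "literal"),
                      include_t0 = TRUE) {
  stopifnot(inherits(dag, "two_slice_dag"), w >= 0)
  penalty_unit <- match.arg(penalty_unit)
  gram <- lag_gram(lag_pairs)
  if (!identical(dag$conditions, gram$conditions)) {
    abort("DAG conditions do not match the lag-pair columns")
  }
  u <- penalty_per_param(gram$n, penalty_unit)
  pa <- dag_parents(dag)
  per_node <- purrr::map_dfr(seq_len(gram$p), function(j) {
    parents <- match(pa[[j]], gram$conditions)
    ll <- local_loglik(gram, j, parents)
    k <- length(parents) + 2L
    tibble::tibble(
      node = paste0(gram$conditions[j], "_t1"),
      n_parents = length(parents), loglik = ll, n_params = k
    )
  })
  if (include_t0) {
    t0 <- purrr::map_dfr(seq_len(gram$p), function(i) {
      tibble::tibble(
        node = paste0(gram$conditions[i], "_t0"),
        n_parents = 0L, loglik = t0_loglik(gram, i), n_params = 2L
      )
    })
    per_node <- dplyr::bind_rows(per_node, t0)
  }
  loglik <- sum(per_node$loglik)
  n_params <- sum(per_node$n_params)
  structure(
    list(
      loglik = loglik, n_params = n_params, n = gram$n, w = w,
      penalty_unit = penalty_unit,
      penalized = loglik - w * u * n_params,
      per_node = per_node
    ),
    class = "dbn_score"
  )
}

#' @export
print.dbn_score <- function(x, ...) {
  cat(
    "<dbn_score> penalized = ", format(x$penalized, digits = 8),
    " (loglik ", format(x$loglik, digits = 8), ", ", x$n_params,
    " parameters, n = ", x$n, ", w = ", x$w, ")\n",
    sep = ""
  )
  invisible(x)
}
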