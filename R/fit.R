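#' Maximum-likelihood fit of a two-slice DBN
#'
#' Fits each t1 node's local linear-Gaussian model by OLS (which is the MLE
#' here): intercept, one coefficient per parent, and the residual variance
#' with the maximum-likelihood denominator `n`. The marginal Gaussian
#' parameters of the t0 nodes, and the observed t0 rows, are stored so the
#' fitted model can be used generatively.
#'
#' @param dag A [two_slice_dag()].
#' @param lag_pairs A [build_lag_pairs()] design.
#' @return An object of class `dbn_fit`: list with `dag`, `nodes` (per t1
#'   node: `intercept`, `coefficients` named by parent, `sigma2`),
#'   `t0_mean`, `t0_var` (MLE marginals), `t0_data` (matrix of observed t0
#'   rows), `n`.
#' @export
fit_dbn <- function(dag, lag_pairs) {
  stopifnot(inherits(dag, "two_slice_dag"))
  conds <- lag_conditions(lag_pairs)
  if (!identical(dag$conditions, conds)) {
    abort("DAG conditions do not match the lag-pair columns")
  }
  X <- lag_matrix(lag_pairs)
  p <- length(conds)
  n <- nrow(X)
  t0 <- X[, seq_len(p), drop = FALSE]
  t1 <- X[, p + seq_len(p), drop = FALSE]
  colnames(t0) <- colnames(t1) <- conds
  pa <- dag_parents(dag)
  nodes <- purrr::map(seq_len(p), function(j) {
    parents <- pa[[j]]
    A <- cbind(`(Intercept)` = 1, t0[, parents, drop = FALSE])
    fit <- lm.fit(A, t1[, j])
    if (fit$rank < ncol(A)) {
      abort(
        paste0("singular design for node ", conds[j]),
        class = "dbnpanel_degenerate"
      )
    }
    cf <- fit$coefficients
    list(
      intercept = unname(cf[1]),
      coefficients = cf[-1],
      sigma2 = sum(fit$residuals^2) / n
    )
  })
  names(nodes) <- conds
  structure(
    list(
      dag = dag, nodes = nodes,
      t0_mean = colMeans(t0),
      t0_var = apply(t0, 2, function(x) mean((x - mean(x))^2)),
      t0_data = t0, n = n
    ),
    class = "dbn_fit"
  )
}

#' @export
print.dbn_fit <- function(x, ...) {
  cat(
    "<dbn_fit> ", length(x$dag$conditions), " conditions, ",
    n_arcs(x$dag), " arcs, fitted on n = ", x$n, " lagged rows\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.dbn_fit <- function(x, ...) {
  purrr::map_dfr(names(x$nodes), function(cc) {
    nd <- x$nodes[[cc]]
    tibble::tibble(
      target = cc,
      term = c("(Intercept)", names(nd$coefficients)),
      estimate = c(nd$intercept, unname(nd$coefficients))
    )
  })
}

#' @export
glance.dbn_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_conditions = length(x$dag$conditions),
    n_arcs = n_arcs(x$dag),
    mean_sigma2 = mean(vapply(x$nodes, function(nd) nd$sigma2, 0))
  )
}

#' Per-condition R-squared of a fitted DBN
#'
#' Evaluates, on the supplied rows (training or held-out), the proportion of
#' each condition's variance at t1 explained by its fitted linear predictor
#' from the previous slice; the cross-condition average is the model's
#' headline predictive accuracy.
#'
#' @param fit A [fit_dbn()] object.
#' @param lag_pairs Evaluation rows (a [build_lag_pairs()] design over the
#'   same conditions).
#' @return A tibble (`condition`, `r2`); `r2` is `NA` where the target has
#'   zero variance on the evaluation rows. The cross-condition mean of the
#'   defined values is stored in the `average` attribute.
#' @export
predict_r2 <- function(fit, lag_pairs) {
  stopifnot(inherits(fit, "dbn_fit"))
  conds <- lag_conditions(lag_pairs)
  if (!identical(fit$dag$conditions, conds)) {
    abort("fit conditions do not match the lag-pair columns")
  }
  X <- lag_matrix(lag_pairs)
  p <- length(conds)
  t0 <- X[, seq_len(p), drop = FALSE]
  colnames(t0) <- conds
  out <- purrr::map_dfr(seq_len(p), function(j) {
    nd <- fit$nodes[[j]]
    y <- X[, p + j]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) {
      return(tibble::tibble(condition = conds[j], r2 = NA_real_))
    }
    pred <- nd$intercept +
      as.vector(t0[, names(nd$coefficients), drop = FALSE] %*% nd$coefficients)
    tibble::tibble(condition = conds[j], r2 = 1 - sum((y - pred)^2) / tss)
  })
  attr(out, "average") <- mean(out$r2, na.rm = TRUE)
  out
}

#' Tune the sparsity penalty on a temporal split
#'
#' Learns a DBN for each penalty `w` on the weeks before `split_week`,
#' evaluates the average R-squared on the remaining weeks, and selects the
#' largest `w` whose validation accuracy ratio against the `w = 1` model
#' still exceeds `ratio_floor` — i.e. the sparsest model whose predictive
#' accuracy is essentially undiminished.
#'
#' @param panel A complete panel tibble.
#' @param w_grid Penalty grid (default the doubling grid 1..128).
#' @param split_week First validation week (default 52: first year trains).
#' @param ratio_floor Minimum acceptable validation accuracy ratio vs the
#'   least-penalized model (default 0.999).
#' @param penalty_unit,include_t0 See [score_dag()].
#' @return A list of class `dbn_tuning`: `table` (tibble with `w`,
#'   `n_arcs`, `train_r2`, `val_r2`, `accuracy_ratio`), `chosen_w`,
#'   `split_week`, and `dags` (the learned structure per `w`).
#' @export
tune_penalty <- function(panel, w_grid = c(1, 2, 4, 8, 16, 32, 64, 128),
                         split_week = 52, ratio_floor = 0.999,
                         penalty_unit = c("bic", "literal"),
                         include_t0 = TRUE) {
  check_panel(panel)
  penalty_unit <- match.arg(penalty_unit)
  weeks <- sort(unique(panel$week))
  if (sum(weeks < split_week) < 2 || sum(weeks >= split_week) < 2) {
    abort("`split_week` must leave at least 2 weeks on each side")
  }
  train <- build_lag_pairs(panel[panel$week < split_week, ])
  val <- build_lag_pairs(panel[panel$week >= split_week, ])
  w_grid <- sort(w_grid)
  dags <- list()
  tab <- purrr::map_dfr(seq_along(w_grid), function(i) {
    dag <- hill_climb(train, w_grid[i], penalty_unit = penalty_unit,
                      include_t0 = include_t0)
    dags[[i]] <<- dag
    fit <- fit_dbn(dag, train)
    tibble::tibble(
      w = w_grid[i],
      n_arcs = n_arcs(dag),
      train_r2 = attr(predict_r2(fit, train), "average"),
      val_r2 = attr(predict_r2(fit, val), "average")
    )
  })
  ref <- tab$val_r2[which.min(tab$w)]
  tab$accuracy_ratio <- tab$val_r2 / ref
  eligible <- tab$w[tab$accuracy_ratio > ratio_floor]
  chosen <- if (length(eligible)) max(eligible) else min(tab$w)
  structure(
    list(
      table = tab, chosen_w = chosen, split_week = split_week,
      dags = setNames(dags, tab$w)
    ),
    class = "dbn_tuning"
  )
}

#' @export
print.dbn_tuning <- function(x, ...) {
  cat("<dbn_tuning> chosen w =", x$chosen_w, "\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.dbn_tuning <- function(x, ...) x$table

#' @export
glance.dbn_tuning <- function(x, ...) {
  tibble::tibble(
    chosen_w = x$chosen_w,
    split_week = x$split_week,
    n_arcs_chosen = x$table$n_arcs[x$table$w == x$chosen_w]
  )
}

#' Plot the penalty-tuning profile
#'
#' Training and validation average R-squared against the penalty
#' coefficient (log2 axis), annotated with arc counts; the chosen penalty
#' is marked.
#'
#' @param object A [tune_penalty()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dbn_tuning <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$table[c("w", "train_r2", "val_r2")],
    -"w",
    names_to = "set", values_to = "r2"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$w, .data$r2, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_w, linetype = 2) +
    ggplot2::geom_text(
      data = object$table,
      ggplot2::aes(.data$w, max(long$r2), label = .data$n_arcs),
      inherit.aes = FALSE, vjust = -0.4, size = 3
    ) +
    ggplot2::scale_x_continuous(trans = "log2", breaks = object$table$w) +
    ggplot2::labs(
      x = "penalty coefficient w",
      y = "average explained variance (R²)",
      colour = NULL,
      title = "Predictive accuracy vs penalty",
      subtitle = "labels: arcs in the learned DAG; dashed line: chosen w"
    ) +
    ggplot2::theme_minimal()
}
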