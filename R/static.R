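#' Remove the spatio-temporal structure from a panel
#'
#' Subtracts, per condition, the predicted state and county random
#' intercepts of the nested mixed-effects model (see
#' [variance_decomposition()]); optionally also pre-whitens the within-county
#' series with the estimated lag-1 autocorrelation. Used to learn a second
#' static network from de-structured data in the misspecification audit.
#'
#' @param panel A complete panel tibble.
#' @param prewhiten Also remove order-1 serial dependence (off by default).
#' @return A panel of the same shape with residualized condition values.
#' @export
remove_spatiotemporal <- function(panel, prewhiten = FALSE) {
  check_panel(panel)
  conds <- panel_conditions(panel)
  panel <- dplyr::arrange(panel, .data$state, .data$county, .data$week)
  out <- panel
  for (cc in conds) {
    df <- data.frame(
      y = panel[[cc]], state = panel$state, county = panel$county
    )
    if (anyNA(df$y)) abort(paste0("condition ", cc, " has missing values"))
    fit <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | state) + (1 | county),
      data = df, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")
    ))
    re <- lme4::ranef(fit)
    pred_re <- re$state[as.character(df$state), 1] +
      re$county[as.character(df$county), 1]
    v <- df$y - pred_re
    if (prewhiten) {
      r <- residuals(fit)
      same <- df$county[-1] == df$county[-nrow(df)]
      phi <- cor(r[-1][same], r[-length(r)][same])
      centre <- mean(v)
      u <- v - centre
      lagged <- c(0, u[-length(u)])
      first <- c(TRUE, !same)
      v <- ifelse(first, u * sqrt(1 - phi^2), u - phi * lagged) + centre
    }
    out[[cc]] <- v
  }
  out
}

#' Learn a static (single-slice) Bayesian network
#'
#' Classical BN structure learning in which variables are not replicated
#' across time points: greedy hill climbing over arc additions, deletions
#' and reversals under an acyclicity constraint, with the same penalized
#' Gaussian score family as the dynamic search. Rows are individual
#' county-weeks.
#'
#' @param data A data frame of condition columns (rows = county-weeks), or a
#'   panel tibble (index columns are dropped).
#' @param w Penalty coefficient.
#' @param penalty_unit See [score_dag()].
#' @return A `static_dag`: list with `conditions` and `arcs` (tibble
#'   `from`/`to`), acyclic by construction.
#' @export
learn_static <- function(data, w = 1, penalty_unit = c("bic", "literal")) {
  penalty_unit <- match.arg(penalty_unit)
  if (all(panel_index_cols %in% names(data))) {
    data <- data[setdiff(names(data), panel_index_cols)]
  }
  X <- as.matrix(data)
  conds <- colnames(X)
  p <- ncol(X)
  n <- nrow(X)
  A <- cbind(1, X)
  G <- crossprod(A)
  step_cost <- w * penalty_per_param(n, penalty_unit)
  ll <- function(j, parents) {
    idx <- c(1L, 1L + parents)
    y <- 1L + j
    R <- tryCatch(chol(G[idx, idx, drop = FALSE]), error = function(e) NULL)
    if (is.null(R) ||
        min(diag(R)) <= sqrt(.Machine$double.eps) * max(diag(R))) {
      abort(paste0("singular design for node ", conds[j]),
            class = "dbnpanel_degenerate")
    }
    z <- backsolve(R, G[idx, y], transpose = TRUE)
    rss <- max(G[y, y] - sum(z^2), n * 1e-300)
    -n / 2 * (log(2 * pi * rss / n) + 1)
  }
  pa <- rep(list(integer()), p)
  node_ll <- vapply(seq_len(p), function(j) ll(j, integer()), 0)
  adj <- matrix(FALSE, p, p)
  reaches <- function(a, b) {
    seen <- rep(FALSE, p)
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
  repeat {
    best <- list(delta = 1e-9)
    for (j in seq_len(p)) {       # deterministic: (target, source, op) order
      for (s in seq_len(p)) {
        if (s == j) next
        if (adj[s, j]) {
          # delete s -> j
          cand <- setdiff(pa[[j]], s)
          d <- ll(j, cand) - node_ll[j] + step_cost
          if (d > best$delta) best <- list(delta = d, op = "del", s = s, j = j)
          # reverse s -> j (becomes j -> s); parameter count unchanged
          if (!reaches_without(adj, s, j, j, s)) {
            d2 <- (ll(j, cand) - node_ll[j]) +
              (ll(s, sort(c(pa[[s]], j))) - node_ll[s])
            if (d2 > best$delta) best <- list(delta = d2, op = "rev", s = s, j = j)
          }
        } else {
          # add s -> j unless it creates a cycle (incl. the 2-cycle case)
          if (adj[j, s] || reaches(j, s)) next
          cand <- sort(c(pa[[j]], s))
          d <- ll(j, cand) - node_ll[j] - step_cost
          if (d > best$delta) best <- list(delta = d, op = "add", s = s, j = j)
        }
      }
    }
    if (is.null(best$op)) break
    s <- best$s; j <- best$j
    if (best$op == "add") {
      pa[[j]] <- sort(c(pa[[j]], s))
      adj[s, j] <- TRUE
    } else if (best$op == "del") {
      pa[[j]] <- setdiff(pa[[j]], s)
      adj[s, j] <- FALSE
    } else {
      pa[[j]] <- setdiff(pa[[j]], s)
      pa[[s]] <- sort(c(pa[[s]], j))
      adj[s, j] <- FALSE
      adj[j, s] <- TRUE
    }
    node_ll <- vapply(seq_len(p), function(k) ll(k, pa[[k]]), 0)
  }
  arcs <- purrr::map_dfr(seq_len(p), function(j) {
    if (length(pa[[j]]) == 0) return(NULL)
    tibble::tibble(from = conds[pa[[j]]], to = conds[j])
  })
  structure(
    list(conditions = conds,
         arcs = if (nrow(arcs)) arcs else
           tibble::tibble(from = character(), to = character())),
    class = "static_dag"
  )
}

# would reversing drop->dropj and adding addfrom->addto leave a cycle?
reaches_without <- function(adj, drop_s, drop_j, new_from, new_to) {
  adj[drop_s, drop_j] <- FALSE
  p <- nrow(adj)
  seen <- rep(FALSE, p)
  stack <- new_to
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v == new_from) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(which(adj[v, ]), stack)
  }
  FALSE
}

#' @export
print.static_dag <- function(x, ...) {
  cat(
    "<static_dag> ", length(x$conditions), " conditions, ",
    nrow(x$arcs), " arcs (acyclic)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.static_dag <- function(x, ...) x$arcs

#' Fit the local regressions of a static BN
#'
#' OLS per node on its parents, as in [fit_dbn()] but on single-slice rows.
#'
#' @param dag A `static_dag`.
#' @param data Condition columns (rows = county-weeks) or a panel tibble.
#' @return A `static_fit` with per-node intercept, coefficients and MLE
#'   residual variance.
#' @export
fit_static <- function(dag, data) {
  stopifnot(inherits(dag, "static_dag"))
  if (all(panel_index_cols %in% names(data))) {
    data <- data[setdiff(names(data), panel_index_cols)]
  }
  X <- as.matrix(data)[, dag$conditions, drop = FALSE]
  n <- nrow(X)
  pa <- split(dag$arcs$from, factor(dag$arcs$to, levels = dag$conditions))
  nodes <- purrr::map(dag$conditions, function(cc) {
    parents <- pa[[cc]]
    A <- cbind(`(Intercept)` = 1, X[, parents, drop = FALSE])
    fit <- lm.fit(A, X[, cc])
    if (fit$rank < ncol(A)) {
      abort(paste0("singular design for node ", cc),
            class = "dbnpanel_degenerate")
    }
    list(
      intercept = unname(fit$coefficients[1]),
      coefficients = fit$coefficients[-1],
      sigma2 = sum(fit$residuals^2) / n
    )
  })
  names(nodes) <- dag$conditions
  structure(list(dag = dag, nodes = nodes, n = n), class = "static_fit")
}

#' @export
tidy.static_fit <- function(x, ...) {
  purrr::map_dfr(names(x$nodes), function(cc) {
    nd <- x$nodes[[cc]]
    if (length(nd$coefficients) == 0) return(NULL)
    tibble::tibble(
      target = cc, term = names(nd$coefficients),
      estimate = unname(nd$coefficients)
    )
  })
}

#' Compare regression coefficients before and after de-structuring
#'
#' Over the arcs shared by a static fit on raw data and one on
#' de-structured data, reports the fraction of coefficients inflated by a
#' factor of at least two (`|beta_raw| >= 2 |beta_resid|`) and the fraction
#' whose sign differs. By default the intersection of the two arc sets is
#' used; with `arcs = "union"` a coefficient absent from one fit is treated
#' as 0 for the inflation comparison and excluded from the sign comparison.
#'
#' @param fit_raw,fit_resid `static_fit` objects (or `dbn_fit`s).
#' @param arcs `"intersection"` (default) or `"union"`.
#' @return A list of class `coef_comparison`: `inflated_fraction`,
#'   `sign_flip_fraction`, `n_arcs`, `arcs_mode`, `detail` (per-coefficient
#'   tibble).
#' @export
compare_coefficients <- function(fit_raw, fit_resid,
                                 arcs = c("intersection", "union")) {
  arcs <- match.arg(arcs)
  t_raw <- dplyr::rename(tidy(fit_raw), beta_raw = "estimate")
  t_res <- dplyr::rename(tidy(fit_resid), beta_resid = "estimate")
  t_raw <- t_raw[t_raw$term != "(Intercept)", ]
  t_res <- t_res[t_res$term != "(Intercept)", ]
  detail <- if (arcs == "intersection") {
    dplyr::inner_join(t_raw, t_res, by = c("target", "term"))
  } else {
    merged <- dplyr::full_join(t_raw, t_res, by = c("target", "term"))
    merged$beta_raw[is.na(merged$beta_raw)] <- 0
    merged$beta_resid[is.na(merged$beta_resid)] <- 0
    merged
  }
  if (nrow(detail) == 0) {
    warn("no shared coefficients; comparison undefined")
    return(structure(
      list(inflated_fraction = NA_real_, sign_flip_fraction = NA_real_,
           n_arcs = 0L, arcs_mode = arcs, detail = detail),
      class = "coef_comparison"
    ))
  }
  detail$inflated <- abs(detail$beta_raw) >= 2 * abs(detail$beta_resid)
  sign_ok <- detail$beta_raw != 0 & detail$beta_resid != 0
  detail$sign_flip <- ifelse(
    sign_ok, sign(detail$beta_raw) != sign(detail$beta_resid), NA
  )
  structure(
    list(
      inflated_fraction = mean(detail$inflated),
      sign_flip_fraction = mean(detail$sign_flip, na.rm = TRUE),
      n_arcs = nrow(detail),
      arcs_mode = arcs,
      detail = tibble::as_tibble(detail)
    ),
    class = "coef_comparison"
  )
}

#' @export
print.coef_comparison <- function(x, ...) {
  cat(
    "<coef_comparison> (", x$arcs_mode, ", ", x$n_arcs, " coefficients) ",
    "inflated >= 2x: ", format(100 * x$inflated_fraction, digits = 3),
    "%; sign flips: ", format(100 * x$sign_flip_fraction, digits = 3), "%\n",
    sep = ""
  )
  invisible(x)
}

#' Classify static-BN arcs against the folded dynamic graph
#'
#' Taking the folded dynamic network as the reference model, each static arc
#' `X -> Y` is `correct` if the folded graph has a unidirectional `X -> Y`,
#' `feedback_collapsed` if it has a feedback loop `X <-> Y` (a cycle a
#' static DAG cannot express), `reversed` if it has only `Y -> X`, and
#' `spurious` if the pair is unconnected. Autoloops in the folded graph are
#' ignored.
#'
#' @param static_dag A `static_dag`.
#' @param folded_dynamic A `folded_graph`.
#' @return A list of class `arc_classification`: `counts` and `fractions`
#'   (named: correct, feedback_collapsed, reversed, spurious), `n_arcs`,
#'   `detail` tibble.
#' @export
classify_arcs <- function(static_dag, folded_dynamic) {
  stopifnot(inherits(static_dag, "static_dag"),
            inherits(folded_dynamic, "folded_graph"))
  if (!setequal(static_dag$conditions, folded_dynamic$conditions)) {
    abort("condition sets differ between the static and folded graphs")
  }
  fa <- folded_dynamic$arcs[folded_dynamic$arcs$class != "autoloop", ]
  uni_key <- paste(fa$from[fa$class == "unidirectional"],
                   fa$to[fa$class == "unidirectional"])
  fb_key <- c(paste(fa$from[fa$class == "feedback"], fa$to[fa$class == "feedback"]),
              paste(fa$to[fa$class == "feedback"], fa$from[fa$class == "feedback"]))
  sa <- static_dag$arcs
  cls <- vapply(seq_len(nrow(sa)), function(r) {
    k <- paste(sa$from[r], sa$to[r])
    krev <- paste(sa$to[r], sa$from[r])
    if (k %in% fb_key) "feedback_collapsed"
    else if (k %in% uni_key) "correct"
    else if (krev %in% uni_key) "reversed"
    else "spurious"
  }, "")
  levels <- c("correct", "feedback_collapsed", "reversed", "spurious")
  counts <- table(factor(cls, levels = levels))
  structure(
    list(
      counts = setNames(as.integer(counts), levels),
      fractions = setNames(as.numeric(counts) / max(nrow(sa), 1), levels),
      n_arcs = nrow(sa),
      detail = dplyr::mutate(sa, class = cls)
    ),
    class = "arc_classification"
  )
}

#' @export
print.arc_classification <- function(x, ...) {
  cat("<arc_classification> ", x$n_arcs, " static arcs\n", sep = "")
  for (k in names(x$fractions)) {
    cat(sprintf("  %-18s %3d  (%.1f%%)\n", k, x$counts[[k]],
                100 * x$fractions[[k]]))
  }
  invisible(x)
}

#' @export
tidy.arc_classification <- function(x, ...) {
  tibble::tibble(
    class = names(x$counts),
    n = unname(x$counts),
    fraction = unname(x$fractions)
  )
}
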