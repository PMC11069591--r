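# Averaged-over-orderings (LMG-style) explained-variance attribution.
# `fixed` columns are always entered first; the remaining columns'
# contributions are incremental explained-variance gains averaged over all
# orderings, computed by subset enumeration. Returns incremental R^2 per
# term (they telescope to the full model's R^2).
lmg_attribution <- function(y, X, fixed = character()) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  keep <- is.finite(y) & apply(X, 1, function(r) all(is.finite(r)))
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  A <- cbind(1, X, y)
  G <- crossprod(A)
  tss <- max(G[ncol(A), ncol(A)] - G[1, ncol(A)]^2 / n, 0)
  if (tss == 0) abort("target has zero variance", class = "dbnpanel_degenerate")
  k_all <- ncol(X)
  rss <- function(cols) { # cols: indices into X's columns
    idx <- c(1L, 1L + cols)
    R <- chol(G[idx, idx, drop = FALSE])
    z <- backsolve(R, G[idx, ncol(A)], transpose = TRUE)
    max(G[ncol(A), ncol(A)] - sum(z^2), 0)
  }
  fixed_idx <- match(fixed, colnames(X))
  free_idx <- setdiff(seq_len(k_all), fixed_idx)
  m <- length(free_idx)
  ess_memo <- new.env(parent = emptyenv())
  ess <- function(free_cols) { # incremental-R2 scale
    key <- paste0("s", paste(free_cols, collapse = ","))
    got <- ess_memo[[key]]
    if (is.null(got)) {
      got <- (tss - rss(c(fixed_idx, free_cols))) / tss
      ess_memo[[key]] <- got
    }
    got
  }
  raw_fixed <- if (length(fixed_idx)) (tss - rss(fixed_idx)) / tss else 0
  raw_free <- setNames(numeric(m), colnames(X)[free_idx])
  if (m > 0) {
    for (jj in seq_len(m)) {
      j <- free_idx[jj]
      others <- free_idx[-jj]
      mo <- length(others)
      total <- 0
      for (mask in 0:(2^max(mo, 0) - 1)) {
        S <- others[bitwAnd(mask, bitwShiftL(1L, seq_len(mo) - 1L)) > 0]
        wgt <- factorial(length(S)) * factorial(m - length(S) - 1) / factorial(m)
        total <- total + wgt * (ess(sort(c(S, j))) - ess(sort(S)))
      }
      raw_free[jj] <- total
    }
  }
  list(
    raw_fixed = raw_fixed,
    raw_free = raw_free,
    total = raw_fixed + sum(raw_free) # telescopes to the full model's R^2
  )
}

#' Parent variance shares of a fitted DBN node
#'
#' Measures each parent's contribution to the explained variance of the
#' target's local regression (ANOVA-style). The self-parent (the target's
#' own previous value) is entered first; the remaining parents'
#' contributions are incremental explained-variance gains averaged over all
#' orderings of the non-self parents, which makes the attribution exactly
#' order-invariant. Because autocorrelations dominate numerically, shares
#' are normalized over the non-self parents only, omitting the condition's
#' own contribution.
#'
#' @param fit A [fit_dbn()] object.
#' @param lag_pairs Rows on which to attribute (typically the training
#'   design or a simulated sample).
#' @param target Condition name.
#' @return A tibble of class `variance_share_report` with columns `parent`,
#'   `role` (`"self"`/`"other"`), `raw_ev` (incremental proportion of the
#'   target's variance explained) and `share` (normalized over non-self
#'   parents; `NA` for the self row). Attributes: `target`,
#'   `total_explained` (the full local model's R-squared), `note`.
#' @export
parent_variance_shares <- function(fit, lag_pairs, target) {
  stopifnot(inherits(fit, "dbn_fit"))
  conds <- fit$dag$conditions
  if (!target %in% conds) abort(paste0("unknown condition ", target))
  parents <- dag_parents(fit$dag)[[target]]
  if (length(parents) == 0) {
    abort(paste0("target ", target, " has no parents"))
  }
  X <- lag_matrix(lag_pairs)
  p <- length(conds)
  y <- X[, p + match(target, conds)]
  XP <- X[, match(parents, conds), drop = FALSE]
  colnames(XP) <- parents
  fixed <- intersect(target, parents)
  att <- lmg_attribution(y, XP, fixed = fixed)
  others <- setdiff(parents, fixed)
  total <- att$raw_fixed + sum(att$raw_free)
  share_base <- sum(att$raw_free)
  out <- dplyr::bind_rows(
    if (length(fixed)) tibble::tibble(
      parent = fixed, role = "self", raw_ev = att$raw_fixed, share = NA_real_
    ),
    if (length(others)) tibble::tibble(
      parent = others, role = "other",
      raw_ev = unname(att$raw_free[others]),
      share = if (share_base > 0) unname(att$raw_free[others]) / share_base
              else NA_real_
    )
  )
  attr(out, "target") <- target
  attr(out, "total_explained") <- total
  attr(out, "note") <- if (length(others) == 0) {
    "only parent is the condition itself; no non-self shares to report"
  }
  class(out) <- c("variance_share_report", class(out))
  out
}

#' @export
autoplot.variance_share_report <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$role == "other")
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$parent, .data$share),
      y = .data$share
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "share of explained variance (self excluded)",
      title = paste0("Parents of ", attr(object, "target"))
    ) +
    ggplot2::theme_minimal()
}

#' Simulate joint two-slice samples from a fitted DBN
#'
#' Uses the fitted model generatively: the t0 slice is drawn either by
#' resampling the observed t0 rows (default, preserving their joint
#' distribution) or from the fitted marginal Gaussians; the t1 slice is then
#' drawn from each node's linear-Gaussian local model.
#'
#' @param fit A [fit_dbn()] object.
#' @param n_samples Number of joint samples.
#' @param t0_source `"empirical"` or `"gaussian"`.
#' @param seed Integer seed.
#' @return A `lag_pairs`-shaped tibble of simulated `*_t0` / `*_t1` columns,
#'   usable by [predict_r2()] and [parent_variance_shares()].
#' @export
simulate_from_dbn <- function(fit, n_samples,
                              t0_source = c("empirical", "gaussian"),
                              seed = 1L) {
  stopifnot(inherits(fit, "dbn_fit"))
  t0_source <- match.arg(t0_source)
  seed <- check_seed(seed)
  conds <- fit$dag$conditions
  p <- length(conds)
  withr::with_seed(seed, {
    t0 <- if (t0_source == "empirical") {
      fit$t0_data[sample.int(nrow(fit$t0_data), n_samples, replace = TRUE), ,
                  drop = FALSE]
    } else {
      sapply(conds, function(cc) {
        rnorm(n_samples, fit$t0_mean[cc], sqrt(fit$t0_var[cc]))
      })
    }
    colnames(t0) <- conds
    t1 <- sapply(conds, function(cc) {
      nd <- fit$nodes[[cc]]
      mu <- nd$intercept +
        if (length(nd$coefficients)) {
          as.vector(t0[, names(nd$coefficients), drop = FALSE] %*%
                      nd$coefficients)
        } else 0
      mu + rnorm(n_samples, 0, sqrt(nd$sigma2))
    })
  })
  df <- tibble::as_tibble(
    setNames(
      as.data.frame(cbind(t0, t1)),
      c(paste0(conds, "_t0"), paste0(conds, "_t1"))
    )
  )
  new_lag_pairs(df, conds)
}

#' Quartile-stratified same-week variance share
#'
#' Probes whether an apparent same-week association between a focal
#' condition and a target is carried by a stratifying condition: simulates
#' joint samples from the fitted DBN, augments the target's regression with
#' the focal condition at t1 (the learned model has no instantaneous arcs,
#' so this is how a same-week association is operationalized), and reports
#' the focal condition's normalized explained-variance share — overall and
#' within strata defined by the stratifier's t0 quartiles (low = bottom
#' quartile, average = middle two, high = top quartile) on the simulated
#' distribution. A share that collapses within every stratum indicates the
#' unstratified association is carried by the stratifier.
#'
#' The stratifier is controlled by the stratification itself and is
#' therefore excluded from the regressor set (inside a stratum its variance
#' is what the analysis deliberately restricts): in a linear-Gaussian model,
#' keeping it as a linear regressor as well would make the focal share
#' identically zero in and out of every stratum, leaving nothing for the
#' stratified comparison to detect.
#'
#' @param fit A [fit_dbn()] object.
#' @param target,focal,stratifier Distinct condition names.
#' @param n_sim Number of simulated samples (default 1e5).
#' @param seed Integer seed.
#' @param t0_source See [simulate_from_dbn()].
#' @param quartile_source Quartiles from the `"simulated"` (default) or
#'   `"empirical"` stratifier distribution.
#' @return A tibble of class `stratified_share`: `stratum`
#'   (`"unstratified"`, `"low"`, `"average"`, `"high"`), `share` (focal's
#'   normalized explained-variance share; `NA` if the stratum is
#'   degenerate), `n` (samples in the stratum).
#' @export
stratified_share <- function(fit, target, focal, stratifier,
                             n_sim = 1e5, seed = 1L,
                             t0_source = c("empirical", "gaussian"),
                             quartile_source = c("simulated", "empirical")) {
  stopifnot(inherits(fit, "dbn_fit"))
  quartile_source <- match.arg(quartile_source)
  t0_source <- match.arg(t0_source)
  if (length(unique(c(target, focal, stratifier))) != 3) {
    abort("`target`, `focal` and `stratifier` must be three distinct conditions")
  }
  conds <- fit$dag$conditions
  stopifnot(all(c(target, focal, stratifier) %in% conds))
  sims <- simulate_from_dbn(fit, n_sim, t0_source = t0_source, seed = seed)
  s0 <- sims[[paste0(stratifier, "_t0")]]
  qs <- if (quartile_source == "simulated") {
    quantile(s0, c(0.25, 0.75), names = FALSE)
  } else {
    quantile(fit$t0_data[, stratifier], c(0.25, 0.75), names = FALSE)
  }
  strat_of <- ifelse(s0 <= qs[1], "low", ifelse(s0 > qs[2], "high", "average"))
  parents <- setdiff(dag_parents(fit$dag)[[target]], stratifier)
  y_all <- sims[[paste0(target, "_t1")]]
  X_all <- cbind(
    as.matrix(sims[paste0(focal, "_t1")]),
    if (length(parents)) as.matrix(sims[paste0(parents, "_t0")])
  )
  colnames(X_all) <- c(paste0(focal, "_t1"), paste0(parents, "_t0"))
  fixed <- if (target %in% parents) paste0(target, "_t0") else character()
  focal_col <- paste0(focal, "_t1")

  share_in <- function(rows) {
    if (length(rows) < ncol(X_all) + 2) return(NA_real_)
    y <- y_all[rows]
    X <- X_all[rows, , drop = FALSE]
    if (var(y) == 0 || any(apply(X, 2, var) == 0)) return(NA_real_)
    att <- tryCatch(
      lmg_attribution(y, X, fixed = fixed),
      dbnpanel_degenerate = function(e) NULL
    )
    if (is.null(att)) return(NA_real_)
    base <- sum(att$raw_free)
    if (base <= 0) return(NA_real_)
    unname(att$raw_free[focal_col]) / base
  }
  out <- tibble::tibble(
    stratum = c("unstratified", "low", "average", "high"),
    share = c(
      share_in(seq_along(y_all)),
      share_in(which(strat_of == "low")),
      share_in(which(strat_of == "average")),
      share_in(which(strat_of == "high"))
    ),
    n = c(length(y_all), sum(strat_of == "low"), sum(strat_of == "average"),
          sum(strat_of == "high"))
  )
  class(out) <- c("stratified_share", class(out))
  out
}
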