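#' Generate a ground-truth two-slice dynamic Bayesian network
#'
#' Builds a known VAR(1)-style linear-Gaussian process over `p` conditions:
#' every condition carries a self-arc (autocorrelation) with coefficient
#' magnitude below one, plus a requested number of feedback pairs
#' (`X@t0 -> Y@t1` and `Y@t0 -> X@t1`) and one-way cross arcs. Cross
#' coefficients are drawn from `+/- coeff_range` and, if needed, rescaled
#' (preserving the sparsity pattern) until the folded coefficient matrix has
#' spectral radius below `max_radius`, so the process is stable.
#'
#' State and county baseline standard deviations are calibrated from the
#' stationary within-county variance so that, on average across conditions,
#' states and counties account for the requested fractions of total variance
#' (defaults emulate weekly health-search panels, where states contribute
#' roughly 12% and counties roughly 49%).
#'
#' @param p Number of conditions (at least 2).
#' @param n_feedback Number of feedback pairs among distinct conditions.
#' @param n_unidirectional Number of one-way cross arcs.
#' @param coeff_range Magnitude interval for cross coefficients.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param self_range Magnitude interval for self (autoregressive)
#'   coefficients; must lie within (0, 1). The default, combined with the
#'   lag-1 correlation the cross arcs add, makes counties plus
#'   autocorrelation explain about 64% of total variance on average.
#' @param state_frac,county_frac Target average fractions of total variance
#'   attributable to state and county baselines. Set both to 0 for a panel
#'   with no spatial structure.
#' @param residual_sd Residual standard deviation of every node equation.
#' @param mean_level Mean frequency level of every condition, in total
#'   standard deviations above zero (default 6). Normalized search
#'   frequencies of retained conditions are bounded away from zero — rare
#'   conditions are filtered out before analysis — so emulated panels
#'   should not have series hovering at zero either; six total standard
#'   deviations keep essentially every simulated value positive without
#'   clipping. Every analysis stage is location-invariant, so this only
#'   affects nonnegativity and relative-error metrics.
#' @param max_radius Stability bound on the spectral radius of the folded
#'   coefficient matrix.
#' @return An object of class `ground_truth`: list with `conditions`, `dag`
#'   (a [two_slice_dag()]), `coefficients` (p x p matrix, rows = targets at
#'   t1, columns = sources at t0), `intercepts`, `residual_sd`, `state_sd`,
#'   `county_sd`, `stationary_cov` (within-county stationary covariance),
#'   `n_feedback`, and `n_unidirectional`.
#' @export
#' @examples
#' gt <- make_ground_truth(p = 4, n_feedback = 1, n_unidirectional = 2, seed = 1)
#' fold(gt$dag)
make_ground_truth <- function(p,
                              n_feedback,
                              n_unidirectional,
                              coeff_range = c(0.2, 0.4),
                              seed = 1L,
                              self_range = c(0.4, 0.55),
                              state_frac = 0.12,
                              county_frac = 0.49,
                              residual_sd = 1,
                              mean_level = 6,
                              max_radius = 0.92) {
  if (p < 2) abort("`p` must be at least 2.")
  n_pairs <- p * (p - 1) / 2
  if (n_feedback + n_unidirectional > n_pairs) {
    abort(sprintf(
      "requested %d feedback pairs + %d one-way arcs exceed the %d available condition pairs",
      n_feedback, n_unidirectional, n_pairs
    ))
  }
  if (state_frac < 0 || county_frac < 0 || state_frac + county_frac >= 1) {
    abort("`state_frac` + `county_frac` must lie in [0, 1).")
  }
  stopifnot(
    min(self_range) > 0, max(self_range) < 1,
    min(coeff_range) >= 0
  )
  seed <- check_seed(seed)
  conds <- sprintf("C%02d", seq_len(p))
  residual_sd <- rep_len(residual_sd, p)

  withr::with_seed(seed, {
    pairs <- utils::combn(p, 2)
    pick <- sample.int(n_pairs, n_feedback + n_unidirectional)
    fb <- pairs[, pick[seq_len(n_feedback)], drop = FALSE]
    uni <- pairs[, pick[seq_len(n_unidirectional) + n_feedback], drop = FALSE]
    flip <- runif(ncol(uni)) < 0.5
    uni[, flip] <- uni[2:1, flip, drop = FALSE]

    # coefficient matrix: rows = target (t1), cols = source (t0)
    B <- matrix(0, p, p, dimnames = list(conds, conds))
    diag(B) <- runif(p, min(self_range), max(self_range))
    draw_cross <- function(n) {
      runif(n, min(coeff_range), max(coeff_range)) * sample(c(-1, 1), n, TRUE)
    }
    for (k in seq_len(ncol(fb))) {
      i <- fb[1, k]; j <- fb[2, k]
      B[j, i] <- draw_cross(1)
      B[i, j] <- draw_cross(1)
    }
    for (k in seq_len(ncol(uni))) {
      B[uni[2, k], uni[1, k]] <- draw_cross(1)
    }
  })

  # rescale cross coefficients (sparsity preserved) until stable
  while (spectral_radius(B) > max_radius) {
    off <- B
    diag(off) <- 0
    B <- B - 0.1 * off
  }

  Sigma <- stationary_cov(B, residual_sd)
  vbar <- mean(diag(Sigma))
  resid_frac <- 1 - state_frac - county_frac
  total_sd <- sqrt(vbar / resid_frac)
  arcs <- tibble::tibble(
    from = conds[col(B)][B != 0],
    to = conds[row(B)][B != 0]
  )
  structure(
    list(
      conditions = conds,
      dag = two_slice_dag(conds, arcs),
      coefficients = B,
      intercepts = setNames(rep(mean_level * total_sd, p), conds),
      residual_sd = setNames(residual_sd, conds),
      state_sd = sqrt(state_frac / resid_frac * vbar),
      county_sd = sqrt(county_frac / resid_frac * vbar),
      stationary_cov = Sigma,
      n_feedback = as.integer(n_feedback),
      n_unidirectional = as.integer(n_unidirectional),
      seed = seed
    ),
    class = "ground_truth"
  )
}

#' Ground truth from an explicit coefficient matrix
#'
#' Lower-level constructor for fully specified truths (useful for designed
#' scenarios such as mediation structures): supply the folded coefficient
#' matrix directly instead of drawing it.
#'
#' @param B Coefficient matrix (rows = targets at t1, columns = sources at
#'   t0), with dimnames giving the condition names; nonzero entries define
#'   the arcs. Must have spectral radius below 1.
#' @param residual_sd Residual standard deviation(s).
#' @param state_sd,county_sd Baseline standard deviations.
#' @param intercepts Node intercepts (default 0).
#' @return A `ground_truth` (see [make_ground_truth()]).
#' @export
ground_truth_from_matrix <- function(B, residual_sd = 1,
                                     state_sd = 0, county_sd = 0,
                                     intercepts = 0) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B))
  conds <- rownames(B) %||% sprintf("C%02d", seq_len(nrow(B)))
  dimnames(B) <- list(conds, conds)
  if (spectral_radius(B) >= 1) abort("`B` must have spectral radius < 1")
  p <- nrow(B)
  residual_sd <- rep_len(residual_sd, p)
  arcs <- tibble::tibble(
    from = conds[col(B)][B != 0],
    to = conds[row(B)][B != 0]
  )
  fb <- sum(B[upper.tri(B)] != 0 & t(B)[upper.tri(B)] != 0)
  uni <- sum(B[upper.tri(B)] != 0 | t(B)[upper.tri(B)] != 0) - fb
  structure(
    list(
      conditions = conds,
      dag = two_slice_dag(conds, arcs),
      coefficients = B,
      intercepts = setNames(rep_len(intercepts, p), conds),
      residual_sd = setNames(residual_sd, conds),
      state_sd = state_sd,
      county_sd = county_sd,
      stationary_cov = stationary_cov(B, residual_sd),
      n_feedback = as.integer(fb),
      n_unidirectional = as.integer(uni),
      seed = NA_integer_
    ),
    class = "ground_truth"
  )
}

# Stationary covariance of Z_t = B Z_{t-1} + eps, eps ~ N(0, diag(sd^2)),
# via the discrete Lyapunov equation Sigma = B Sigma B' + D.
stationary_cov <- function(B, residual_sd) {
  p <- nrow(B)
  if (spectral_radius(B) >= 1) abort("coefficient matrix is not stable")
  D <- diag(residual_sd^2, p)
  vec <- solve(diag(p * p) - kronecker(B, B), as.vector(D))
  Sigma <- matrix(vec, p, p, dimnames = dimnames(B))
  (Sigma + t(Sigma)) / 2
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(
    "<ground_truth> ", length(x$conditions), " conditions, ",
    x$n_feedback, " feedback pairs, ", x$n_unidirectional,
    " one-way arcs; spectral radius ",
    format(spectral_radius(x$coefficients), digits = 3),
    "; state_sd ", format(x$state_sd, digits = 3),
    ", county_sd ", format(x$county_sd, digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.ground_truth <- function(x, ...) {
  B <- x$coefficients
  dplyr::mutate(
    x$dag$arcs,
    coefficient = B[cbind(match(.data$to, rownames(B)), match(.data$from, colnames(B)))]
  )
}
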