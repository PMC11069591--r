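#' Simulate a spatio-temporal search-frequency panel
#'
#' Generates a weekly panel of nonnegative condition frequencies for counties
#' nested in states. Each county follows the ground truth's VAR(1) process
#' around a county-specific baseline: the state and county baselines are
#' time-constant random intercepts (`N(0, state_sd^2)` and
#' `N(0, county_sd^2)`, drawn independently per condition), and the
#' within-county dynamics are the linear-Gaussian two-slice model. A burn-in
#' period is discarded so the series are approximately stationary, then the
#' whole panel is shifted by a constant so at least 99.9% of values are
#' nonnegative and clipped at zero (the clipped fraction is recorded in the
#' `clipped_fraction` attribute).
#'
#' @param gt A [make_ground_truth()] object.
#' @param n_states,counties_per_state,n_weeks Panel dimensions (defaults give
#'   the desk-scale analogue of a national county-level panel:
#'   10 x 20 x 100).
#' @param seed Integer seed.
#' @param burn_in Number of initial weeks discarded.
#' @return A tibble with columns `state`, `county`, `week` (0-based,
#'   contiguous) and one column per condition. Attributes: `ground_truth`
#'   seed info, `shift`, `clipped_fraction`.
#' @export
#' @examples
#' gt <- make_ground_truth(3, 1, 1, seed = 1)
#' panel <- simulate_panel(gt, n_states = 2, counties_per_state = 3,
#'                         n_weeks = 10, seed = 1)
#' head(panel)
simulate_panel <- function(gt,
                           n_states = 10,
                           counties_per_state = 20,
                           n_weeks = 100,
                           seed = 1L,
                           burn_in = 50) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_weeks < 3) abort("`n_weeks` must be at least 3.")
  if (n_states < 1 || counties_per_state < 1) {
    abort("`n_states` and `counties_per_state` must be at least 1.")
  }
  if (spectral_radius(gt$coefficients) >= 1) {
    abort(paste0(
      "ground truth is unstable (spectral radius ",
      format(spectral_radius(gt$coefficients), digits = 4),
      " >= 1); refusing to simulate a divergent panel"
    ))
  }
  seed <- check_seed(seed)
  p <- length(gt$conditions)
  B <- gt$coefficients
  n_counties <- n_states * counties_per_state
  states <- sprintf("S%02d", seq_len(n_states))
  state_of <- rep(seq_len(n_states), each = counties_per_state)
  counties <- sprintf("%s_C%03d", states[state_of],
                      rep(seq_len(counties_per_state), times = n_states))

  # baseline draws are centred and rescaled to their exact target variance,
  # so the realized spatial variance fractions do not wobble with the few
  # state-level draws available
  exact_scale <- function(M, sd_target) {
    if (sd_target == 0) return(M * 0)
    if (nrow(M) < 2) return(M * sd_target)
    apply(M, 2, function(x) (x - mean(x)) / sd(x) * sd_target)
  }
  withr::with_seed(seed, {
    a_state <- exact_scale(
      matrix(rnorm(n_states * p), n_states, p), gt$state_sd
    )
    b_county <- exact_scale(
      matrix(rnorm(n_counties * p), n_counties, p), gt$county_sd
    )
    total_t <- burn_in + n_weeks
    # Z[county, condition] iterated over weeks; start at the process mean 0
    Z <- matrix(0, n_counties, p)
    noise_sd <- rep(gt$residual_sd, each = n_counties)
    out <- array(NA_real_, c(n_counties, n_weeks, p))
    for (t in seq_len(total_t)) {
      eps <- matrix(rnorm(n_counties * p, 0, noise_sd), n_counties, p)
      Z <- Z %*% t(B) + eps
      if (t > burn_in) out[, t - burn_in, ] <- Z
    }
  })

  base <- a_state[state_of, , drop = FALSE] + b_county +
    matrix(gt$intercepts, n_counties, p, byrow = TRUE)
  for (i in seq_len(p)) out[, , i] <- out[, , i] + base[, i]

  # shifting at the 0.05% quantile keeps well over 99.9% of values
  # nonnegative, so the clipped fraction stays below the 0.1% design bound
  shift <- max(0, -quantile(out, 0.0005, names = FALSE, type = 1))
  out <- out + shift
  clipped <- mean(out < 0)
  out[out < 0] <- 0

  panel <- tibble::tibble(
    state = rep(states[state_of], each = n_weeks),
    county = rep(counties, each = n_weeks),
    week = rep(seq_len(n_weeks) - 1L, times = n_counties)
  )
  for (i in seq_len(p)) {
    panel[[gt$conditions[i]]] <- as.vector(t(out[, , i]))
  }
  attr(panel, "shift") <- shift
  attr(panel, "clipped_fraction") <- clipped
  if (clipped > 0.001) {
    warn(sprintf("clipping affected %.3f%% of values", 100 * clipped))
  }
  panel
}

#' Inject artificial missingness into a fully observed panel
#'
#' Removes cells to benchmark imputation: `mode = "single"` removes
#' independently sampled (county, condition, week) cells; `mode = "batch4"`
#' removes non-adjacent runs of four consecutive weeks, emulating a month
#' without measurements. The removed true values are retained in the
#' `injected` attribute for benchmarking.
#'
#' @param panel A fully observed panel tibble (see [simulate_panel()]).
#' @param rate Target missing fraction, in (0, 1); the realized fraction is
#'   within 0.5 percentage points of the target.
#' @param mode `"single"` or `"batch4"`.
#' @param seed Integer seed.
#' @return The panel with injected `NA` cells; attributes `injected` (tibble
#'   with `state`, `county`, `week`, `condition`, `true_value`) and
#'   `realized_rate`.
#' @export
inject_missingness <- function(panel, rate, mode = c("single", "batch4"),
                               seed = 1L) {
  check_panel(panel)
  mode <- match.arg(mode)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0 || rate >= 1) {
    abort("`rate` must be a single number in (0, 1).")
  }
  seed <- check_seed(seed)
  # canonical condition order, so the injected cell set does not depend on
  # the panel's column order
  conds <- sort(panel_conditions(panel))
  vals <- as.matrix(panel[conds])
  if (anyNA(vals)) {
    abort("`panel` must be fully observed before injecting missingness.")
  }
  n_total <- length(vals)
  target <- round(rate * n_total)

  panel <- dplyr::arrange(panel, .data$state, .data$county, .data$week)
  vals <- as.matrix(panel[conds])

  if (mode == "single") {
    idx <- withr::with_seed(seed, sample.int(n_total, target))
  } else {
    # series = (county, condition); runs of 4 within a series, kept
    # non-adjacent so every maximal injected run has length exactly 4
    counties <- unique(panel$county)
    t_len <- vapply(counties, function(cc) sum(panel$county == cc), 1L)
    row_off <- c(0L, cumsum(t_len))[seq_along(counties)]
    cand <- list()
    k <- 1L
    for (ci in seq_along(counties)) {
      if (t_len[ci] < 4) next
      for (j in seq_along(conds)) {
        starts <- seq_len(t_len[ci] - 3L)
        cand[[k]] <- cbind(row_off[ci] + starts, j, t_len[ci], row_off[ci])
        k <- k + 1L
      }
    }
    cand <- do.call(rbind, cand)
    ord <- withr::with_seed(seed, sample.int(nrow(cand)))
    miss <- matrix(FALSE, nrow(vals), ncol(vals))
    n_missing <- 0L
    for (r in ord) {
      if (n_missing >= target) break
      start <- cand[r, 1]; j <- cand[r, 2]
      t_n <- cand[r, 3]; off <- cand[r, 4]
      run <- start:(start + 3L)
      # keep at least one observed week between runs in the same series
      lo <- max(off + 1L, start - 1L)
      hi <- min(off + t_n, start + 4L)
      if (any(miss[lo:hi, j])) next
      miss[run, j] <- TRUE
      n_missing <- n_missing + 4L
    }
    idx <- which(miss)
  }

  realized <- length(idx) / n_total
  if (abs(realized - rate) > 0.005) {
    warn(sprintf(
      "realized missing fraction %.4f differs from target %.4f by more than 0.005",
      realized, rate
    ))
  }
  rowcol <- arrayInd(idx, dim(vals))
  injected <- tibble::tibble(
    state = panel$state[rowcol[, 1]],
    county = panel$county[rowcol[, 1]],
    week = panel$week[rowcol[, 1]],
    condition = conds[rowcol[, 2]],
    true_value = vals[idx]
  )
  vals[idx] <- NA_real_
  for (j in seq_along(conds)) panel[[conds[j]]] <- vals[, j]
  attr(panel, "injected") <- injected
  attr(panel, "realized_rate") <- realized
  panel
}
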