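#' Drop conditions with too much missing data
#'
#' Removes every condition whose overall missing fraction across all
#' county-weeks strictly exceeds `max_missing` ("more than" the threshold;
#' a condition at exactly the threshold is retained).
#'
#' @param panel A panel tibble with `NA` marking missing cells.
#' @param max_missing Missing-fraction threshold (default 0.30).
#' @return The panel restricted to the retained conditions; dropped names
#'   are reported via a message and in the `dropped_conditions` attribute.
#' @export
filter_conditions <- function(panel, max_missing = 0.30) {
  check_panel(panel)
  conds <- panel_conditions(panel)
  frac <- vapply(conds, function(cc) mean(is.na(panel[[cc]])), 0)
  drop <- conds[frac > max_missing]
  if (length(drop) == length(conds)) {
    abort(paste0(
      "all conditions exceed the ", max_missing,
      " missing-data threshold; nothing left to analyse"
    ))
  }
  if (length(drop) > 0) {
    inform(paste0(
      "dropping ", length(drop), " condition(s) with more than ",
      round(100 * max_missing), "% missing data: ", paste(drop, collapse = ", ")
    ))
  }
  out <- panel[c(panel_index_cols, setdiff(conds, drop))]
  attr(out, "dropped_conditions") <- drop
  out
}

#' Exponentially weighted moving-average imputation of one series
#'
#' Fills each missing cell with the weighted mean of up to `k` observed
#' neighbours on each side, weighted `2^(-distance)` and renormalized over
#' the neighbours actually available. Observed cells are never altered, so
#' imputed values are convex combinations of observed neighbours.
#'
#' @param series Numeric vector (one county x condition time series) with
#'   `NA` for missing cells.
#' @param k Maximum number of observed neighbours used on each side.
#' @param min_observed Minimum number of observed values required; below it
#'   the series is unimputable and an error of class
#'   `dbnpanel_unimputable` is signalled (callers route such series to
#'   [drop_unimputable()]).
#' @return The completed series.
#' @export
#' @examples
#' impute_ewma(c(1, NA, 3))
impute_ewma <- function(series, k = 4, min_observed = 1) {
  obs <- which(!is.na(series))
  if (length(obs) < max(1, min_observed)) {
    abort(
      sprintf(
        "series has %d observed value(s), fewer than min_observed = %d",
        length(obs), min_observed
      ),
      class = "dbnpanel_unimputable"
    )
  }
  gaps <- which(is.na(series))
  for (t in gaps) {
    left <- rev(obs[obs < t])
    right <- obs[obs > t]
    nb <- c(head(left, k), head(right, k))
    w <- 2^(-abs(nb - t))
    series[t] <- sum(w * series[nb]) / sum(w)
  }
  series
}

# Linear interpolation comparator (flat extension at the series ends).
impute_interp <- function(series, min_observed = 1, ...) {
  obs <- sum(!is.na(series))
  if (obs < max(1, min_observed)) {
    abort("insufficient observed values", class = "dbnpanel_unimputable")
  }
  as.numeric(zoo::na.approx(series, na.rm = FALSE, rule = 2))
}

resolve_method <- function(method) {
  if (is.function(method)) return(method)
  switch(as.character(method),
    ewma = impute_ewma,
    interp = impute_interp,
    abort(paste0(
      "unknown imputation method '", method,
      "'; use \"ewma\", \"interp\", or supply a function(series, ...)"
    ))
  )
}

#' Impute every missing cell of a panel
#'
#' Applies a univariate imputation method independently to each
#' (county, condition) series. Series with fewer than `min_observed`
#' observed values are left untouched (all other cells imputed normally);
#' remove them first with [drop_unimputable()].
#'
#' @param panel A panel tibble with `NA` cells.
#' @param method `"ewma"` (default), `"interp"` (linear interpolation), or a
#'   function `f(series, ...)` returning a completed series — the hook used
#'   to plug in external imputers such as Kalman smoothers.
#' @param k EWMA window (observed neighbours per side).
#' @param min_observed Minimum observed values per series.
#' @return The imputed panel; the `imputation_failures` attribute lists
#'   series the method could not complete.
#' @export
impute_panel <- function(panel, method = "ewma", k = 4, min_observed = 5) {
  check_panel(panel)
  fn <- resolve_method(method)
  conds <- panel_conditions(panel)
  panel <- dplyr::arrange(panel, .data$state, .data$county, .data$week)
  county_rows <- split(seq_len(nrow(panel)), panel$county)
  failures <- list()
  for (cc in conds) {
    x <- panel[[cc]]
    if (!anyNA(x)) next
    for (cty in unique(panel$county[is.na(x)])) {
      rows <- county_rows[[cty]]
      res <- tryCatch(
        fn(x[rows], k = k, min_observed = min_observed),
        dbnpanel_unimputable = function(e) NULL,
        error = function(e) structure(list(msg = conditionMessage(e)), class = "impute_fail")
      )
      if (is.numeric(res)) {
        x[rows] <- res
      } else {
        failures[[length(failures) + 1L]] <- tibble::tibble(
          county = cty, condition = cc,
          reason = if (is.null(res)) "unimputable" else res$msg
        )
      }
    }
    panel[[cc]] <- x
  }
  attr(panel, "imputation_failures") <-
    if (length(failures)) dplyr::bind_rows(failures) else NULL
  panel
}

#' Drop series with too few observed values
#'
#' Marks every (county, condition) series with fewer than `min_observed`
#' observed cells as entirely missing, mirroring the removal of unimputable
#' series from the analysis; rows containing such cells are later excluded
#' when lagged pairs are built.
#'
#' @param panel A panel tibble.
#' @param min_observed Minimum observed cells per series (default 5).
#' @return The panel, with attributes `dropped_series` (tibble) and
#'   `n_cells` (observed-cell count before and after).
#' @export
drop_unimputable <- function(panel, min_observed = 5) {
  check_panel(panel)
  conds <- panel_conditions(panel)
  before <- sum(!is.na(as.matrix(panel[conds])))
  dropped <- list()
  for (cc in conds) {
    counts <- tapply(!is.na(panel[[cc]]), panel$county, sum)
    bad <- names(counts)[counts < min_observed]
    if (length(bad) > 0) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        county = bad, condition = cc, n_observed = as.integer(counts[bad])
      )
      panel[[cc]][panel$county %in% bad] <- NA_real_
    }
  }
  after <- sum(!is.na(as.matrix(panel[conds])))
  attr(panel, "dropped_series") <-
    if (length(dropped)) dplyr::bind_rows(dropped) else
      tibble::tibble(county = character(), condition = character(),
                     n_observed = integer())
  attr(panel, "n_cells") <- c(before = before, after = after)
  panel
}

#' Benchmark imputation methods by injection
#'
#' Starting from a fully observed panel, injects missingness at each
#' requested rate and pattern, imputes with each method, and scores the mean
#' relative error `|imputed - true| / |true|` over the injected cells. Cells
#' whose true value is zero have an undefined relative error; they are
#' excluded from the mean and counted separately.
#'
#' @param panel A fully observed panel.
#' @param methods Character names (`"ewma"`, `"interp"`) and/or named list
#'   entries with imputation functions. `"oracle"` (returning the true
#'   values) is accepted for calibration.
#' @param rates Missing-fraction grid (default the conventional
#'   2/5/10/20%).
#' @param modes Injection patterns, subset of `c("single", "batch4")`.
#' @param seed Integer seed; each (rate, mode) setting gets an independent
#'   derived seed, so results do not depend on grid order.
#' @param k,min_observed Passed to the imputers.
#' @return A tibble of class `imputation_report` with columns `method`,
#'   `rate`, `mode`, `mean_relative_error`, `n_cells`, `n_zero_true_cells`,
#'   `n_failed_series`.
#' @export
benchmark_imputation <- function(panel,
                                 methods = c("ewma", "interp"),
                                 rates = c(0.02, 0.05, 0.10, 0.20),
                                 modes = c("single", "batch4"),
                                 seed = 1L,
                                 k = 4,
                                 min_observed = 5) {
  check_panel(panel)
  conds <- panel_conditions(panel)
  if (anyNA(as.matrix(panel[conds]))) {
    abort("`panel` must be fully observed to benchmark imputation.")
  }
  seed <- check_seed(seed)
  settings <- tidyr::expand_grid(rate = rates, mode = modes)
  sub_seeds <- derive_seeds(seed, nrow(settings))
  method_names <- vapply(seq_along(methods), function(i) {
    nm <- names(methods)[i]
    if (!is.null(nm) && nzchar(nm)) nm else as.character(methods[[i]])
  }, "")

  rows <- list()
  for (s in seq_len(nrow(settings))) {
    rate <- settings$rate[s]
    mode <- settings$mode[s]
    holed <- inject_missingness(panel, rate, mode, seed = sub_seeds[s])
    injected <- attr(holed, "injected")
    holed <- dplyr::arrange(holed, .data$state, .data$county, .data$week)
    for (m in seq_along(methods)) {
      method <- methods[[m]]
      if (identical(method, "oracle")) {
        imputed_vals <- injected$true_value
        n_failed <- 0L
      } else {
        done <- impute_panel(holed, method = method, k = k,
                             min_observed = min_observed)
        fails <- attr(done, "imputation_failures")
        n_failed <- if (is.null(fails)) 0L else nrow(fails)
        row_id <- match(
          paste(injected$county, injected$week),
          paste(done$county, done$week)
        )
        col_id <- match(injected$condition, conds)
        imputed_vals <- as.matrix(done[conds])[cbind(row_id, col_id)]
      }
      nonzero <- injected$true_value != 0
      ok <- nonzero & !is.na(imputed_vals)
      rel <- abs(imputed_vals[ok] - injected$true_value[ok]) /
        abs(injected$true_value[ok])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = method_names[m], rate = rate, mode = mode,
        mean_relative_error = mean(rel),
        n_cells = sum(ok),
        n_zero_true_cells = sum(!nonzero),
        n_failed_series = n_failed
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("imputation_report", class(out))
  out
}
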