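#' Variance decomposition of the spatio-temporal panel structure
#'
#' For each condition, fits a variance-components model with nested random
#' intercepts (state, county within state) by REML, and quantifies the
#' order-1 serial dependence as the additional fraction of total variance
#' explained when the within-county residuals are regressed on their lag-1
#' values. Reported shares are, per condition:
#' * `state_prop` — state intercept variance / total,
#' * `county_prop` — county-within-state intercept variance / total,
#' * `county_ar1_prop` — `county_prop` plus the incremental lag-1 share,
#'   matching the convention of reporting counties "together with
#'   autocorrelation".
#'
#' Shares are invariant to affine rescaling of a condition. Negative
#' variance components cannot occur under lme4's constrained REML; boundary
#' (zero) fits are flagged in the `singular` column.
#'
#' @param panel A complete panel tibble (impute first).
#' @param conditions Conditions to decompose (default all).
#' @return A tibble of class `variance_decomposition` with one row per
#'   condition (`condition`, `state_prop`, `county_prop`, `county_ar1_prop`,
#'   `ar1_coef`, `singular`), and a `summary` attribute holding the
#'   cross-condition mean, min and max of each share.
#' @export
variance_decomposition <- function(panel, conditions = NULL) {
  check_panel(panel)
  conds <- conditions %||% panel_conditions(panel)
  n_states <- dplyr::n_distinct(panel$state)
  counties_per_state <- dplyr::summarise(
    dplyr::group_by(panel, .data$state),
    n = dplyr::n_distinct(.data$county), .groups = "drop"
  )$n
  if (n_states < 2 || any(counties_per_state < 2)) {
    abort(paste0(
      "variance components need at least 2 states and 2 counties per state; ",
      "got ", n_states, " state(s), min ", min(counties_per_state),
      " county(ies) per state"
    ))
  }
  panel <- dplyr::arrange(panel, .data$state, .data$county, .data$week)
  rows <- purrr::map(conds, function(cc) {
    df <- data.frame(
      y = panel[[cc]], state = panel$state, county = panel$county,
      week = panel$week
    )
    if (anyNA(df$y)) {
      abort(paste0("condition ", cc, " has missing values; impute first"))
    }
    fit <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | state) + (1 | county),
      data = df, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore")
    ))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_state <- vc$vcov[vc$grp == "state"]
    v_county <- vc$vcov[vc$grp == "county"]
    v_resid <- vc$vcov[vc$grp == "Residual"]
    total <- v_state + v_county + v_resid
    # lag-1 share of the within-county residual process
    r <- residuals(fit)
    same <- df$county[-1] == df$county[-nrow(df)]
    phi <- cor(r[-1][same], r[-length(r)][same])
    ar1_inc <- phi^2 * (v_resid / total)
    tibble::tibble(
      condition = cc,
      state_prop = v_state / total,
      county_prop = v_county / total,
      county_ar1_prop = v_county / total + ar1_inc,
      ar1_coef = phi,
      singular = lme4::isSingular(fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  shares <- c("state_prop", "county_prop", "county_ar1_prop")
  attr(out, "summary") <- tibble::tibble(
    share = shares,
    mean = unname(vapply(shares, function(s) mean(out[[s]]), 0)),
    min = unname(vapply(shares, function(s) min(out[[s]]), 0)),
    max = unname(vapply(shares, function(s) max(out[[s]]), 0))
  )
  class(out) <- c("variance_decomposition", class(out))
  out
}

#' @export
autoplot.variance_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("condition", "state_prop", "county_prop",
                                "county_ar1_prop")],
    -"condition",
    names_to = "component", values_to = "share"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$condition, y = .data$share, fill = .data$component)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "share of total variance",
      title = "Spatio-temporal variance decomposition"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
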