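# Shared fixtures, built in code.

# pure AR(1) truth with identical self-coefficients and no cross arcs
ar_truth <- function(p = 3, phi = 0.8, residual_sd = 1,
                     state_sd = 0, county_sd = 0) {
  conds <- sprintf("C%02d", seq_len(p))
  B <- diag(phi, p)
  dimnames(B) <- list(conds, conds)
  ground_truth_from_matrix(B, residual_sd = residual_sd,
                           state_sd = state_sd, county_sd = county_sd)
}

# white-noise truth: no arcs at all
noise_truth <- function(p = 3, state_sd = 0, county_sd = 0) {
  conds <- sprintf("C%02d", seq_len(p))
  B <- matrix(0, p, p, dimnames = list(conds, conds))
  ground_truth_from_matrix(B, residual_sd = 1,
                           state_sd = state_sd, county_sd = county_sd)
}

# mediation truth: the stratifier drives both the focal and the target in
# the same week; the target has one further non-self parent
mediation_truth <- function() {
  conds <- c("TGT", "FOC", "STR", "OTH")
  B <- matrix(0, 4, 4, dimnames = list(conds, conds))
  diag(B) <- 0.5
  B["TGT", "STR"] <- 0.6
  B["FOC", "STR"] <- 0.6
  B["TGT", "OTH"] <- 0.4
  ground_truth_from_matrix(B)
}

# hand-rolled lag-pairs object from explicit t0/t1 matrices
manual_lag_pairs <- function(t0, t1) {
  conds <- colnames(t0)
  df <- tibble::as_tibble(
    stats::setNames(
      as.data.frame(cbind(t0, t1)),
      c(paste0(conds, "_t0"), paste0(conds, "_t1"))
    )
  )
  dbnpanel:::new_lag_pairs(df, conds)
}

# pooled within-county lag-1 autocorrelation of one condition
lag1_autocor <- function(panel, condition) {
  lp <- build_lag_pairs(panel)
  stats::cor(lp[[paste0(condition, "_t0")]], lp[[paste0(condition, "_t1")]])
}
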