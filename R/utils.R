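# Internal helpers shared across modules.

# Condition (variable) columns of a panel: everything except the index.
panel_index_cols <- c("state", "county", "week")

panel_conditions <- function(panel) {
  setdiff(names(panel), panel_index_cols)
}

check_panel <- function(panel, call = rlang::caller_env()) {
  missing_cols <- setdiff(panel_index_cols, names(panel))
  if (length(missing_cols) > 0) {
    abort(
      paste0("`panel` lacks index column(s): ", paste(missing_cols, collapse = ", ")),
      call = call
    )
  }
  if (length(panel_conditions(panel)) == 0) {
    abort("`panel` has no condition columns.", call = call)
  }
  invisible(panel)
}

check_seed <- function(seed, call = rlang::caller_env()) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.", call = call)
  }
  as.integer(seed)
}

# Independent substream seeds so resamples can run in any order.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Spectral radius of a square matrix.
spectral_radius <- function(B) {
  max(Mod(eigen(B, only.values = TRUE)$values))
}
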