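#' Greedy structure search for the two-slice DAG
#'
#' Hill climbing over single-arc additions and deletions, starting from the
#' empty graph and maximizing the penalized log-likelihood. Arc reversal is
#' not a move, because a reversed arc would point backward in time. Because
#' the score decomposes over t1 nodes and forward-only arcs never interact
#' across targets, accepting the single best improving move per step until
#' none remains is equivalent to running the greedy add/delete search per
#' target; the search is deterministic, with ties broken lexicographically
#' by (target, source) in condition order.
#'
#' @param lag_pairs A [build_lag_pairs()] design.
#' @param w Penalty coefficient.
#' @param whitelist,blacklist Optional data frames with `from`/`to` columns:
#'   whitelisted arcs are always present (never deleted), blacklisted arcs
#'   are never added.
#' @param penalty_unit,include_t0 See [score_dag()].
#' @return A [two_slice_dag()].
#' @export
hill_climb <- function(lag_pairs, w = 1, whitelist = NULL, blacklist = NULL,
                       penalty_unit = c("bic", "literal"),
                       include_t0 = TRUE) {
  stopifnot(w >= 0)
  penalty_unit <- match.arg(penalty_unit)
  gram <- lag_gram(lag_pairs)
  conds <- gram$conditions
  p <- gram$p
  step_cost <- w * penalty_per_param(gram$n, penalty_unit)

  arc_idx <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(matrix(0L, 0, 2))
    cbind(match(df$from, conds), match(df$to, conds))
  }
  wl <- arc_idx(whitelist)
  bl <- arc_idx(blacklist)

  arcs <- list()
  for (j in seq_len(p)) {
    forced <- wl[wl[, 2] == j, 1]
    banned <- bl[bl[, 2] == j, 1]
    pa <- sort(unique(forced))
    memo <- new.env(parent = emptyenv())
    ll <- function(parents) {
      key <- paste0("p", paste(parents, collapse = ","))
      got <- memo[[key]]
      if (is.null(got)) {
        got <- local_loglik(gram, j, parents)
        memo[[key]] <- got
      }
      got
    }
    cur <- ll(pa)
    repeat {
      best_delta <- 1e-9
      best_pa <- NULL
      for (s in seq_len(p)) {            # lexicographic tie-break on source
        if (s %in% pa) {
          if (s %in% forced) next
          cand <- setdiff(pa, s)
          delta <- ll(cand) - cur + step_cost
        } else {
          if (s %in% banned) next
          cand <- sort(c(pa, s))
          delta <- ll(cand) - cur - step_cost
        }
        if (delta > best_delta) {
          best_delta <- delta
          best_pa <- cand
        }
      }
      if (is.null(best_pa)) break
      pa <- best_pa
      cur <- ll(pa)
    }
    if (length(pa) > 0) {
      arcs[[length(arcs) + 1L]] <- tibble::tibble(from = conds[pa], to = conds[j])
    }
  }
  two_slice_dag(conds, if (length(arcs)) dplyr::bind_rows(arcs) else NULL)
}

#' Exhaustive per-node best-parent-subset search
#'
#' Brute-force reference for small systems: because the penalized score
#' decomposes over t1 nodes and forward-only arcs cannot form cycles, the
#' global optimum is found by enumerating, for every target, all `2^p`
#' parent subsets and keeping the best. Intended as an independent check of
#' [hill_climb()] for `p <= 12`-ish (cost grows as `p * 2^p`).
#'
#' @inheritParams hill_climb
#' @param max_p Safety cap on the number of conditions.
#' @return A [two_slice_dag()] attaining the globally optimal score.
#' @export
exhaustive_dag <- function(lag_pairs, w = 1,
                           penalty_unit = c("bic", "literal"),
                           max_p = 12) {
  penalty_unit <- match.arg(penalty_unit)
  gram <- lag_gram(lag_pairs)
  p <- gram$p
  if (p > max_p) abort("exhaustive search is limited to small systems")
  conds <- gram$conditions
  step_cost <- w * penalty_per_param(gram$n, penalty_unit)
  subsets <- purrr::map(0:(2^p - 1), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) > 0)
  })
  # deterministic preference: higher score, then fewer parents, then
  # lexicographically earlier subset (subsets are enumerated in that order)
  arcs <- list()
  for (j in seq_len(p)) {
    best <- -Inf
    best_set <- integer()
    for (S in subsets) {
      sc <- local_loglik(gram, j, S) - step_cost * length(S)
      if (sc > best + 1e-9) {
        best <- sc
        best_set <- S
      }
    }
    if (length(best_set) > 0) {
      arcs[[length(arcs) + 1L]] <-
        tibble::tibble(from = conds[best_set], to = conds[j])
    }
  }
  two_slice_dag(conds, if (length(arcs)) dplyr::bind_rows(arcs) else NULL)
}
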