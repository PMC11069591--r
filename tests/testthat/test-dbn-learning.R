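test_that("lag pairs count one row per consecutive within-county week pair", {
  gt <- noise_truth(2)
  p1 <- simulate_panel(gt, 1, 1, 100, seed = 1)
  expect_equal(nrow(build_lag_pairs(p1)), 99)

  p2 <- simulate_panel(gt, 2, 3, 10, seed = 2)
  expect_equal(nrow(build_lag_pairs(p2)), 6 * 9)

  p3 <- simulate_panel(gt, 1, 1, 3, seed = 3)[1:2, ]
  lp <- build_lag_pairs(p3)
  expect_equal(nrow(lp), 1)
  expect_equal(lp$C01_t0, p3$C01[1])
  expect_equal(lp$C01_t1, p3$C01[2])

  # rows with missing cells contribute nothing; all-missing errors
  p4 <- simulate_panel(gt, 1, 1, 4, seed = 4)
  p4$C01[2] <- NA
  expect_equal(nrow(build_lag_pairs(p4)), 1) # only weeks 2-3 survive
  p4$C01[] <- NA
  expect_error(build_lag_pairs(p4), "no county")
})

test_that("the local score matches the closed-form Gaussian MLE log-likelihood", {
  t0 <- matrix(rnorm(3), dimnames = list(NULL, "X"))
  t1 <- matrix(c(-1, 0, 1), dimnames = list(NULL, "X"))
  lp <- manual_lag_pairs(t0, t1)
  dag <- two_slice_dag("X") # no parents: intercept-only fit
  sc <- score_dag(dag, lp, w = 1, include_t0 = FALSE)
  expect_equal(sc$loglik, -(3 / 2) * (log(2 * pi * 2 / 3) + 1))
  expect_equal(sc$n_params, 2)

  # w = 0: penalized equals the log-likelihood
  sc0 <- score_dag(dag, lp, w = 0)
  expect_equal(sc0$penalized, sc0$loglik)
})

test_that("adding a parent never decreases the log-likelihood", {
  gt <- make_ground_truth(3, 1, 0, seed = 4, state_frac = 0, county_frac = 0)
  lp <- build_lag_pairs(simulate_panel(gt, 1, 5, 50, seed = 5))
  conds <- gt$conditions
  base <- two_slice_dag(conds)
  prev <- score_dag(base, lp, w = 0)$loglik
  arcs <- NULL
  for (src in conds) {
    arcs <- rbind(arcs, data.frame(from = src, to = "C01"))
    cur <- score_dag(two_slice_dag(conds, arcs), lp, w = 0)$loglik
    expect_gte(cur, prev - 1e-8)
    prev <- cur
  }
})

test_that("the score decomposes exactly over nodes", {
  gt <- make_ground_truth(4, 1, 2, seed = 8, state_frac = 0, county_frac = 0)
  lp <- build_lag_pairs(simulate_panel(gt, 1, 4, 40, seed = 9))
  conds <- gt$conditions
  d1 <- two_slice_dag(conds, data.frame(from = c("C01", "C02"),
                                        to = c("C01", "C01")))
  d2 <- two_slice_dag(conds, data.frame(from = "C01", to = "C01"))
  s1 <- score_dag(d1, lp, w = 2)
  s2 <- score_dag(d2, lp, w = 2)
  local1 <- s1$per_node$loglik[s1$per_node$node == "C01_t1"]
  local2 <- s2$per_node$loglik[s2$per_node$node == "C01_t1"]
  u <- log(nrow(lp)) / 2
  expect_equal(s1$penalized - s2$penalized, (local1 - local2) - 2 * u)
})

test_that("degenerate designs raise a per-node error naming the node", {
  withr::with_seed(77, {
    t0 <- cbind(A = rnorm(20), B = 0)
    t0 <- cbind(t0, C = t0[, "A"]) # collinear with A
    t1 <- cbind(A = rnorm(20), B = rnorm(20), C = rnorm(20))
  })
  lp <- manual_lag_pairs(t0, t1)
  dag <- two_slice_dag(c("A", "B", "C"),
                       data.frame(from = c("A", "C"), to = c("B", "B")))
  expect_error(score_dag(dag, lp, include_t0 = FALSE),
               "node B", class = "dbnpanel_degenerate")
})

test_that("hill climbing returns an empty graph on independent noise at large w", {
  gt <- noise_truth(3)
  lp <- build_lag_pairs(simulate_panel(gt, 2, 3, 40, seed = 6))
  dag <- hill_climb(lp, w = 64)
  expect_equal(nrow(dag$arcs), 0)
})

test_that("hill climbing matches exhaustive per-node subset search", {
  for (sd in 1:3) {
    gt <- make_ground_truth(3, 1, 1, seed = sd, state_frac = 0,
                            county_frac = 0)
    lp <- build_lag_pairs(simulate_panel(gt, 2, 10, 101, seed = sd + 50))
    hc <- hill_climb(lp, w = 1)
    ex <- exhaustive_dag(lp, w = 1)
    expect_equal(score_dag(hc, lp, 1)$penalized,
                 score_dag(ex, lp, 1)$penalized)
  }
})

test_that("arc count is non-increasing in the penalty", {
  gt <- make_ground_truth(5, 2, 3, seed = 13)
  panel <- simulate_panel(gt, 3, 5, 60, seed = 14)
  lp <- build_lag_pairs(panel)
  counts <- vapply(c(1, 2, 4, 8, 16, 32, 64, 128),
                   function(w) nrow(hill_climb(lp, w)$arcs), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("whitelists and blacklists are honoured", {
  gt <- noise_truth(3)
  lp <- build_lag_pairs(simulate_panel(gt, 2, 3, 40, seed = 7))
  wl <- data.frame(from = "C01", to = "C02")
  dag <- hill_climb(lp, w = 8, whitelist = wl)
  expect_true(any(dag$arcs$from == "C01" & dag$arcs$to == "C02"))

  gt2 <- ar_truth(2, phi = 0.8)
  lp2 <- build_lag_pairs(simulate_panel(gt2, 2, 5, 60, seed = 8))
  bl <- data.frame(from = c("C01", "C02"), to = c("C01", "C02"))
  dag2 <- hill_climb(lp2, w = 1, blacklist = bl)
  expect_false(any(dag2$arcs$from == dag2$arcs$to))
})

test_that("maximum-likelihood fits recover generating parameters", {
  withr::with_seed(21, {
    x <- rnorm(5000)
    y <- 2 + 0.5 * x + rnorm(5000, 0, 0.1)
  })
  lp <- manual_lag_pairs(cbind(X = x), cbind(X = y))
  dag <- two_slice_dag("X", data.frame(from = "X", to = "X"))
  fit <- fit_dbn(dag, lp)
  expect_gt(fit$nodes$X$coefficients[["X"]], 0.48)
  expect_lt(fit$nodes$X$coefficients[["X"]], 0.52)
  expect_gt(fit$nodes$X$intercept, 1.9)
  expect_lt(fit$nodes$X$intercept, 2.1)

  # noiseless data: exact coefficients, vanishing residual variance
  lp2 <- manual_lag_pairs(cbind(X = x), cbind(X = 2 + 0.5 * x))
  fit2 <- fit_dbn(dag, lp2)
  expect_equal(fit2$nodes$X$coefficients[["X"]], 0.5, tolerance = 1e-9)
  expect_lt(fit2$nodes$X$sigma2, 1e-10)

  # empty parent set: sample mean and MLE variance
  dag0 <- two_slice_dag("X")
  fit0 <- fit_dbn(dag0, lp)
  expect_equal(fit0$nodes$X$intercept, mean(y))
  expect_equal(fit0$nodes$X$sigma2, mean((y - mean(y))^2))
})

test_that("tidy and glance summarise fits", {
  gt <- ar_truth(2, 0.6)
  lp <- build_lag_pairs(simulate_panel(gt, 2, 3, 30, seed = 3))
  fit <- fit_dbn(gt$dag, lp)
  td <- tidy(fit)
  expect_setequal(names(td), c("target", "term", "estimate"))
  expect_equal(nrow(td), 4) # 2 intercepts + 2 self-coefficients
  gl <- glance(fit)
  expect_equal(gl$n_arcs, 2)
  expect_equal(gl$n, nrow(lp))
})

test_that("R-squared is 1 on noiseless fits and near 0 on noise", {
  withr::with_seed(31, x <- rnorm(500))
  lp <- manual_lag_pairs(cbind(X = x), cbind(X = 1 + 2 * x))
  dag <- two_slice_dag("X", data.frame(from = "X", to = "X"))
  fit <- fit_dbn(dag, lp)
  expect_equal(predict_r2(fit, lp)$r2, 1, tolerance = 1e-12)

  gt <- noise_truth(2)
  panel <- simulate_panel(gt, 2, 5, 120, seed = 1)
  train <- build_lag_pairs(panel[panel$week < 60, ])
  test_rows <- build_lag_pairs(panel[panel$week >= 60, ])
  fit2 <- fit_dbn(hill_climb(train, w = 1), train)
  r2 <- predict_r2(fit2, test_rows)$r2
  expect_true(all(abs(r2) <= 0.05))
})

test_that("a designed R-squared level is recovered", {
  # pure AR(1) with phi^2 = 0.6: the population R2 equals phi^2
  gt <- ar_truth(p = 2, phi = sqrt(0.6))
  lp <- build_lag_pairs(simulate_panel(gt, 2, 10, 251, seed = 17))
  fit <- fit_dbn(hill_climb(lp, w = 1), lp)
  expect_lt(abs(attr(predict_r2(fit, lp), "average") - 0.6), 0.05)
})

test_that("penalty tuning prefers sparse models at unchanged accuracy", {
  gt <- make_ground_truth(4, 1, 2, seed = 23)
  panel <- simulate_panel(gt, 3, 5, 80, seed = 24)
  tuning <- tune_penalty(center_counties(panel), w_grid = c(1, 4, 16, 64),
                         split_week = 40)
  tab <- tuning$table
  expect_equal(tab$accuracy_ratio[tab$w == 1], 1)
  expect_true(all(tab$val_r2 <= tab$train_r2 + 0.05))
  # the chosen model's arc count is close to the truth's
  chosen_arcs <- tab$n_arcs[tab$w == tuning$chosen_w]
  expect_lt(abs(chosen_arcs - nrow(gt$dag$arcs)) / nrow(gt$dag$arcs), 0.2 + 1e-9)
  expect_error(tune_penalty(panel, split_week = 79), "at least 2 weeks")
})
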