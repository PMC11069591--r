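test_that("folding classifies arcs exactly", {
  d1 <- two_slice_dag(c("A", "B"),
                      data.frame(from = c("A", "B", "A"), to = c("B", "A", "A")))
  f1 <- fold(d1)
  expect_equal(f1$arcs$class[f1$arcs$from == "A" & f1$arcs$to == "B"],
               "feedback")
  expect_equal(sum(f1$arcs$class == "autoloop"), 1)

  d2 <- two_slice_dag(c("B", "C"), data.frame(from = "C", to = "B"))
  f2 <- fold(d2)
  expect_equal(f2$arcs$class, "unidirectional")
  expect_equal(f2$arcs$from, "C")

  expect_equal(nrow(fold(two_slice_dag(c("A", "B")))$arcs), 0)
})

test_that("fold and unfold are inverse on valid two-slice DAGs", {
  for (sd in 1:5) {
    gt <- make_ground_truth(5, 2, 3, seed = sd)
    folded <- fold(gt$dag)
    back <- unfold(folded)
    expect_setequal(paste(back$arcs$from, back$arcs$to),
                    paste(gt$dag$arcs$from, gt$dag$arcs$to))
    refolded <- fold(back)
    expect_equal(
      dplyr::arrange(refolded$arcs, from, to, class),
      dplyr::arrange(folded$arcs, from, to, class)
    )
  }
})

test_that("orthogonal parents split explained variance by squared effect size", {
  n <- 2e4
  withr::with_seed(41, {
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    xs <- rnorm(n)
  })
  # exactly orthogonal, unit-variance regressors
  q <- qr.Q(qr(cbind(x1, x2, xs)))
  q <- sweep(q, 2, apply(q, 2, sd), "/")
  withr::with_seed(42, {
    y_self <- 0.5 * q[, 3]
    y <- y_self + 0.5 * q[, 1] + 0.5 * q[, 2] + rnorm(n, 0, 0.5)
  })
  t0 <- cbind(P1 = q[, 1], P2 = q[, 2], TG = q[, 3])
  t1 <- cbind(P1 = rnorm(n), P2 = rnorm(n), TG = y)
  lp <- manual_lag_pairs(t0, t1)
  dag <- two_slice_dag(c("P1", "P2", "TG"),
                       data.frame(from = c("P1", "P2", "TG"),
                                  to = c("TG", "TG", "TG")))
  fit <- fit_dbn(dag, lp)
  rep_eq <- parent_variance_shares(fit, lp, "TG")
  others <- rep_eq[rep_eq$role == "other", ]
  expect_equal(others$share, c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(others$share), 1, tolerance = 1e-9)

  # beta = (0.6, 0.3): shares in ratio 4:1 (variance scales with beta^2)
  withr::with_seed(43, {
    y2 <- 0.5 * q[, 3] + 0.6 * q[, 1] + 0.3 * q[, 2] + rnorm(n, 0, 0.5)
  })
  t1b <- t1
  t1b[, "TG"] <- y2
  lp2 <- manual_lag_pairs(t0, t1b)
  fit2 <- fit_dbn(dag, lp2)
  rep2 <- parent_variance_shares(fit2, lp2, "TG")
  o2 <- rep2[rep2$role == "other", ]
  expect_equal(o2$share[o2$parent == "P1"] / o2$share[o2$parent == "P2"],
               4, tolerance = 0.15)
})

test_that("variance-share attribution is exactly order-invariant", {
  gt <- make_ground_truth(4, 2, 2, seed = 3, state_frac = 0, county_frac = 0)
  lp <- build_lag_pairs(simulate_panel(gt, 2, 5, 80, seed = 4))
  target <- gt$dag$arcs$to[which(table(gt$dag$arcs$to)[gt$dag$arcs$to] >= 3)[1]]
  fit <- fit_dbn(gt$dag, lp)
  a <- parent_variance_shares(fit, lp, target)
  # permute the arc rows (hence parent order) and refit
  dag_perm <- two_slice_dag(gt$conditions, gt$dag$arcs[rev(seq_len(nrow(gt$dag$arcs))), ])
  b <- parent_variance_shares(fit_dbn(dag_perm, lp), lp, target)
  a <- dplyr::arrange(tibble::as_tibble(a), parent)
  b <- dplyr::arrange(tibble::as_tibble(b), parent)
  expect_equal(a$raw_ev, b$raw_ev, tolerance = 1e-12)
})

test_that("self-only targets report no non-self shares", {
  gt <- ar_truth(2, 0.7)
  lp <- build_lag_pairs(simulate_panel(gt, 2, 3, 40, seed = 5))
  fit <- fit_dbn(gt$dag, lp)
  rep <- parent_variance_shares(fit, lp, "C01")
  expect_equal(nrow(rep[rep$role == "other", ]), 0)
  expect_match(attr(rep, "note"), "condition itself")
  expect_error(parent_variance_shares(fit_dbn(two_slice_dag(gt$conditions), lp),
                                      lp, "C01"),
               "no parents")
})

test_that("generative simulation is consistent with the fitted model", {
  gt <- make_ground_truth(3, 1, 1, seed = 6, state_frac = 0, county_frac = 0)
  lp <- build_lag_pairs(simulate_panel(gt, 2, 10, 101, seed = 7))
  fit <- fit_dbn(gt$dag, lp)
  sims <- simulate_from_dbn(fit, 1e5, seed = 8)
  expect_identical(as.data.frame(sims),
                   as.data.frame(simulate_from_dbn(fit, 1e5, seed = 8)))
  for (cc in gt$conditions) {
    nd <- fit$nodes[[cc]]
    mu_hat <- nd$intercept + sum(nd$coefficients * fit$t0_mean[names(nd$coefficients)])
    se <- sd(sims[[paste0(cc, "_t1")]]) / sqrt(1e5)
    expect_lt(abs(mean(sims[[paste0(cc, "_t1")]]) - mu_hat), 4 * se)
    # regressing simulated t1 on its parents recovers the fitted coefficients
    refit <- fit_dbn(fit$dag, sims)
    expect_equal(unname(refit$nodes[[cc]]$coefficients),
                 unname(nd$coefficients), tolerance = 0.03)
  }
})

test_that("a null fit simulates uncorrelated slices", {
  gt <- noise_truth(2)
  lp <- build_lag_pairs(simulate_panel(gt, 2, 5, 101, seed = 9))
  fit <- fit_dbn(two_slice_dag(gt$conditions), lp)
  sims <- simulate_from_dbn(fit, 1e5, seed = 10)
  for (cc in gt$conditions) {
    expect_lt(abs(cor(sims[[paste0(cc, "_t0")]], sims[[paste0(cc, "_t1")]])),
              0.02)
  }
})

test_that("stratification dissolves a stratifier-borne association", {
  gt <- mediation_truth()
  lp <- build_lag_pairs(simulate_panel(gt, 2, 5, 500, seed = 11))
  fit <- fit_dbn(gt$dag, lp)
  ss <- stratified_share(fit, "TGT", "FOC", "STR", n_sim = 1e5, seed = 12)
  un <- ss$share[ss$stratum == "unstratified"]
  within <- ss$share[ss$stratum != "unstratified"]
  expect_true(all(within <= un / 3))

  # a focal unrelated to the target keeps a trivial share everywhere
  gt2 <- mediation_truth()
  B <- gt2$coefficients
  B["FOC", "STR"] <- 0 # focal now independent of the stratifier and target
  gt3 <- ground_truth_from_matrix(B)
  fit3 <- fit_dbn(gt3$dag, build_lag_pairs(simulate_panel(gt3, 2, 5, 500,
                                                          seed = 13)))
  ss3 <- stratified_share(fit3, "TGT", "FOC", "STR", n_sim = 1e5, seed = 14)
  expect_true(all(ss3$share < 0.01))

  # Monte-Carlo stability across seeds
  ss4 <- stratified_share(fit, "TGT", "FOC", "STR", n_sim = 1e5, seed = 99)
  expect_lt(abs(ss4$share[1] - un) / un, 0.2)
  expect_error(stratified_share(fit, "TGT", "TGT", "STR"), "distinct")
})
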