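test_that("de-structuring removes county baselines", {
  gt <- make_ground_truth(2, 1, 0, seed = 1, state_frac = 0,
                          county_frac = 0.5)
  panel <- simulate_panel(gt, 5, 8, 80, seed = 2)
  resid <- remove_spatiotemporal(panel)
  # per-county means collapse towards the global mean
  for (cc in gt$conditions) {
    m_raw <- tapply(panel[[cc]], panel$county, mean)
    m_res <- tapply(resid[[cc]], resid$county, mean)
    expect_lt(sd(m_res) / sd(m_raw), 0.15)
  }
  vd <- variance_decomposition(resid)
  expect_true(all(vd$state_prop < 0.05))
  expect_true(all(vd$county_prop < 0.05))
})

test_that("panels without structure pass through nearly unchanged", {
  gt <- noise_truth(2)
  panel <- simulate_panel(gt, 3, 4, 50, seed = 3)
  resid <- remove_spatiotemporal(panel)
  for (cc in gt$conditions) {
    expect_lt(max(abs(resid[[cc]] - panel[[cc]])) / sd(panel[[cc]]), 0.25)
  }
})

test_that("prewhitening reduces serial dependence", {
  gt <- ar_truth(2, phi = 0.8, county_sd = 1)
  panel <- simulate_panel(gt, 4, 5, 100, seed = 4)
  white <- remove_spatiotemporal(panel, prewhiten = TRUE)
  for (cc in gt$conditions) {
    expect_lt(abs(lag1_autocor(white, cc)), 0.15)
  }
})

test_that("static learning finds chains and stays acyclic", {
  # independent columns at a heavy penalty: empty DAG
  withr::with_seed(5, noise <- as.data.frame(matrix(rnorm(3000), ncol = 3)))
  names(noise) <- c("A", "B", "C")
  expect_equal(nrow(learn_static(noise, w = 16)$arcs), 0)

  # chain truth A -> B -> C with strong effects: skeleton recovered
  withr::with_seed(6, {
    A <- rnorm(3000)
    B <- 0.9 * A + rnorm(3000, 0, 0.5)
    C <- 0.9 * B + rnorm(3000, 0, 0.5)
  })
  dag <- learn_static(data.frame(A, B, C), w = 1)
  skel <- unique(apply(dag$arcs, 1, function(r) paste(sort(r), collapse = "-")))
  expect_setequal(skel, c("A-B", "B-C"))

  # acyclicity on feedback-rich data, checked on every run
  gt <- make_ground_truth(8, 5, 5, seed = 7)
  panel <- simulate_panel(gt, 3, 6, 60, seed = 8)
  for (w in c(1, 4)) {
    sdag <- learn_static(panel, w = w)
    g <- igraph::graph_from_data_frame(sdag$arcs,
                                       vertices = sdag$conditions)
    expect_true(igraph::is_dag(g))
  }
})

test_that("coefficient comparison fractions behave on constructed fits", {
  gt <- ar_truth(3, 0.6)
  panel <- simulate_panel(gt, 2, 4, 60, seed = 9)
  dag <- learn_static(panel, w = 1)
  # guarantee at least one arc for the comparison
  if (nrow(dag$arcs) == 0) {
    dag$arcs <- tibble::tibble(from = "C01", to = "C02")
  }
  fit <- fit_static(dag, panel)
  same <- compare_coefficients(fit, fit)
  expect_equal(same$inflated_fraction, 0)
  expect_equal(same$sign_flip_fraction, 0)

  halved <- fit
  for (cc in names(halved$nodes)) {
    halved$nodes[[cc]]$coefficients <- halved$nodes[[cc]]$coefficients / 2
  }
  doubled_vs_half <- compare_coefficients(fit, halved)
  expect_equal(doubled_vs_half$inflated_fraction, 1)
  expect_equal(doubled_vs_half$sign_flip_fraction, 0)
})

test_that("spatial structure inflates static coefficients", {
  gt_struct <- make_ground_truth(5, 2, 3, seed = 10)
  gt_flat <- make_ground_truth(5, 2, 3, seed = 10, state_frac = 0,
                               county_frac = 0)
  inflation <- function(gt, seed) {
    panel <- simulate_panel(gt, 5, 8, 80, seed = seed)
    raw_dag <- learn_static(panel, w = 4)
    resid <- remove_spatiotemporal(panel)
    comp <- compare_coefficients(fit_static(raw_dag, panel),
                                 fit_static(learn_static(resid, w = 4), resid),
                                 arcs = "union")
    comp$inflated_fraction
  }
  expect_gt(inflation(gt_struct, 11), inflation(gt_flat, 11))
})

test_that("arc classification against the folded truth is exact", {
  folded_fb <- fold(two_slice_dag(c("A", "B"),
                                  data.frame(from = c("A", "B"),
                                             to = c("B", "A"))))
  sdag <- structure(
    list(conditions = c("A", "B"),
         arcs = tibble::tibble(from = "A", to = "B")),
    class = "static_dag"
  )
  expect_equal(classify_arcs(sdag, folded_fb)$fractions[["feedback_collapsed"]], 1)

  folded_rev <- fold(two_slice_dag(c("A", "B"),
                                   data.frame(from = "B", to = "A")))
  expect_equal(classify_arcs(sdag, folded_rev)$fractions[["reversed"]], 1)

  folded_mix <- fold(two_slice_dag(c("A", "B", "C", "D"),
                                   data.frame(from = "A", to = "B")))
  sdag2 <- structure(
    list(conditions = c("A", "B", "C", "D"),
         arcs = tibble::tibble(from = c("A", "C"), to = c("B", "D"))),
    class = "static_dag"
  )
  cls <- classify_arcs(sdag2, folded_mix)
  expect_equal(cls$fractions[["correct"]], 0.5)
  expect_equal(cls$fractions[["spurious"]], 0.5)
  expect_equal(sum(cls$fractions), 1, tolerance = 1e-9)
})

test_that("static BNs misrepresent feedback-rich dynamics", {
  gt <- make_ground_truth(12, 8, 10, seed = 12)
  panel <- simulate_panel(gt, 4, 10, 60, seed = 13)
  cls <- classify_arcs(learn_static(panel, w = 4), fold(gt$dag))
  expect_lt(cls$fractions[["correct"]], 0.5)
  expect_gt(cls$fractions[["feedback_collapsed"]] +
              cls$fractions[["reversed"]] + cls$fractions[["spurious"]], 0.5)
})
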