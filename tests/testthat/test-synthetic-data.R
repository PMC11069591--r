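test_that("ground truths have the requested folded arc classes", {
  gt <- make_ground_truth(p = 2, n_feedback = 1, n_unidirectional = 0, seed = 1)
  folded <- fold(gt$dag)
  expect_equal(sum(folded$arcs$class == "feedback"), 1)
  expect_equal(sum(folded$arcs$class == "unidirectional"), 0)
  expect_equal(sum(folded$arcs$class == "autoloop"), 2)

  gt2 <- make_ground_truth(p = 3, n_feedback = 0, n_unidirectional = 2, seed = 7)
  folded2 <- fold(gt2$dag)
  expect_equal(sum(folded2$arcs$class == "unidirectional"), 2)
  expect_equal(sum(folded2$arcs$class == "feedback"), 0)
  expect_equal(sum(folded2$arcs$class == "autoloop"), 3)
})

test_that("dense ground truths are rescaled to a stable VAR(1)", {
  gt <- make_ground_truth(p = 12, n_feedback = 8, n_unidirectional = 10, seed = 3)
  ev <- eigen(gt$coefficients, only.values = TRUE)$values
  expect_lt(max(Mod(ev)), 1)
  # self-arcs present on every node, magnitude < 1
  expect_true(all(abs(diag(gt$coefficients)) < 1))
  expect_true(all(diag(gt$coefficients) != 0))
  expect_true(all(gt$residual_sd > 0))
})

test_that("infeasible arc counts are rejected", {
  expect_error(make_ground_truth(p = 3, n_feedback = 2, n_unidirectional = 2),
               "exceed")
  expect_error(make_ground_truth(p = 1, n_feedback = 0, n_unidirectional = 0),
               "at least 2")
})

test_that("ground truths are deterministic given the seed and round-trip to JSON", {
  a <- make_ground_truth(5, 2, 3, seed = 42)
  b <- make_ground_truth(5, 2, 3, seed = 42)
  expect_identical(a$coefficients, b$coefficients)

  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(a, path)
  back <- read_ground_truth(path)
  expect_equal(back$coefficients, a$coefficients)
  expect_equal(back$dag$arcs, a$dag$arcs)
  expect_equal(back$state_sd, a$state_sd)
})

test_that("white-noise panels have near-zero lag-1 autocorrelation", {
  gt <- noise_truth(p = 2)
  panel <- simulate_panel(gt, n_states = 5, counties_per_state = 10,
                          n_weeks = 100, seed = 1)
  for (cc in gt$conditions) {
    expect_lt(abs(lag1_autocor(panel, cc)), 0.05)
  }
})

test_that("AR(1) panels recover their self-coefficient as lag-1 autocorrelation", {
  gt <- ar_truth(p = 2, phi = 0.8)
  panel <- simulate_panel(gt, n_states = 5, counties_per_state = 10,
                          n_weeks = 100, seed = 2)
  for (cc in gt$conditions) {
    expect_lt(abs(lag1_autocor(panel, cc) - 0.8), 0.05)
  }
})

test_that("simulated panels are reproducible, tidy and nonnegative", {
  gt <- make_ground_truth(3, 1, 1, seed = 5)
  a <- simulate_panel(gt, 2, 3, 20, seed = 9)
  b <- simulate_panel(gt, 2, 3, 20, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(names(a)[1:3], c("state", "county", "week"))
  vals <- as.matrix(a[gt$conditions])
  expect_true(all(is.finite(vals)) && all(vals >= 0))
  expect_lt(attr(a, "clipped_fraction"), 0.001)
  # contiguous weeks per county, counties nested in one state
  expect_silent(dbnpanel:::validate_panel(a))
})

test_that("long stable series are stationary in mean", {
  gt <- make_ground_truth(3, 1, 1, seed = 6)
  panel <- simulate_panel(gt, 2, 5, 300, seed = 7)
  for (cc in gt$conditions) {
    # per-county half-difference: its mean should be 0 under stationarity
    d <- tapply(seq_len(nrow(panel)), panel$county, function(i) {
      mean(panel[[cc]][i][panel$week[i] < 150]) -
        mean(panel[[cc]][i][panel$week[i] >= 150])
    })
    t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_lt(abs(t_stat), 3)
  }
})

test_that("unstable ground truths are refused by the simulator", {
  gt <- ar_truth(p = 2, phi = 0.5)
  gt$coefficients <- gt$coefficients * 3 # spectral radius 1.5
  expect_error(simulate_panel(gt, 2, 2, 10, seed = 1), "unstable")
})

test_that("single-cell injection hits the requested rate deterministically", {
  gt <- noise_truth(3)
  panel <- simulate_panel(gt, 3, 5, 50, seed = 4)
  holed <- inject_missingness(panel, 0.10, "single", seed = 5)
  frac <- mean(is.na(as.matrix(holed[gt$conditions])))
  expect_gte(frac, 0.095)
  expect_lte(frac, 0.105)
  again <- inject_missingness(panel, 0.10, "single", seed = 5)
  expect_identical(
    which(is.na(as.matrix(holed[gt$conditions]))),
    which(is.na(as.matrix(again[gt$conditions])))
  )
  inj <- attr(holed, "injected")
  expect_equal(nrow(inj), sum(is.na(as.matrix(holed[gt$conditions]))))
  expect_false(anyNA(inj$true_value))
})

test_that("batch injection removes maximal runs of exactly four weeks", {
  gt <- noise_truth(2)
  panel <- simulate_panel(gt, 3, 5, 60, seed = 4)
  holed <- inject_missingness(panel, 0.20, "batch4", seed = 5)
  holed <- dplyr::arrange(holed, state, county, week)
  for (cc in gt$conditions) {
    runs <- tapply(is.na(holed[[cc]]), holed$county, function(m) {
      r <- rle(m)
      r$lengths[r$values]
    })
    lens <- unlist(runs)
    expect_true(length(lens) > 0 && all(lens == 4))
  }
  frac <- mean(is.na(as.matrix(holed[gt$conditions])))
  expect_lt(abs(frac - 0.20), 0.005)
})

test_that("injection rejects invalid rates", {
  gt <- noise_truth(2)
  panel <- simulate_panel(gt, 2, 2, 10, seed = 1)
  expect_error(inject_missingness(panel, 0, seed = 1), "rate")
  expect_error(inject_missingness(panel, 1.2, seed = 1), "rate")
})
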