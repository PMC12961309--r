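test_that("GMFP is the across-channel standard deviation", {
  # identical channels -> zero dispersion
  eeg <- flat_eeg(matrix(3, 4, 50))
  expect_equal(gmfp(eeg), rep(0, 50))

  # two channels at +1 and -1 uV -> 1 uV (divisor K, not K-1)
  eeg2 <- flat_eeg(rbind(rep(1, 20), rep(-1, 20)))
  expect_equal(gmfp(eeg2), rep(1, 20))

  # homogeneity: scaling all channels scales GMFP by |c|
  set.seed(3)
  m <- matrix(rnorm(5 * 30), 5, 30)
  expect_equal(gmfp(flat_eeg(-2.5 * m)), 2.5 * gmfp(flat_eeg(m)))

  expect_error(gmfp(flat_eeg(matrix(1, 1, 10))), "2 channels")
})

test_that("GMFA integrates GMFP with the trapezoidal rule", {
  # zero signal -> 0
  expect_equal(gmfa(flat_eeg(matrix(0, 2, 200)), c(0, 199)), 0)

  # constant GMFP of 1 uV over 0.1 s -> 0.1 uV*s
  eeg <- flat_eeg(rbind(rep(1, 201), rep(-1, 201)))
  expect_equal(gmfa(eeg, c(0, 100)), 0.1)

  # triangular ramp 0 -> 2 uV over 0.1 s -> 0.1 uV*s (trapezoid exact)
  ramp <- seq(0, 2, length.out = 101)
  eeg2 <- flat_eeg(rbind(ramp, -ramp))
  expect_equal(gmfa(eeg2, c(0, 100)), 0.1)

  expect_error(gmfa(eeg, c(90, 90.5)), "fewer than 2")
})

test_that("relative GMFA is a percentage of the default run", {
  expect_equal(relative_gmfa(5, 5), 100)
  expect_equal(relative_gmfa(1.2573 * 7, 7), 125.73)
  expect_equal(relative_gmfa(0, 3), 0)
  expect_error(relative_gmfa(1, 0), "positive")
})

test_that("sweep grids cover the design ranges", {
  g <- make_sweep_grid(50)
  expect_equal(nrow(g), 51)
  expect_equal(range(g$value), c(25, 75))
  expect_true(0 %in% g$percent)
  expect_equal(g$value[g$percent == 0], 50)

  g2 <- make_sweep_grid(33.75)
  expect_equal(range(g2$value), c(16.875, 50.625))

  expect_equal(nrow(make_sweep_grid(10, span_percent = 0,
                                    step_percent = 2)), 1)
  expect_error(make_sweep_grid(10, step_percent = 0), "positive")
  expect_error(make_sweep_grid(10, 50, 3), "divisible")
})

test_that("the combined sweep plan counts 101 distinct simulations", {
  plan <- plan_sweep(c("b", "C4"))
  expect_equal(nrow(plan), 101)
  expect_equal(sum(plan$parameter == "default"), 1)
  expect_equal(sum(plan$parameter == "b"), 50)
  expect_equal(sum(plan$parameter == "C4"), 50)
  expect_equal(range(plan$value[plan$parameter == "b"]), c(25, 75))
  expect_equal(range(plan$value[plan$parameter == "C4"]),
               c(16.875, 50.625))
})

test_that("the repetition manifest scales to the full design", {
  plan <- plan_repetitions(n_subjects = 20, n_reps = 100)
  expect_equal(nrow(plan), 2000)
  expect_equal(length(unique(plan$seed)), 2000)
  # deterministic
  expect_identical(plan, plan_repetitions(20, 100))
  expect_equal(nrow(plan_repetitions(2, 3)), 6)
})

test_that("peak windows are disjoint and increasing", {
  w <- peak_windows()
  expect_named(w, c("N45", "P60", "N100", "P185"))
  expect_error(peak_windows(N45 = c(30, 90)), "disjoint")
})

test_that("derived seeds are stable, distinct and below 2^31", {
  s1 <- derive_seed(1, "sweep_b")
  expect_identical(s1, derive_seed(1, "sweep_b"))
  expect_false(s1 == derive_seed(1, "sweep_C4"))
  expect_false(s1 == derive_seed(2, "sweep_b"))
  expect_lt(s1, 2^31)
  expect_gte(s1, 1)
})
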