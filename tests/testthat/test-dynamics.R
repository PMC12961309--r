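test_that("psp kernel matches its closed form", {
  expect_equal(psp_kernel(-1, 3.25, 0.01), 0)
  # maximum at t = tau with value H/e
  expect_equal(psp_kernel(0.01, 3.25, 0.01), 3.25 / exp(1))
  expect_equal(psp_kernel(0.01, 3.25, 0.01), 1.1956, tolerance = 1e-4)
  tt <- seq(0, 0.1, by = 1e-4)
  expect_lte(max(psp_kernel(tt, 22, 0.02)), 22 / exp(1))
  expect_error(psp_kernel(0.1, 3.25, 0), "positive")
})

test_that("firing-rate sigmoid has the required anchor points", {
  expect_equal(sigmoid_rate(6, 2.5, 6, 0.56), 2.5)
  expect_equal(sigmoid_rate(1e4, 2.5, 6, 0.56), 5)
  expect_equal(sigmoid_rate(-1e4, 2.5, 6, 0.56), 0)
  # quarter saturation at v0 - ln(3)/r
  expect_equal(sigmoid_rate(6 - log(3) / 0.56, 2.5, 6, 0.56), 1.25)
  v <- seq(-20, 30, by = 0.5)
  expect_true(all(diff(sigmoid_rate(v)) > 0))
})

test_that("coupling sigmoid saturates and crosses its midpoint", {
  cp <- coupling_params(gmin = 1, gmax = 9, gmid = 6, gsigma = 1,
                        ga = 0.56)
  expect_equal(coupling_sigmoid(-1e4, cp), 1)
  expect_equal(coupling_sigmoid(1e4, cp), 9)
  expect_equal(coupling_sigmoid(6, cp), 5)  # (gmin + gmax) / 2
  x <- seq(-10, 20, by = 0.5)
  expect_true(all(diff(coupling_sigmoid(x, cp)) > 0))
})

test_that("jr_rhs implements the population equations", {
  p <- jr_params()
  z <- rep(0, 2)
  state <- list(y0 = z, y1 = z, y2 = z, y3 = z, y4 = z, y5 = z)
  d <- jr_rhs(state, qcou = 0, stimulus_now = 0, noise_now = 0, p = p)
  s0 <- sigmoid_rate(0, p$vmax, p$v0, p$r)
  expect_equal(d$dy3, rep(p$A * p$a * s0, 2))
  expect_equal(d$dy5, rep(p$B * p$b * p$C4 * s0, 2))
  expect_equal(d$dy4, rep(p$A * p$a * (p$C2 * s0 + p$qcon), 2))

  # stimulus perturbs only the EIN second-order equation
  d_stim <- jr_rhs(state, 0, stimulus_now = 100, noise_now = 0, p = p)
  expect_equal(d_stim$dy3, d$dy3)
  expect_equal(d_stim$dy5, d$dy5)
  expect_false(isTRUE(all.equal(d_stim$dy4, d$dy4)))

  # IIN drive is linear in C4
  p2 <- p
  p2$C4 <- 2 * p$C4
  d2 <- jr_rhs(state, 0, 0, 0, p2)
  expect_equal(d2$dy5, 2 * d$dy5)
  expect_equal(d2$dy3, d$dy3)
})

test_that("delayed_input sums weighted delayed PSPs", {
  n <- 3
  conn <- connectome(matrix(0, n, n),
                     matrix(10, n, n) - diag(10, n))
  delays <- compute_delays(conn, 2.5, 0.1)  # 40 steps off-diagonal
  hist <- matrix(4, n, 100)
  # all weights zero -> zero input
  expect_equal(delayed_input(hist, conn, delays, 1, 50), 0)

  # two regions, M_12 = 0.5, psp_2 = 4 -> x_1 = 2
  conn2 <- connectome(matrix(c(0, 0, 0.5, 0), 2, 2),
                      matrix(c(0, 10, 10, 0), 2, 2))
  d2 <- compute_delays(conn2, 2.5, 0.1)
  expect_equal(delayed_input(matrix(4, 2, 100), conn2, d2, 1, 50), 2)

  # zero delays, all-ones off-diagonal weights, uniform psp p
  conn3 <- connectome(matrix(1, n, n) - diag(n), matrix(0, n, n))
  d3 <- compute_delays(conn3, 2.5, 0.1)
  expect_equal(delayed_input(matrix(7, n, 10), conn3, d3, 2, 1),
               (n - 1) * 7)

  # insufficient history is an error
  expect_error(delayed_input(hist, conn, delays, 1, 10),
               "insufficient history")
})

test_that("alter_parameter scales exactly one parameter", {
  p <- jr_params()
  expect_equal(alter_parameter(p, "b", -50)$b, 25)
  expect_equal(alter_parameter(p, "C4", 50)$C4, 50.625)
  expect_equal(alter_parameter(p, "b", 0), p)
  pb <- alter_parameter(p, "b", 20)
  expect_equal(pb[names(pb) != "b"], p[names(p) != "b"])
  expect_error(alter_parameter(p, "A", 10), "unknown parameter")
  expect_warning(alter_parameter(p, "b", 60), "outside")
})

test_that("integration is deterministic and symmetric", {
  conn <- connectome(matrix(0, 3, 3), matrix(20, 3, 3) - diag(20, 3))
  cfg <- sim_config(duration = 0.6, transient = 0.3,
                    pre_stimulus = 0.05, seed = 5)
  s1 <- simulate_network(conn, noise = noise_spec(std = 30, seed = 5),
                         config = cfg)
  s2 <- simulate_network(conn, noise = noise_spec(std = 30, seed = 5),
                         config = cfg)
  expect_identical(s1$psp, s2$psp)

  # zero coupling, zero noise, identical parameters: identical regions
  s3 <- simulate_network(conn, noise = noise_spec(std = 0),
                         config = cfg)
  expect_equal(s3$psp[1, ], s3$psp[2, ])
  expect_equal(s3$psp[1, ], s3$psp[3, ])
})

test_that("single node converges to the root-finder equilibrium", {
  p <- jr_params(qcon = 80)
  S <- function(v) sigmoid_rate(v, p$vmax, p$v0, p$r)
  # with all-zero weights the summed input x is 0, but the coupling
  # sigmoid still contributes its floor value at x = 0
  qcou0 <- coupling_sigmoid(0, coupling_params())
  f <- function(y) {
    y0 <- p$A * S(y) / p$a
    y1 <- p$A * (p$C2 * S(p$C1 * y0) + qcou0 + p$qcon) / p$a
    y2 <- p$B * p$C4 * S(p$C3 * y0) / p$b
    y1 - y2 - y
  }
  y_star <- uniroot(f, c(-20, 20), tol = 1e-12)$root
  src <- simulate_network(single_node(), p, stimulus = NULL,
                          noise = noise_spec(std = 0),
                          config = sim_config(duration = 8,
                                              transient = 7))
  expect_equal(tail(src$psp[1, ], 1), y_star, tolerance = 1e-4)
})

test_that("Heun scheme shows second-order convergence in dt", {
  p <- jr_params(qcon = 80)
  run_dt <- function(dt) {
    src <- simulate_network(single_node(), p, stimulus = NULL,
                            noise = noise_spec(std = 0),
                            config = sim_config(dt = dt,
                                                duration = 0.2,
                                                transient = 0.1,
                                                pre_stimulus = 0,
                                                sampling_rate = 1000))
    src$final_state
  }
  ref <- run_dt(0.005)
  e1 <- sqrt(sum((run_dt(0.1) - ref)^2))
  e2 <- sqrt(sum((run_dt(0.05) - ref)^2))
  expect_gt(e1 / e2, 3)    # ~4 for O(dt^2)
  expect_lt(e1 / e2, 5.5)
})

test_that("noise-driven single node has an alpha-band spectral peak", {
  src <- simulate_network(single_node(), jr_params(qcon = 220),
                          stimulus = NULL,
                          noise = noise_spec(std = 22, seed = 7),
                          config = sim_config(duration = 6,
                                              transient = 1))
  x <- src$psp[1, ] - mean(src$psp[1, ])
  sp <- spec.pgram(ts(x, frequency = 1000), spans = 9, plot = FALSE,
                   taper = 0.1)
  f_peak <- sp$freq[which.max(sp$spec)]
  expect_gte(f_peak, 7)
  expect_lte(f_peak, 13)
})

test_that("divergent parameter sets raise an instability error", {
  conn <- single_node()
  expect_error(
    simulate_network(conn, jr_params(A = 3.25e5, qcon = 1e5),
                     stimulus = NULL, noise = noise_spec(std = 0),
                     config = sim_config(duration = 1.2,
                                         transient = 1)),
    "diverged")
})
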