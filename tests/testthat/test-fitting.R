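# SC fitting on a small network: target generated by the model itself
# so the optimum is known to be reachable.

make_fit_problem <- function(n = 10, seed = 42, perturb = FALSE) {
  conn <- synth_connectome(n, seed = seed)
  conn <- normalize_weights(conn, "max_one")
  conn$weights <- conn$weights / mean(rowSums(conn$weights))
  lf <- synth_leadfield(6, n, seed = seed,
                        coords = attr(conn, "coords"))
  stim <- synth_stimulus(n, 1:2, amplitude = 2000)
  cfg <- sim_config(duration = 0.9, transient = 0.5,
                    pre_stimulus = 0.05, seed = seed)
  p <- jr_params(qcon = 80)
  cp <- coupling_params(gmax = 90)

  conn_target <- conn
  if (perturb) {
    set.seed(seed + 1)
    idx <- which(upper.tri(conn$weights), arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), ceiling(0.1 * nrow(idx))), ,
                drop = FALSE]
    w <- conn_target$weights
    w[pick] <- w[pick] * 3
    w[pick[, c(2, 1), drop = FALSE]] <- w[pick]
    conn_target$weights <- w
  }
  src <- simulate_network(conn_target, p, cp, stim,
                          noise_spec(std = 0), cfg)
  target <- project(src, lf, reference = "average")
  list(conn = conn, conn_target = conn_target, lf = lf, stim = stim,
       cfg = cfg, p = p, cp = cp, target = target)
}

test_that("pcc scores flattened channel x time correlation", {
  set.seed(1)
  a <- eeg_timeseries(seq(0, 0.05, 1e-3), matrix(rnorm(3 * 51), 3))
  b <- a
  expect_equal(pcc(a, a), 1)
  b$data <- -a$data
  expect_equal(pcc(a, b), -1)
  b$data <- 2 * a$data + 3
  expect_equal(pcc(a, b), 1)
  b$data <- matrix(0, 3, 51)
  expect_error(pcc(a, b), "zero variance")
  b <- eeg_timeseries(seq(0, 0.05, 1e-3), matrix(rnorm(2 * 51), 2))
  expect_error(pcc(a, b), "shape")
})

test_that("a self-generated target is already near the optimum", {
  prob <- make_fit_problem(n = 6, seed = 7)
  fit <- optimize_sc(prob$conn, prob$target, prob$lf, prob$p, prob$cp,
                     prob$stim, noise_spec(std = 0), prob$cfg,
                     fit_config(iterations = 5, reps = 1,
                                epoch_window = c(0, 0.3)),
                     seed = 1)
  expect_gte(fit$pcc, 0.99)
  # near-zero weight change from the optimum start
  expect_lt(max(abs(fit$weights - prob$conn$weights)),
            0.05 * max(prob$conn$weights))
})

test_that("optimization recovers a perturbed connectome", {
  prob <- make_fit_problem(n = 10, seed = 42, perturb = TRUE)
  fit <- optimize_sc(prob$conn, prob$target, prob$lf, prob$p, prob$cp,
                     prob$stim, noise_spec(std = 0), prob$cfg,
                     fit_config(loss = "mse", learning_rate = 1,
                                gradient = "finite_difference",
                                iterations = 25,
                                epoch_window = c(0, 0.3)),
                     seed = 3)
  expect_true(all(is.finite(fit$loss_trace)))
  expect_gt(fit$pcc, fit$initial_pcc)
  # parameter recovery: final loss well below the initial loss
  expect_lt(fit$best_loss, 0.1 * fit$initial_loss)
  # non-negativity under clipping
  expect_true(all(fit$weights >= 0))
})

test_that("repetitions are seeded, distinct and reproducible", {
  prob <- make_fit_problem(n = 6, seed = 7, perturb = TRUE)
  fitcfg <- fit_config(iterations = 3, reps = 3,
                       epoch_window = c(0, 0.3))
  fits <- run_repetitions(prob$conn, prob$target, prob$lf, prob$p,
                          prob$cp, prob$stim, noise_spec(std = 10),
                          prob$cfg, fitcfg, master_seed = 5)
  expect_length(fits, 3)
  seeds <- vapply(fits, `[[`, integer(1), "seed")
  expect_equal(length(unique(seeds)), 3)
  traces <- lapply(fits, `[[`, "loss_trace")
  expect_false(identical(traces[[1]], traces[[2]]))

  # same seed list -> identical results
  fitcfg2 <- fit_config(iterations = 3, reps = 2,
                        seeds = c(101L, 102L),
                        epoch_window = c(0, 0.3))
  f1 <- run_repetitions(prob$conn, prob$target, prob$lf, prob$p,
                        prob$cp, prob$stim, noise_spec(std = 10),
                        prob$cfg, fitcfg2, master_seed = 1)
  f2 <- run_repetitions(prob$conn, prob$target, prob$lf, prob$p,
                        prob$cp, prob$stim, noise_spec(std = 10),
                        prob$cfg, fitcfg2, master_seed = 99)
  expect_equal(f1[[1]]$weights, f2[[1]]$weights)
  expect_equal(f1[[2]]$loss_trace, f2[[2]]$loss_trace)
})
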