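test_that("connectome construction validates shapes and values", {
  conn <- connectome(diag(3), matrix(0, 3, 3))
  expect_s3_class(conn, "connectome")
  expect_equal(conn$n_regions, 3)

  expect_error(connectome(matrix(0, 3, 4), matrix(0, 3, 3)), "square")
  expect_error(connectome(matrix(0, 3, 3), matrix(0, 4, 4)),
               "do not match")
  expect_error(connectome(-diag(3), matrix(0, 3, 3)), "non-negative")
  w <- diag(3); w[1, 2] <- NaN
  expect_error(connectome(w, matrix(0, 3, 3)), "non-finite")
  d <- matrix(1, 3, 3)
  expect_error(connectome(diag(3), d), "diagonal")
})

test_that("plain-text round trip reproduces matrices bit-exactly", {
  conn <- tiny_connectome(5)
  conn$weights[1, 2] <- conn$weights[2, 1] <- pi * 1e-7  # awkward value
  wp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".txt")
  write_connectome(conn, wp, dp, lp)
  back <- read_connectome(wp, dp, lp)
  expect_identical(back$weights, conn$weights)
  expect_identical(back$distances, conn$distances)
  expect_identical(back$labels, conn$labels)
})

test_that("read_connectome rejects mismatched matrix files", {
  wp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0 1 0", "1 0 1", "0 1 0"), wp)
  writeLines(c("0 1 1 1", "1 0 1 1", "1 1 0 1", "1 1 1 0"), dp)
  expect_error(read_connectome(wp, dp), "do not match")
})

test_that("normalize_weights modes behave as documented", {
  conn <- tiny_connectome(4)
  conn$weights <- conn$weights * 4 / max(conn$weights)

  expect_equal(max(normalize_weights(conn, "max_one")$weights), 1)
  expect_identical(normalize_weights(conn, "none")$weights,
                   conn$weights)

  # hand computation: {0, e-1, e^2-1} -> log1p -> {0, 1, 2} -> {0, .5, 1}
  conn2 <- connectome(matrix(c(0, exp(1) - 1, exp(1) - 1, exp(2) - 1),
                             2, 2),
                      matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sort(unique(as.vector(
    normalize_weights(conn2, "log_scaled")$weights))),
    c(0, 0.5, 1))

  conn$weights[] <- 0
  expect_error(normalize_weights(conn, "max_one"), "all-zero")
})

test_that("compute_delays converts distances to integer steps", {
  conn <- connectome(matrix(1, 2, 2), matrix(c(0, 25, 25, 0), 2, 2))
  # 25 mm at 2.5 m/s = 10 ms = 100 steps of 0.1 ms
  dt <- compute_delays(conn, speed = 2.5, dt = 0.1)
  expect_equal(dt$delays_steps[1, 2], 100L)
  expect_equal(diag(dt$delays_steps), c(0L, 0L))

  # 1 mm at 2.5 m/s = 0.4 ms -> rounds to 0 steps at dt = 1 ms
  conn2 <- connectome(matrix(1, 2, 2), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(compute_delays(conn2, 2.5, 1)$delays_steps[1, 2], 0L)

  expect_error(compute_delays(conn, speed = 0), "positive")
  expect_error(compute_delays(conn, dt = -1), "positive")
})

test_that("delays are homogeneous in conduction speed before rounding", {
  conn <- tiny_connectome(4)
  set.seed(2)
  conn$distances <- conn$distances * matrix(runif(16, 0.5, 4), 4)
  conn$distances <- (conn$distances + t(conn$distances)) / 2
  diag(conn$distances) <- 0
  slow <- conn$distances / 2.5
  fast <- conn$distances / 5
  expect_equal(slow / 2, fast)  # pre-rounding homogeneity
  # and rounded tables agree with direct computation
  expect_equal(compute_delays(conn, 5, 0.1)$delays_steps,
               matrix(as.integer(round(fast / 0.1)), 4))
})
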