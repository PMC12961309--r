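test_that("synthetic connectomes are valid, symmetric and seeded", {
  c1 <- synth_connectome(20, seed = 3)
  c2 <- synth_connectome(20, seed = 3)
  expect_identical(c1$weights, c2$weights)
  expect_identical(c1$distances, c2$distances)
  expect_equal(c1$weights, t(c1$weights))
  expect_equal(diag(c1$weights), rep(0, 20))
  expect_silent(vtep:::validate_connectome(c1))

  c3 <- synth_connectome(200, seed = 1)
  expect_equal(dim(c3$weights), c(200, 200))
  expect_lte(max(c3$distances), 140)
  expect_error(synth_connectome(1), "at least 2")
})

test_that("synthetic lead fields have full shape and no dead channels", {
  lf <- synth_leadfield(62, 200, seed = 1)
  expect_equal(dim(lf$gain), c(62, 200))
  for (s in 0:9) {
    g <- synth_leadfield(16, 20, seed = s)$gain
    expect_true(all(rowSums(abs(g)) > 0))
  }
  expect_identical(synth_leadfield(16, 20, seed = 4)$gain,
                   synth_leadfield(16, 20, seed = 4)$gain)
})

test_that("synthetic stimulus hits exactly the listed regions", {
  st <- synth_stimulus(200, 49:53, amplitude = 500)
  expect_equal(sum(st$region_amplitudes > 0), 5)
  expect_equal(which(st$region_amplitudes > 0), 49:53)
  expect_equal(max(st$region_amplitudes), 500)  # focal region
  expect_true(all(diff(st$region_amplitudes[49:53]) <= 0))

  expect_equal(synth_stimulus(10, integer(0))$region_amplitudes,
               rep(0, 10))
  expect_equal(max(synth_stimulus(10, 2:4, 0)$region_amplitudes), 0)
  expect_error(synth_stimulus(10, c(2, 2)), "duplicate")
})

test_that("the synthetic target TEP shows the four deflections", {
  spec <- fixture_spec(n_regions = 40, n_channels = 16, seed = 2)
  lf <- synth_leadfield(16, 40, seed = 2)
  tep <- synth_target_tep(spec, lf, stim_indices = 1:5)
  expect_equal(range(tep$time), c(-0.1, 0.4))

  g <- gmfp(tep)
  t_ms <- tep$time * 1000
  for (i in seq_len(nrow(spec$tep_peaks))) {
    pk <- spec$tep_peaks[i, ]
    win <- t_ms >= pk$latency_ms - 1.5 * pk$width_ms &
      t_ms <= pk$latency_ms + 1.5 * pk$width_ms
    # a local GMFP maximum lies inside the peak's own window
    expect_gt(max(g[win]), 1.5 * stats::median(g[t_ms < 0]))
  }

  # channel peaks are in the physiological range
  expect_gt(max(abs(tep$data)), 4)
  expect_lt(max(abs(tep$data)), 15)

  # same seed -> identical epoch; zero amplitudes -> noise floor
  tep2 <- synth_target_tep(spec, lf, stim_indices = 1:5)
  expect_identical(tep$data, tep2$data)
  spec0 <- spec
  spec0$tep_peaks$amplitude_uv <- 0
  flat <- synth_target_tep(spec0, lf, stim_indices = 1:5)
  expect_lt(max(abs(flat$data)), 1)
})

test_that("fixture bundles are consistent and round-trip to disk", {
  fx <- make_fixture(preset = "test", seed = 5)
  expect_equal(fx$connectome$n_regions, 20)
  expect_equal(nrow(fx$lead_field$gain), 16)
  expect_equal(ncol(fx$lead_field$gain), 20)
  expect_equal(sum(fx$stimulus$region_amplitudes > 0), 3)

  fxp <- make_fixture(preset = "paper", seed = 5)
  expect_equal(fxp$connectome$n_regions, 200)
  expect_equal(nrow(fxp$lead_field$gain), 62)
  expect_equal(sum(fxp$stimulus$region_amplitudes > 0), 5)
  # stimulated regions lie in one hemisphere of the coordinate set
  coords <- attr(fxp$connectome, "coords")
  expect_true(all(coords[fxp$stim_indices, 1] < 0))

  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  back <- read_fixture(dir)
  expect_identical(back$connectome$weights, fx$connectome$weights)
  expect_equal(back$lead_field$gain, fx$lead_field$gain,
               tolerance = 1e-12)
  expect_equal(back$stimulus$region_amplitudes,
               fx$stimulus$region_amplitudes)
  expect_equal(back$target$data, fx$target$data, tolerance = 1e-10)
})
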