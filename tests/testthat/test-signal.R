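test_that("closed-form steady state matches the Bloch stepper across T1 and B1", {
  p <- study_protocol()
  t1 <- seq(0.3, 5.0, by = 0.2)
  for (b1 in c(0.8, 1.0, 1.2)) {
    cf <- simulate_signals(p, t1, b1_scale = b1)
    bl <- simulate_signals_bloch(p, t1, b1_scale = b1)
    expect_lt(max(abs(cf$s1 - bl$s1)), 1e-8)
    expect_lt(max(abs(cf$s2 - bl$s2)), 1e-8)
  }
})

test_that("signal limits: zero flip gives zero signal, short T1 fully recovers", {
  p <- study_protocol()
  z <- simulate_signals(p, 1.3, b1_scale = 0)
  expect_identical(c(z$s1, z$s2), c(0, 0))
  s <- simulate_signals(p, 1e-6)
  expect_equal(s$s1, sin(5 * pi / 180), tolerance = 1e-6)
  expect_equal(s$s2, sin(5 * pi / 180), tolerance = 1e-6)
})

test_that("signal model scales linearly with m0 and rejects bad inputs", {
  p <- study_protocol()
  s1 <- simulate_signals(p, 1.3, m0 = 1)
  s2 <- simulate_signals(p, 1.3, m0 = 2.5)
  expect_equal(s2$s1, 2.5 * s1$s1)
  expect_error(simulate_signals(p, -1), "positive")
  expect_error(mp2rage_protocol(ti1 = 3, ti2 = 1), "ti1 < ti2")
  expect_error(mp2rage_protocol(tr_mp2rage = 3.5), "fit inside")
})

test_that("UNI combination is bounded and hits its closed-form extremes", {
  expect_equal(uni_from_signals(list(s1 = 1, s2 = 1)), 0.5)
  expect_equal(uni_from_signals(list(s1 = 1, s2 = -1)), -0.5)
  expect_equal(uni_from_signals(list(s1 = 0, s2 = 1)), 0)
  expect_error(uni_from_signals(list(s1 = 0, s2 = 0)), "undefined")
  expect_equal(uni_from_signals(list(s1 = 0, s2 = 0), zero_undefined = TRUE), 0)
  set.seed(42)
  u <- uni_from_signals(list(s1 = rnorm(2000), s2 = rnorm(2000)))
  expect_true(all(u >= -0.5 & u <= 0.5))
})

test_that("UNI is strictly monotone in T1 over the retained branch", {
  lut <- build_lookup(study_protocol(), 0.3, 5.0, 0.001)
  expect_true(all(diff(lut$uni_values) < 0))
  expect_gt(length(lut$t1_grid), 3000)
})

test_that("lookup inversion is exact at nodes, clamps outside, round-trips", {
  p <- study_protocol()
  lut <- build_lookup(p, 0.3, 5.0, 0.001)
  # self-consistency at nodes
  nodes <- seq(1, length(lut$t1_grid), by = 200)
  inv <- t1_from_uni(lut$uni_values[nodes], lut)
  expect_equal(inv$t1, lut$t1_grid[nodes])
  expect_false(any(inv$out_of_range))
  # clamping contract
  hi <- t1_from_uni(max(lut$uni_values) + 0.01, lut)
  expect_true(hi$out_of_range)
  expect_equal(hi$t1, lut$t1_grid[which.max(lut$uni_values)])
  # forward-simulation round trip within one grid step
  for (t1 in c(0.8, 1.3, 1.912, 2.43, 3.5)) {
    u <- uni_from_signals(simulate_signals(p, t1))
    expect_lt(abs(t1_from_uni(u, lut)$t1 - t1), 0.001 + 1e-9)
  }
  expect_error(build_lookup(p, 0.3, 5.0, step = 10), "step")
  expect_error(build_lookup(p, -1, 5.0), "t1_min")
})

test_that("denoised T1-weighted product suppresses background and multiplies", {
  shp <- c(8, 8, 8)
  uni <- array(-0.5, shp); inv2 <- array(2, shp)
  expect_true(all(denoised_t1w(inv2, uni) == 0))
  expect_true(all(denoised_t1w(array(0, shp), array(0.3, shp)) == 0))
  expect_equal(denoised_t1w(array(2, shp), array(0, shp))[1, 1, 1], 1.0)
  expect_error(denoised_t1w(array(0, c(4, 4, 4)), array(0, shp)), "shape")
})
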