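test_that("reconstruction and edge losses match brute force and kill offsets", {
  set.seed(7)
  x <- unclass(random_stack(5, 5, 3, seed = 1))
  xh <- unclass(random_stack(5, 5, 3, seed = 2))
  expect_equal(reconstruction_l1(x, x), 0)
  expect_equal(reconstruction_l1(x + 0.1, x), 0.1)
  expect_equal(reconstruction_l1(xh, x), loop_l1(xh, x), tolerance = 1e-12)

  expect_equal(edge_l1(x, x), 0)
  expect_equal(edge_l1(x + 0.25, x), 0)  # gradients kill constants
  expect_error(edge_l1(x, x[1:4, , , drop = FALSE]), "shape")

  # 5-px hand calculation: step vs ramp, forward differences
  step <- array(c(0, 0, 1, 1, 1), c(5, 1, 1))
  ramp <- array(c(0, 0.25, 0.5, 0.75, 1), c(5, 1, 1))
  # row gradients: step (0,1,0,0,0) vs ramp (.25,.25,.25,.25,0)
  # |diff| = (.25,.75,.25,.25,0) -> mean = 0.3; column term 0; average = 0.15
  expect_equal(edge_l1(step, ramp), 0.15)
})

test_that("spectral coherence penalizes inter-band differences as written", {
  same <- array(0.4, c(4, 4, 3))
  expect_equal(spectral_coherence(same), 0)
  bands <- array(0, c(4, 4, 3))
  bands[, , 2] <- 0.5; bands[, , 3] <- 1
  expect_equal(spectral_coherence(bands), 1.0)

  set.seed(8)
  r <- unclass(random_stack(6, 6, 3, seed = 3))
  oracle <- loop_l1(r[, , 1], r[, , 2]) + loop_l1(r[, , 2], r[, , 3])
  expect_equal(spectral_coherence(r), oracle, tolerance = 1e-12)

  # residual variant is zero when predicted differences equal the truth's
  truth <- unclass(random_stack(6, 6, 3, seed = 4))
  shifted <- truth + 0.2
  expect_equal(spectral_coherence(shifted, truth, residual = TRUE), 0)
  expect_error(spectral_coherence(array(0, c(4, 4, 2))), "3-channel")
})

test_that("sensor consistency averages over sampled entries only", {
  mz <- make_mosaic(6, 6, "bars", params = list(period = 2))
  expect_equal(sensor_consistency(unclass(mz$x), mz$y), 0)
  expect_equal(sensor_consistency(unclass(mz$x) + 0.2, mz$y), 0.2)

  set.seed(9)
  xh <- unclass(random_stack(6, 6))
  m <- unclass(mz$mask)
  oracle <- sum(abs(m * xh - mz$y$data)) / sum(m)
  expect_equal(sensor_consistency(xh, mz$y), oracle, tolerance = 1e-12)
})

test_that("total loss combines verified terms affinely in the weights", {
  mz <- make_mosaic(4, 4, "flat", params = list(value = 0.5))
  x <- unclass(mz$x)
  # perfect prediction with band-equal NIR truth -> exact zero
  expect_equal(as.numeric(total_loss(x, x, w = loss_weights())), 0)

  # degenerate weights reduce to the reconstruction term
  set.seed(10)
  xh <- unclass(random_stack(4, 4, 6, seed = 5))
  w100 <- loss_weights(rec = 1, edge = 0, spec = 0)
  expect_equal(as.numeric(total_loss(xh, x, w = w100)),
               reconstruction_l1(xh, x))

  # crafted 4x4 pair: total equals the hand-combined verified terms
  w <- loss_weights(rec = 1, edge = 0.1, spec = 0.01)
  expect_equal(as.numeric(total_loss(xh, x, w = w)),
               reconstruction_l1(xh, x) + 0.1 * edge_l1(xh, x) +
                 0.01 * spectral_coherence(xh[, , 4:6]),
               tolerance = 1e-12)

  # sensor-consistency mode swaps the first term
  wm <- loss_weights(rec = 1, edge = 0, spec = 0, mos = 2)
  got <- total_loss(xh, y = mz$y, w = wm, mode = "sensor-consistency")
  expect_equal(as.numeric(got), 2 * sensor_consistency(xh, mz$y))
  expect_error(total_loss(xh, w = w), "requires ground truth")
  expect_error(total_loss(xh, w = w, mode = "sensor-consistency"),
               "requires a mosaic")
  expect_error(loss_weights(rec = -1), ">= 0")
  expect_error(loss_weights(rec = 0, edge = 0, spec = 0, mos = 0), "> 0")
})

test_that("every loss term is nonnegative and zero only at its exact condition", {
  set.seed(11)
  for (i in 1:5) {
    a <- unclass(random_stack(5, 5, 3, seed = 20 + i))
    b <- unclass(random_stack(5, 5, 3, seed = 40 + i))
    expect_gte(reconstruction_l1(a, b), 0)
    expect_gte(edge_l1(a, b), 0)
    expect_gte(spectral_coherence(a), 0)
    expect_gt(reconstruction_l1(a, b), 0)  # random pairs differ
  }
})
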