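test_that("checkerboard mask satisfies the dialect invariants and geometry", {
  # smallest checkerboard, modality-triplet
  m <- build_checkerboard_mask(2, 2)
  expect_equal(m[1, 1, ], c(1, 1, 1, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(m[2, 2, ], c(1, 1, 1, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(m[1, 2, ], c(0, 0, 0, 1, 1, 1), ignore_attr = TRUE)
  expect_equal(m[2, 1, ], c(0, 0, 0, 1, 1, 1), ignore_attr = TRUE)

  # parity count and 4-neighbor property on 4x4
  m4 <- build_checkerboard_mask(4, 4)
  mod <- mask_modality_map(m4)
  expect_equal(sum(mod == "visible"), 8)
  expect_equal(sum(mod == "nir"), 8)
  for (i in 1:4) for (j in 1:4) {
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (all(nb >= 1) && all(nb <= 4))
        expect_true(mod[i, j] != mod[nb[1], nb[2]])
    }
  }

  # per-pixel channel sums per dialect
  expect_true(all(apply(m4, c(1, 2), sum) == 3))
  ms <- build_checkerboard_mask(3, 3, "strict-single-channel")
  expect_true(all(apply(ms, c(1, 2), sum) == 1))

  # strict dialect: enumerate all 9 pixels against the documented sub-pattern
  # (channel = (row0 + floor((row0 + col0)/2)) mod 3 within the modality)
  for (i in 1:3) for (j in 1:3) {
    r0 <- i - 1; c0 <- j - 1
    vis <- (r0 + c0) %% 2 == 0
    sub <- (r0 + (r0 + c0) %/% 2) %% 3
    expected_ch <- sub + 1 + if (vis) 0 else 3
    expect_equal(which(ms[i, j, ] == 1), expected_ch)
  }

  # phase flips the corner; odd dims allowed
  modd <- build_checkerboard_mask(3, 5, phase = "odd")
  expect_equal(mask_modality_map(modd)[1, 1], "nir")
  expect_error(build_checkerboard_mask(1, 4), "height and width")
})

test_that("sampling density is exactly one half for even dims", {
  for (d in list(c(4, 6), c(8, 8), c(10, 4))) {
    m <- build_checkerboard_mask(d[1], d[2])
    expect_equal(sum(mask_modality_map(m) == "visible"), prod(d) / 2)
  }
})

test_that("forward model implements masked sampling with zeros elsewhere", {
  x <- spectral_stack(array(0.5, c(2, 2, 6)))
  m <- build_checkerboard_mask(2, 2)
  y <- apply_forward_model(x, m)
  expect_true(all(y$data[m == 1] == 0.5))
  expect_true(all(y$data[m == 0] == 0))

  # mask idempotence: S * (S * X) = S * X exactly
  expect_identical(y$data * unclass(m), y$data)

  # shape mismatch errors
  expect_error(apply_forward_model(x, build_checkerboard_mask(4, 4)),
               "shape mismatch")
})

test_that("noise is seeded, deterministic, and applied at sampled entries only", {
  set.seed(99)
  x <- random_stack(8, 8)
  m <- build_checkerboard_mask(8, 8)
  nz <- noise_model("gaussian", sigma = 0.01, seed = 0)
  y1 <- apply_forward_model(x, m, nz)
  y2 <- apply_forward_model(x, m, nz)
  expect_identical(y1$data, y2$data)
  expect_true(all(y1$data[m == 0] == 0))

  # closed form E|N(0, sigma)| = sigma * sqrt(2/pi) ~ 0.008; generous band
  mad <- mean(abs(y1$data[m == 1] - unclass(x)[m == 1]))
  expect_gt(mad, 0.004)
  expect_lt(mad, 0.012)

  # poisson-gaussian also deterministic under the same seed
  np <- noise_model("poisson-gaussian", sigma = 0.005, gain = 1e4, seed = 3)
  expect_identical(apply_forward_model(x, m, np)$data,
                   apply_forward_model(x, m, np)$data)
})

test_that("modality extraction partitions the stack and carries mask slices", {
  x <- random_stack(4, 4)
  v <- extract_modality(x, "visible")
  n <- extract_modality(x, "nir")
  expect_equal(unclass(v), unclass(x)[, , 1:3], ignore_attr = TRUE)
  expect_equal(unclass(n), unclass(x)[, , 4:6], ignore_attr = TRUE)
  expect_equal(unclass(combine_modalities(v, n)), unclass(x),
               ignore_attr = TRUE)

  m <- build_checkerboard_mask(4, 4)
  y <- apply_forward_model(x, m)
  yv <- extract_modality(y, "visible")
  expect_s3_class(yv, "modality_mosaic")
  expect_equal(dim(yv$data), c(4, 4, 3))
  expect_equal(unclass(yv$mask), unclass(m)[, , 1:3], ignore_attr = TRUE)
  expect_error(extract_modality(x, "thermal"))
})
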