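test_that("bilinear recovers constants exactly and ramps on the interior", {
  mz <- make_mosaic(6, 6, "flat", params = list(value = 0.5))
  out <- bilinear_demosaic(mz$y)
  expect_equal(max(abs(unclass(out) - 0.5)), 0)

  # the 4-neighbor mean of an affine field equals its center value
  h <- 10; w <- 12
  grads <- cbind(seq(0.1, 0.6, length.out = 6) / (h - 1),
                 seq(0.5, 0.2, length.out = 6) / (w - 1))
  x <- generate_scene(scene_spec("ramp", h, w, list(gradients = grads,
                                                    offsets = rep(0.1, 6))))
  m <- build_checkerboard_mask(h, w)
  rec <- bilinear_demosaic(apply_forward_model(x, m))
  interior <- abs(unclass(rec) - unclass(x))[2:(h - 1), 2:(w - 1), ]
  expect_lt(max(interior), 1e-12)
})

test_that("bilinear is linear, data-consistent, and range-bounded", {
  set.seed(3)
  m <- build_checkerboard_mask(8, 8)
  x1 <- random_stack(8, 8, seed = 1); x2 <- random_stack(8, 8, seed = 2)
  y1 <- apply_forward_model(x1, m); y2 <- apply_forward_model(x2, m)
  a <- 0.7; b <- -1.3
  ycomb <- structure(list(data = a * y1$data + b * y2$data, mask = m),
                     class = "raw_mosaic")
  lhs <- unclass(bilinear_demosaic(ycomb))
  rhs <- a * unclass(bilinear_demosaic(y1)) + b * unclass(bilinear_demosaic(y2))
  expect_lt(max(abs(lhs - rhs)), 1e-12)

  # measured entries preserved exactly
  rec <- unclass(bilinear_demosaic(y1))
  expect_identical(rec * unclass(m), y1$data)

  # convex-combination bound per channel
  for (c in 1:6) {
    sampled <- y1$data[, , c][m[, , c] == 1]
    expect_gte(min(rec[, , c]), min(sampled))
    expect_lte(max(rec[, , c]), max(sampled))
  }

  # strict-single-channel dialect is rejected
  ms <- build_checkerboard_mask(8, 8, "strict-single-channel")
  ys <- apply_forward_model(x1, ms)
  expect_error(bilinear_demosaic(ys), "dialect")
})

test_that("residual CNN is a residual map with validated configuration", {
  cfg <- residual_cnn_config(depth = 3, width = 8, seed = 2)
  w <- residual_cnn_init(cfg, channels = 3)
  mz <- make_mosaic(8, 8, "bars", params = list(period = 4))
  yv <- extract_modality(mz$y, "visible")

  # zero final layer -> output equals Y entrywise
  wz <- w
  wz[["conv3.w"]] <- wz[["conv3.w"]] * 0
  wz[["conv3.b"]] <- wz[["conv3.b"]] * 0
  out <- residual_cnn_demosaic(yv, cfg, wz)
  expect_identical(unclass(out), yv$data, ignore_attr = TRUE)

  # deterministic forward
  o1 <- residual_cnn_demosaic(yv, cfg, w)
  o2 <- residual_cnn_demosaic(yv, cfg, w)
  expect_identical(unclass(o1), unclass(o2))

  # output spatial shape equals input for assorted sizes
  for (d in list(c(5, 7), c(8, 8), c(9, 12))) {
    mzi <- make_mosaic(d[1], d[2], "flat")
    oi <- residual_cnn_demosaic(extract_modality(mzi$y, "nir"), cfg, w)
    expect_equal(dim(unclass(oi))[1:2], d)
  }

  # weight/config mismatch
  expect_error(residual_cnn_demosaic(yv, residual_cnn_config(depth = 4, width = 8), w),
               "weights")
  expect_error(residual_cnn_config(depth = 1), "depth")
  expect_error(residual_cnn_config(kernel = 4), "kernel")
})
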