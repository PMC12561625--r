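test_that("MSE and PSNR match closed forms and stay mutually consistent", {
  x <- unclass(random_stack(6, 6, seed = 1))
  expect_equal(mse(x, x), 0)
  expect_equal(mse(x + 0.1, x), 0.01)
  xh <- unclass(random_stack(6, 6, seed = 2))
  s <- 0
  for (i in seq_along(x)) s <- s + (xh[i] - x[i])^2
  expect_equal(mse(xh, x), s / length(x), tolerance = 1e-12)

  expect_identical(psnr(x, x), Inf)
  expect_equal(psnr(x + 0.1, x, peak = 1), 20, tolerance = 1e-9)
  expect_equal(psnr(xh, x, channel = 2),
               10 * log10(1 / mse(xh, x, 2)), tolerance = 1e-9)
  expect_error(psnr(xh, x, peak = 0), "peak")
})

test_that("windowed SSIM/DSSIM matches the brute-force oracle on 16x16", {
  set.seed(12)
  a <- matrix(runif(16 * 16), 16, 16)
  b <- pmin(pmax(a + rnorm(256, 0, 0.1), 0), 1)
  expect_equal(ssim_map(a, b), oracle_ssim(a, b), tolerance = 1e-6)

  xa <- unclass(random_stack(16, 16, seed = 3))
  xb <- unclass(random_stack(16, 16, seed = 4))
  dv <- unlist(lapply(1:3, function(c) (1 - oracle_ssim(xa[, , c], xb[, , c])) / 2))
  expect_equal(dssim_p95(xa, xb, "visible"),
               unname(quantile(dv, 0.95, type = 7)), tolerance = 1e-6)

  # identical images -> 0; anti-correlated structure -> near 1 on interior
  expect_equal(dssim_p95(xa, xa, "nir"), 0)
  u <- matrix(runif(24 * 24), 24, 24)
  smap <- ssim_map(u, 1 - u)
  expect_gt(min((1 - smap) / 2), 0.9)
  expect_error(ssim_map(matrix(0, 5, 5), matrix(0, 5, 5)), "window")
})

test_that("CIEDE2000 reproduces the published verification pairs to 1e-4", {
  p <- ciede2000_pairs()
  expect_equal(delta_e00(p$lab1, p$lab2), p$expected, tolerance = 1e-4)
  # metric symmetry on random Lab pairs
  set.seed(13)
  l1 <- cbind(runif(20, 0, 100), runif(20, -60, 60), runif(20, -60, 60))
  l2 <- cbind(runif(20, 0, 100), runif(20, -60, 60), runif(20, -60, 60))
  expect_equal(delta_e00(l1, l2), delta_e00(l2, l1), tolerance = 1e-12)
  # independent-library cross-check
  theirs <- vapply(1:20, function(i)
    farver::compare_colour(l1[i, , drop = FALSE], l2[i, , drop = FALSE],
                           from_space = "lab", method = "cie2000")[1, 1], 0)
  expect_equal(delta_e00(l1, l2), theirs, tolerance = 1e-3)
})

test_that("delta E p95 is zero at equality and permutation invariant", {
  x <- unclass(random_stack(12, 12, seed = 5))
  expect_equal(delta_e00_p95(x, x, "visible"), 0)
  xh <- unclass(random_stack(12, 12, seed = 6))
  d1 <- delta_e00_p95(xh, x, "nir")
  expect_gt(d1, 0)
  # shuffling paired pixels leaves the percentile unchanged
  set.seed(14)
  perm <- sample(144)
  xs <- x; xhs <- xh
  for (c in 1:6) {
    xs[, , c] <- matrix(x[, , c][perm], 12, 12)
    xhs[, , c] <- matrix(xh[, , c][perm], 12, 12)
  }
  expect_equal(delta_e00_p95(xhs, xs, "nir"), d1, tolerance = 1e-12)
})

test_that("error maps localize differences; CNR and rise distance are exact", {
  x <- unclass(random_stack(8, 8, seed = 7))
  expect_true(all(error_map(x, x) == 0))
  xh <- x; xh[3, 5, ] <- xh[3, 5, ] + 0.3
  em <- error_map(xh, x)
  expect_equal(em[3, 5], 0.3, tolerance = 1e-12)
  expect_equal(sum(em != 0), 1)

  # CNR arithmetic: fg mean .8, bg mean .2, bg sd .1 -> 6
  img <- matrix(0.2, 8, 8)
  bg_idx <- cbind(rep(5:8, 4), rep(5:8, each = 4))
  vals <- rep(c(0.1, 0.3), 8)  # population sd exactly 0.1
  img[bg_idx] <- vals
  img[1:2, 1:2] <- 0.8
  expect_equal(cnr(img, cbind(rep(1:2, 2), rep(1:2, each = 2)), bg_idx),
               (0.8 - 0.2) / 0.1, tolerance = 1e-9)
  expect_error(cnr(img, bg_idx, bg_idx), "disjoint")

  # rise distance: ideal step <= 1 px; 10-px ramp -> 8 px; logistic closed form
  expect_lte(rise_distance(c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(rise_distance(seq(0, 1, length.out = 11)), 8)
  t <- seq(-8, 8, by = 0.25)
  kslope <- 0.9
  prof <- 1 / (1 + exp(-kslope * t))
  # analytic crossings of the logistic: t = log(p/(1-p)) / k
  expected <- (log(0.9 / 0.1) - log(0.1 / 0.9)) / kslope / 0.25
  # normalization uses the finite endpoints, so allow their small offset
  expect_equal(rise_distance(prof), expected, tolerance = 0.05)
  expect_error(rise_distance(rep(0.5, 5)), "rise")
})

test_that("metric reports keep the PSNR-MSE identity and support both modes", {
  mz <- make_mosaic(16, 16, "bars", params = list(period = 4))
  rec <- bilinear_demosaic(mz$y)
  rep1 <- metric_report(rec, mz$x, mz$y, image_id = "bars", method = "bilinear")
  nm <- c("vis_r", "vis_g", "vis_b", "nir_s", "nir_m", "nir_l")
  for (k in nm) {
    m <- rep1[[paste0("mse_", k)]]
    p <- rep1[[paste0("psnr_", k)]]
    if (m > 0) expect_equal(p, 10 * log10(1 / m), tolerance = 1e-9)
  }
  expect_true(rep1$dssim_p95_vis >= 0 && rep1$dssim_p95_vis <= 1)
  expect_gte(rep1$de00_p95_nir, 0)
  expect_equal(rep1$consistency, 0)  # bilinear preserves measurements

  # perfect reconstruction row
  rep0 <- metric_report(mz$x, mz$x, method = "oracle")
  expect_true(all(unlist(rep0[paste0("mse_", nm)]) == 0))
  expect_true(all(unlist(rep0[paste0("psnr_", nm)]) == Inf))

  # truth-free mode: consistency only
  rep2 <- metric_report(rec, x = NULL, y = mz$y, method = "bilinear")
  expect_named(rep2, c("image_id", "method", "consistency"))
})
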