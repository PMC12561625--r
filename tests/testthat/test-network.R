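test_that("tokenize counts, orders and round-trips patches", {
  set.seed(10)
  z <- array(runif(4 * 4 * 6), c(4, 4, 6))
  ts <- tokenize(z, p = 2)
  expect_equal(nrow(ts$tokens), 4)
  expect_equal(ts$grid, c(2, 2))
  # row-major patch order: token 2 covers rows 1:2, cols 3:4; feature 1 is
  # pixel (1,1) of the patch in channel 1
  expect_equal(ts$tokens[2, 1], z[1, 3, 1])
  expect_equal(ts$tokens[3, 1], z[3, 1, 1])

  # identity projection (d = 6 p^2): unfold then fold reconstructs exactly
  expect_identical(fold_tokens(ts), z)

  # odd dims: padded to 6x6, L = 9, cropped back after folding
  z5 <- array(runif(5 * 5 * 6), c(5, 5, 6))
  t5 <- tokenize(z5, p = 2)
  expect_equal(nrow(t5$tokens), 9)
  expect_equal(t5$padded, c(6, 6))
  expect_identical(fold_tokens(t5), z5)
  expect_error(tokenize(z, p = 0), "p must be")
})

test_that("mask-derived attention bias encodes patch modality classes", {
  m <- build_checkerboard_mask(4, 4)
  # p = 1: tokens split into the two modality classes
  b1 <- build_attention_bias(m, p = 1, beta = 5)
  expect_true(all(b1$bias %in% c(0, -5)))
  expect_true(isSymmetric(b1$bias))
  expect_true(all(diag(b1$bias) == 0))
  cls <- b1$classes
  expect_equal(sum(cls == 1), 8)
  expect_equal(b1$bias[cls == 1, cls == 0] == -5, matrix(TRUE, 8, 8),
               ignore_attr = TRUE)

  # even p: every patch covers both modalities equally -> inert bias
  b2 <- build_attention_bias(m, p = 2, beta = 7)
  expect_true(all(b2$bias == 0))

  # beta = 0 is the neutral element
  b0 <- build_attention_bias(m, p = 1, beta = 0)
  expect_true(all(b0$bias == 0))
  expect_error(build_attention_bias(m, 1, -1), "beta")
})

test_that("masked token attention matches the dense oracle and normalizes", {
  set.seed(21)
  L <- 9; d <- 8; heads <- 2
  tok <- matrix(rnorm(L * d), L, d)
  w <- list(wq = matrix(rnorm(d * d, sd = 0.4), d, d),
            wk = matrix(rnorm(d * d, sd = 0.4), d, d),
            wv = matrix(rnorm(d * d, sd = 0.4), d, d))
  cls <- rep(c(1, 0, 1), 3)
  bias <- list(bias = -2 * outer(cls, cls, "!="), beta = 2)
  out <- masked_attention(tok, bias, w, heads = heads,
                          return_attention = TRUE)
  expect_equal(unclass(out), oracle_token_attention(tok, bias$bias,
                                                    w$wq, w$wk, w$wv, heads),
               tolerance = 1e-6, ignore_attr = TRUE)
  for (A in attr(out, "attention"))
    expect_equal(rowSums(A), rep(1, L), tolerance = 1e-6)

  # zero value projection -> residual identity
  wz <- w; wz$wv <- wz$wv * 0
  expect_equal(masked_attention(tok, bias, wz, heads = heads), tok,
               ignore_attr = TRUE)

  # identical tokens, no bias -> uniform attention rows
  tok_c <- matrix(rep(rnorm(d), each = L), L, d)
  outu <- masked_attention(tok_c, NULL, w, heads = 1,
                           return_attention = TRUE)
  expect_equal(attr(outu, "attention")[[1]],
               matrix(1 / L, L, L), tolerance = 1e-6)
  expect_error(masked_attention(tok, bias, list(wq = diag(3), wk = diag(3),
                                                wv = diag(3))),
               "shapes")
})

test_that("cross-modality attention mass is monotone nonincreasing in beta", {
  set.seed(31)
  # fixed 4-token example, two tokens per class
  d <- 4
  tok <- matrix(rnorm(16), 4, d)
  w <- list(wq = diag(d), wk = diag(d), wv = diag(d))
  cls <- c(1, 0, 1, 0)
  cross_mass <- vapply(c(0, 1, 10, 100), function(beta) {
    bias <- list(bias = -beta * outer(cls, cls, "!="), beta = beta)
    A <- attr(masked_attention(tok, bias, w, heads = 1,
                               return_attention = TRUE), "attention")[[1]]
    sum(A[outer(cls, cls, "!=")])
  }, 0)
  expect_true(all(diff(cross_mass) < 0))
  # beta = 20: cross-class mass is negligible relative to in-class mass
  bias20 <- list(bias = -20 * outer(cls, cls, "!="), beta = 20)
  A20 <- attr(masked_attention(tok, bias20, w, heads = 1,
                               return_attention = TRUE), "attention")[[1]]
  cross <- sum(A20[outer(cls, cls, "!=")])
  within <- sum(A20[outer(cls, cls, "==")])
  expect_lt(cross / within, 1e-6)
})

test_that("MDTA matches the brute-force channel-attention oracle", {
  set.seed(41)
  x <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  C <- 4; heads <- 2
  w <- list(q_pw = matrix(rnorm(C * C, sd = 0.4), C, C),
            q_dw = matrix(rnorm(9 * C, sd = 0.4), 9, C),
            k_pw = matrix(rnorm(C * C, sd = 0.4), C, C),
            k_dw = matrix(rnorm(9 * C, sd = 0.4), 9, C),
            v_pw = matrix(rnorm(C * C, sd = 0.4), C, C),
            v_dw = matrix(rnorm(9 * C, sd = 0.4), 9, C),
            alpha = c(1.3, 0.7),
            proj.w = matrix(rnorm(C * C, sd = 0.4), C, C),
            proj.b = rnorm(C, sd = 0.1))
  expect_equal(mdta_block(x, w, heads = heads), oracle_mdta(x, w, heads),
               tolerance = 1e-6)

  # zero projection -> identity
  wz <- w; wz$proj.w <- wz$proj.w * 0; wz$proj.b <- wz$proj.b * 0
  expect_equal(mdta_block(x, wz, heads = heads), x)
  expect_error(mdta_block(x, w, heads = 3), "heads")
})

test_that("GDFN matches its scalar-loop oracle and closed forms", {
  set.seed(51)
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  w <- make_gdfn_weights(4, 8)
  expect_equal(gdfn_block(x, w, phi = "gelu"),
               oracle_gdfn(x, w, function(v) v * pnorm(v)),
               tolerance = 1e-6)

  # identity weights, phi = identity -> X + X * X
  delta <- matrix(0, 9, 4); delta[5, ] <- 1  # centered depthwise identity
  wi <- list(w1_pw = diag(4), w1_dw = delta, w2_pw = diag(4), w2_dw = delta,
             w0.w = diag(4), w0.b = rep(0, 4))
  expect_equal(gdfn_block(x, wi, phi = "identity"), x + x * x,
               tolerance = 1e-12)

  # zero W0 -> identity
  wz <- w; wz$w0.w <- wz$w0.w * 0; wz$w0.b <- wz$w0.b * 0
  expect_equal(gdfn_block(x, wz), x)
})

test_that("deep path preserves spatial shape and is nonlinear", {
  cfg <- hybrid_config(levels = 2, widths = c(8, 12), mdta_heads = c(1, 2),
                       blocks = 1, token_dim = 8, head_width = 4,
                       shallow = residual_cnn_config(depth = 2, width = 8),
                       seed = 3)
  w <- hybrid_init(cfg)
  dw <- w[grep("^deep\\.", names(w))]
  set.seed(6)
  for (d in list(c(32, 32), c(33, 47), c(65, 40))) {
    fsf <- array(rnorm(prod(d) * 3, sd = 0.3), c(d, 3))
    s <- unclass(build_checkerboard_mask(d[1], d[2]))[, , 1:3]
    out <- deep_feature_path(fsf, s, cfg, dw)
    expect_equal(dim(out), c(d, 3))
  }
  # doubling a bias-free input does not double the output (nonlinearity);
  # give the zero-initialized output conv a random value so the deep
  # features reach the output
  dw[["deep.out.w"]] <- matrix(rnorm(length(dw[["deep.out.w"]]), sd = 0.1),
                               nrow(dw[["deep.out.w"]]))
  fsf <- array(rnorm(32 * 32 * 3, sd = 0.3), c(32, 32, 3))
  s <- unclass(build_checkerboard_mask(32, 32))[, , 1:3]
  o1 <- deep_feature_path(fsf, s, cfg, dw)
  o2 <- deep_feature_path(2 * fsf, s, cfg, dw)
  expect_gt(max(abs(o2 - 2 * o1)), 1e-6)
})

test_that("hybrid forward is a residual chain with deterministic output", {
  cfg <- hybrid_config_tiny(seed = 4)
  w <- hybrid_init(cfg)
  mz <- make_mosaic(12, 12, "bars", params = list(period = 4))
  yn <- extract_modality(mz$y, "nir")

  # zeroing every update branch reduces the network to the shallow Z = Y
  wz <- w
  for (nm in names(wz)) {
    if (grepl("^shallow\\.", nm) || nm == "tok.wo" ||
        startsWith(nm, "deep.out") || startsWith(nm, "head.conv2"))
      wz[[nm]] <- wz[[nm]] * 0
  }
  oz <- hybrid_forward(yn, cfg, wz)
  expect_identical(unclass(oz), yn$data, ignore_attr = TRUE)

  # bit-identical repeated forward
  expect_identical(unclass(hybrid_forward(yn, cfg, w)),
                   unclass(hybrid_forward(yn, cfg, w)))

  # shape contract across sizes, including odd
  for (d in list(c(7, 9), c(16, 10))) {
    mzi <- make_mosaic(d[1], d[2], "flat")
    oi <- hybrid_forward(extract_modality(mzi$y, "visible"), cfg, w)
    expect_equal(dim(unclass(oi))[1:2], d)
  }

  # weight/config mismatch is caught
  expect_error(hybrid_forward(yn, hybrid_config_tiny(), w[-3]), "weights")
})
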