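# Independent brute-force oracles shared by the unit and acceptance tests.
# These re-implement the definitions directly (scalar loops, dense
# softmax, explicit windows) and stay free of the package internals.

oracle_pointwise <- function(x, w, b = NULL) {
  d <- dim(x); co <- ncol(w)
  out <- array(0, c(d[1], d[2], co))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (o in seq_len(co)) {
    acc <- 0
    for (c in seq_len(d[3])) acc <- acc + x[i, j, c] * w[c, o]
    out[i, j, o] <- acc + if (is.null(b)) 0 else b[o]
  }
  out
}

oracle_depthwise <- function(x, w, k = 3) {
  d <- dim(x); pad <- (k - 1) / 2
  out <- array(0, d)
  for (c in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    acc <- 0
    for (dj in seq_len(k)) for (di in seq_len(k)) {
      ii <- i + di - 1 - pad; jj <- j + dj - 1 - pad
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
        acc <- acc + w[(dj - 1) * k + di, c] * x[ii, jj, c]
    }
    out[i, j, c] <- acc
  }
  out
}

oracle_softmax_row <- function(v) exp(v - max(v)) / sum(exp(v - max(v)))

oracle_mdta <- function(x, w, heads) {
  d <- dim(x); N <- d[1] * d[2]; C <- d[3]; ch <- C / heads
  q <- oracle_depthwise(oracle_pointwise(x, w$q_pw), w$q_dw)
  k <- oracle_depthwise(oracle_pointwise(x, w$k_pw), w$k_dw)
  v <- oracle_depthwise(oracle_pointwise(x, w$v_pw), w$v_dw)
  qm <- matrix(q, N, C); km <- matrix(k, N, C); vm <- matrix(v, N, C)
  outm <- matrix(0, N, C)
  for (h in seq_len(heads)) {
    idx <- (h - 1) * ch + seq_len(ch)
    logits <- matrix(0, ch, ch)
    for (a in seq_len(ch)) for (b in seq_len(ch)) {
      s <- 0
      for (n in seq_len(N)) s <- s + qm[n, idx[a]] * km[n, idx[b]]
      logits[a, b] <- s * w$alpha[h] / N
    }
    A <- t(apply(logits, 1, oracle_softmax_row))
    for (n in seq_len(N)) for (a in seq_len(ch)) {
      s <- 0
      for (b in seq_len(ch)) s <- s + A[a, b] * vm[n, idx[b]]
      outm[n, idx[a]] <- s
    }
  }
  attn <- array(outm, d)
  oracle_pointwise(attn, w$proj.w, w$proj.b) + x
}

oracle_gdfn <- function(x, w, phi = identity) {
  b1 <- oracle_depthwise(oracle_pointwise(x, w$w1_pw), w$w1_dw)
  b2 <- oracle_depthwise(oracle_pointwise(x, w$w2_pw), w$w2_dw)
  oracle_pointwise(phi(b1) * b2, w$w0.w, w$w0.b) + x
}

oracle_token_attention <- function(tok, bias, wq, wk, wv, heads) {
  L <- nrow(tok); d <- ncol(tok); dh <- d / heads
  q <- tok %*% wq; k <- tok %*% wk; v <- tok %*% wv
  out <- matrix(0, L, d)
  for (h in seq_len(heads)) {
    idx <- (h - 1) * dh + seq_len(dh)
    for (i in seq_len(L)) {
      logit <- numeric(L)
      for (j in seq_len(L))
        logit[j] <- sum(q[i, idx] * k[j, idx]) / sqrt(dh) +
          if (is.null(bias)) 0 else bias[i, j]
      a <- oracle_softmax_row(logit)
      for (f in seq_len(dh)) out[i, idx[f]] <- sum(a * v[, idx[f]])
    }
  }
  tok + out
}

make_gdfn_weights <- function(C, hid, seed = 1) {
  set.seed(seed)
  list(w1_pw = matrix(rnorm(C * hid, sd = 0.3), C, hid),
       w1_dw = matrix(rnorm(9 * hid, sd = 0.3), 9, hid),
       w2_pw = matrix(rnorm(C * hid, sd = 0.3), C, hid),
       w2_dw = matrix(rnorm(9 * hid, sd = 0.3), 9, hid),
       w0.w = matrix(rnorm(hid * C, sd = 0.3), hid, C),
       w0.b = rnorm(C, sd = 0.1))
}

oracle_ssim <- function(a, b, win = 11, sigma = 1.5, peak = 1) {
  r <- (win - 1) / 2
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  wmat <- outer(g1, g1); wmat <- wmat / sum(wmat)
  c1 <- (0.01 * peak)^2; c2 <- (0.03 * peak)^2
  H <- nrow(a); W <- ncol(a)
  out <- matrix(NA_real_, H - win + 1, W - win + 1)
  for (i in seq_len(H - win + 1)) for (j in seq_len(W - win + 1)) {
    pa <- a[i:(i + win - 1), j:(j + win - 1)]
    pb <- b[i:(i + win - 1), j:(j + win - 1)]
    mua <- sum(wmat * pa); mub <- sum(wmat * pb)
    va <- sum(wmat * pa^2) - mua^2
    vb <- sum(wmat * pb^2) - mub^2
    cab <- sum(wmat * pa * pb) - mua * mub
    out[i, j] <- ((2 * mua * mub + c1) * (2 * cab + c2)) /
      ((mua^2 + mub^2 + c1) * (va + vb + c2))
  }
  out
}

# published CIEDE2000 verification pairs (Lab1, Lab2, expected dE00)
ciede2000_pairs <- function() {
  m <- rbind(
    c(50, 2.6772, -79.7751, 50, 0, -82.7485, 2.0425),
    c(50, 3.1571, -77.2803, 50, 0, -82.7485, 2.8615),
    c(50, 2.8361, -74.0200, 50, 0, -82.7485, 3.4412),
    c(50, -1.3802, -84.2814, 50, 0, -82.7485, 1.0000),
    c(50, -1.1848, -84.8006, 50, 0, -82.7485, 1.0000),
    c(50, -0.9009, -85.5211, 50, 0, -82.7485, 1.0000),
    c(50, 0, 0, 50, -1, 2, 2.3669),
    c(50, -1, 2, 50, 0, 0, 2.3669),
    c(50, 2.49, -0.001, 50, -2.49, 0.0009, 7.1792),
    c(50, 2.49, -0.001, 50, -2.49, 0.0010, 7.1792),
    c(50, 2.49, -0.001, 50, -2.49, 0.0011, 7.2195),
    c(50, 2.49, -0.001, 50, -2.49, 0.0012, 7.2195),
    c(50, -0.001, 2.49, 50, 0.0009, -2.49, 4.8045),
    c(50, -0.001, 2.49, 50, 0.0010, -2.49, 4.8045),
    c(50, -0.001, 2.49, 50, 0.0011, -2.49, 4.7461),
    c(50, 2.5, 0, 50, 0, -2.5, 4.3065),
    c(50, 2.5, 0, 73, 25, -18, 27.1492),
    c(50, 2.5, 0, 61, -5, 29, 22.8977),
    c(50, 2.5, 0, 56, -27, -3, 31.9030),
    c(50, 2.5, 0, 58, 24, 15, 19.4535),
    c(50, 2.5, 0, 50, 3.1736, 0.5854, 1.0000),
    c(50, 2.5, 0, 50, 3.2972, 0, 1.0000),
    c(50, 2.5, 0, 50, 1.8634, 0.5757, 1.0000),
    c(50, 2.5, 0, 50, 3.2592, 0.3350, 1.0000),
    c(60.2574, -34.0099, 36.2677, 60.4626, -34.1751, 39.4387, 1.2644),
    c(63.0109, -31.0961, -5.8663, 62.8187, -29.7946, -4.0864, 1.2630),
    c(61.2901, 3.7196, -5.3901, 61.4292, 2.2480, -4.9620, 1.8731),
    c(35.0831, -44.1164, 3.7933, 35.0232, -40.0716, 1.5901, 1.8645),
    c(22.7233, 20.0904, -46.6940, 23.0331, 14.9730, -42.5619, 2.0373),
    c(36.4612, 47.8580, 18.3852, 36.2715, 50.5065, 21.2231, 1.4146),
    c(90.8027, -2.0831, 1.4410, 91.1528, -1.6435, 0.0447, 1.4441),
    c(90.9257, -0.5406, -0.9208, 88.6381, -0.8985, -0.7239, 1.5381),
    c(6.7747, -0.2908, -2.4247, 5.8714, -0.0985, -2.2286, 0.6377),
    c(2.0776, 0.0795, -1.1350, 0.9033, -0.0636, -0.5514, 0.9082))
  list(lab1 = m[, 1:3], lab2 = m[, 4:6], expected = m[, 7])
}
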