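#' Checkerboard-aware bilinear demosaicing
#'
#' Reference interpolation baseline. At pixels where a channel's modality was
#' sampled, the measurement is kept exactly; at the complementary pixels each
#' missing channel is the mean of the same channel at the 4 edge-adjacent
#' pixels, all of which are sampled for that modality by the checkerboard
#' property. At borders only in-bounds neighbors (2 or 3) are averaged, so no
#' out-of-frame data is invented.
#'
#' @param y A `raw_mosaic` (6 channels) or `modality_mosaic` (3 channels)
#'   carrying a modality-triplet checkerboard mask.
#' @return A `spectral_stack` of the same channel count.
#' @export
bilinear_demosaic <- function(y) {
  if (!inherits(y, c("raw_mosaic", "modality_mosaic")))
    stop("`y` must be a raw_mosaic or modality_mosaic", call. = FALSE)
  if (!identical(attr(y$mask, "dialect"), "modality-triplet"))
    stop("bilinear_demosaic supports only the modality-triplet dialect",
         call. = FALSE)
  d <- dim(y$data)
  out <- array(0, dim = d)
  for (c in seq_len(d[3])) {
    z <- y$data[, , c]
    m <- y$mask[, , c]
    zm <- z * m
    num <- matrix(0, d[1], d[2]); den <- matrix(0, d[1], d[2])
    # up / down / left / right shifts
    num[-1, ] <- num[-1, ] + zm[-d[1], ];      den[-1, ] <- den[-1, ] + m[-d[1], ]
    num[-d[1], ] <- num[-d[1], ] + zm[-1, ];   den[-d[1], ] <- den[-d[1], ] + m[-1, ]
    num[, -1] <- num[, -1] + zm[, -d[2]];      den[, -1] <- den[, -1] + m[, -d[2]]
    num[, -d[2]] <- num[, -d[2]] + zm[, -1];   den[, -d[2]] <- den[, -d[2]] + m[, -1]
    fill <- num / pmax(den, 1)
    out[, , c] <- m * z + (1 - m) * fill
  }
  ch <- if (d[3] == 6L) hex_channels() else {
    md <- if (inherits(y, "modality_mosaic")) y$modality else "visible"
    if (md == "visible") hex_channels()[1:3] else hex_channels()[4:6]
  }
  spectral_stack(out, channels = ch)
}

#' Residual CNN configuration
#'
#' The learned comparison baseline: a plain convolutional network that sees
#' the concatenated measurements and mask and predicts an additive correction,
#' `Z = Y + R([Y, S])`. The architecture is configuration-driven since only
#' its residual form is prescribed.
#'
#' @param depth Number of convolution layers (>= 2).
#' @param width Feature channels in the hidden layers (>= 4).
#' @param kernel Odd spatial kernel extent in px.
#' @param activation `"relu"` (default), `"gelu"` or `"identity"`.
#' @param warm_start Initialize at the classical interpolation (see
#'   [residual_cnn_init()]); `FALSE` gives the plain random init.
#' @param seed Seed used by [residual_cnn_init()].
#' @return A `rescnn_config` list.
#' @export
residual_cnn_config <- function(depth = 8L, width = 64L, kernel = 3L,
                                activation = "relu", warm_start = TRUE,
                                seed = 0L) {
  if (depth < 2) stop("depth must be >= 2", call. = FALSE)
  if (width < 4) stop("width must be >= 4", call. = FALSE)
  if (kernel %% 2 != 1) stop("kernel must be odd", call. = FALSE)
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 kernel = as.integer(kernel), activation = activation,
                 warm_start = isTRUE(warm_start), seed = as.integer(seed)),
            class = "rescnn_config")
}

#' Initialize residual CNN weights
#'
#' Fan-in-scaled uniform initialization with the config's stored seed. By
#' default the network is warm-started at the classical interpolator: the
#' first layer's leading units compute the masked 4-neighbor average
#' `(1 - S) (*) avg4(Y)` exactly (realizable with ReLU because the mask is
#' binary), middle layers pass these units through, and the final layer maps
#' them one-to-one, so `Z = Y + R([Y, S])` starts as checkerboard-aware
#' bilinear interpolation rather than at the raw mosaic. The remaining
#' units keep the random fan-in init and supply learning capacity.
#'
#' @param cfg A [residual_cnn_config()].
#' @param channels Number of image channels the model reconstructs (3 for a
#'   per-modality model, 6 for a joint model).
#' @param warm_start Start at the classical interpolation (default); needs
#'   `kernel >= 3` and `width >= channels`, otherwise it falls back to the
#'   plain random init.
#' @return Named list of parameter arrays.
#' @export
residual_cnn_init <- function(cfg, channels = 3L,
                              warm_start = !isFALSE(cfg$warm_start)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  k <- cfg$kernel
  cin <- 2L * channels  # [Y, S]
  widths <- c(cin, rep(cfg$width, cfg$depth - 1L), channels)
  ngroup <- max(1L, channels %/% 3L)  # mask triplets share one count group
  exact <- warm_start && k >= 3L && cfg$depth >= 3L &&
    cfg$activation == "relu" && cfg$width >= 3L * channels + 4L * ngroup
  warm <- warm_start && k >= 3L && cfg$width >= channels
  w <- list()
  for (l in seq_len(cfg$depth)) {
    fi <- k * k * widths[l]
    g <- if (l == cfg$depth) { if (warm) 0 else 0.1 } else 1
    w[[sprintf("conv%d.w", l)]] <- init_weight(fi, widths[l + 1L], fi, gain = g)
    w[[sprintf("conv%d.b", l)]] <- rep(0, widths[l + 1L])
  }
  m <- (k - 1L) %/% 2L  # center offset
  row_of <- function(ch, di, dj) (ch * k + dj) * k + di + 1L
  cross <- rbind(c(m - 1L, m), c(m + 1L, m), c(m, m - 1L), c(m, m + 1L))
  put_cross <- function(W, ch, u, value) {
    for (r in seq_len(4)) W[row_of(ch, cross[r, 1], cross[r, 2]), u] <- value
    W
  }
  if (exact) {
    # Border-exact warm start: R([Y,S]) = (1-S) * mean(in-bounds sampled
    # 4-neighbors of Y). The neighbor count is the cross-sum of the binary
    # mask channel (values 2/3/4 at missing pixels, 0 at sampled pixels), so
    # the divide-by-count is realized by ReLU-gated units, one per count.
    # Layer 1 units (per channel c): t_k = cross(Y_c)/k for k = 2,3,4;
    # shared per mask group: u = ReLU(cnt-2), v = ReLU(cnt-3),
    # wng = ReLU(3-cnt), s = S(center).
    w1 <- w[["conv1.w"]]
    tk <- function(c, k2) (c - 1L) * 3L + match(k2, 2:4)  # unit index
    base_sh <- 3L * channels
    sh <- function(g2, j) base_sh + (g2 - 1L) * 4L + j     # u,v,w,s units
    b1 <- w[["conv1.b"]]
    for (c in seq_len(channels)) {
      for (k2 in 2:4) {
        u <- tk(c, k2)
        w1[, u] <- 0
        w1 <- put_cross(w1, c - 1L, u, 1 / k2)
      }
    }
    for (g2 in seq_len(ngroup)) {
      sc <- channels + (g2 - 1L) * 3L  # 0-based mask channel of this group
      u <- sh(g2, 1L); w1[, u] <- 0; w1 <- put_cross(w1, sc, u, 1); b1[u] <- -2
      u <- sh(g2, 2L); w1[, u] <- 0; w1 <- put_cross(w1, sc, u, 1); b1[u] <- -3
      u <- sh(g2, 3L); w1[, u] <- 0; w1 <- put_cross(w1, sc, u, -1); b1[u] <- 3
      u <- sh(g2, 4L); w1[, u] <- 0; w1[row_of(sc, m, m), u] <- 1
    }
    w[["conv1.w"]] <- w1; w[["conv1.b"]] <- b1
    # Layer 2: gated means m_k = ReLU(t_k - gate_k); only the matching
    # count's unit survives, and sampled pixels are suppressed via s.
    w2 <- w[[sprintf("conv%d.w", 2L)]]
    b2 <- w[[sprintf("conv%d.b", 2L)]]
    mk <- function(c, k2) (c - 1L) * 3L + match(k2, 2:4)
    for (c in seq_len(channels)) {
      g2 <- (c - 1L) %/% 3L + 1L
      uu <- sh(g2, 1L); vv <- sh(g2, 2L); ww <- sh(g2, 3L); ss <- sh(g2, 4L)
      u <- mk(c, 2L); w2[, u] <- 0
      w2[row_of(tk(c, 2L) - 1L, m, m), u] <- 1
      w2[row_of(ww - 1L, m, m), u] <- 2
      w2[row_of(ss - 1L, m, m), u] <- -6
      b2[u] <- -2
      u <- mk(c, 3L); w2[, u] <- 0
      w2[row_of(tk(c, 3L) - 1L, m, m), u] <- 1
      w2[row_of(uu - 1L, m, m), u] <- 2
      w2[row_of(vv - 1L, m, m), u] <- -4
      w2[row_of(ss - 1L, m, m), u] <- -2
      b2[u] <- -2
      u <- mk(c, 4L); w2[, u] <- 0
      w2[row_of(tk(c, 4L) - 1L, m, m), u] <- 1
      w2[row_of(vv - 1L, m, m), u] <- 2
      w2[row_of(ss - 1L, m, m), u] <- -2
      b2[u] <- -2
    }
    w[[sprintf("conv%d.w", 2L)]] <- w2; w[[sprintf("conv%d.b", 2L)]] <- b2
    # Layer 3: per channel, sum the three gated means into unit c ...
    w3 <- w[[sprintf("conv%d.w", 3L)]]
    for (c in seq_len(channels)) {
      if (cfg$depth > 3L) w3[, c] <- 0
      for (k2 in 2:4) w3[row_of(mk(c, k2) - 1L, m, m), c] <- 1
    }
    w[[sprintf("conv%d.w", 3L)]] <- w3
    # ... then pass through any remaining layers
    for (l in seq(4L, length.out = max(cfg$depth - 3L, 0L))) {
      wl <- w[[sprintf("conv%d.w", l)]]
      for (c in seq_len(channels)) {
        if (l < cfg$depth) wl[, c] <- 0
        wl[row_of(c - 1L, m, m), c] <- 1
      }
      w[[sprintf("conv%d.w", l)]] <- wl
    }
  } else if (warm) {
    # Interior-exact fallback for depth 2: first layer computes the masked
    # quarter-sum ReLU(avg4(Y) - S), the last layer maps it one-to-one
    # (borders underestimate where neighbors are missing).
    w1 <- w[["conv1.w"]]
    for (u in seq_len(channels)) {
      w1[, u] <- 0
      w1 <- put_cross(w1, u - 1L, u, 0.25)
      w1[row_of(channels + u - 1L, m, m), u] <- -1
    }
    w[["conv1.w"]] <- w1
    for (l in seq(2L, length.out = max(cfg$depth - 2L, 0L))) {
      wl <- w[[sprintf("conv%d.w", l)]]
      for (u in seq_len(channels)) {
        if (l < cfg$depth) wl[, u] <- 0
        wl[row_of(u - 1L, m, m), u] <- 1
      }
      w[[sprintf("conv%d.w", l)]] <- wl
    }
    wl <- w[[sprintf("conv%d.w", cfg$depth)]]
    for (u in seq_len(channels)) wl[row_of(u - 1L, m, m), u] <- 1
    w[[sprintf("conv%d.w", cfg$depth)]] <- wl
  }
  w
}

# ag-graph forward of the correction network R([Y, S]); inputs are nodes
.rescnn_graph <- function(yz, s, cfg, params) {
  act <- .ag_activation(cfg$activation)
  h <- ag_concat_ch(yz, s)
  for (l in seq_len(cfg$depth)) {
    h <- ag_conv2d(h, params[[sprintf("conv%d.w", l)]],
                   params[[sprintf("conv%d.b", l)]], k = cfg$kernel)
    if (l < cfg$depth) h <- act(h)
  }
  ag_add(yz, h)  # Z = Y + R([Y, S])
}

.check_rescnn_weights <- function(cfg, weights, channels) {
  expect <- names(residual_cnn_init(cfg, channels))
  if (!setequal(names(weights), expect))
    stop("weights do not match the residual CNN config ",
         "(expected parameters: ", paste(expect, collapse = ", "), ")",
         call. = FALSE)
  k <- cfg$kernel
  if (nrow(weights[["conv1.w"]]) != k * k * 2L * channels)
    stop("weights were initialized for a different channel count or kernel",
         call. = FALSE)
}

#' Residual CNN demosaicing
#'
#' Runs the learned baseline: `Z = Y + R([Y, S])` with the correction network
#' `R` defined by `cfg` and `weights` (see [residual_cnn_init()],
#' [train_model()]).
#'
#' @param y A `raw_mosaic` or `modality_mosaic`.
#' @param cfg A [residual_cnn_config()].
#' @param weights Named parameter list matching `cfg`.
#' @return A `spectral_stack` with the same channels as `y`.
#' @export
residual_cnn_demosaic <- function(y, cfg, weights) {
  d <- dim(y$data)
  .check_rescnn_weights(cfg, weights, d[3])
  params <- lapply(weights, ag_const)
  z <- .rescnn_graph(ag_const(y$data), ag_const(unclass(y$mask)), cfg, params)
  ch <- if (d[3] == 6L) hex_channels() else {
    md <- if (inherits(y, "modality_mosaic")) y$modality else "visible"
    if (md == "visible") hex_channels()[1:3] else hex_channels()[4:6]
  }
  spectral_stack(z$value, channels = ch)
}
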