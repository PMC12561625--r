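#' Hybrid CNN-transformer configuration
#'
#' Configuration of the full demosaicing network: a shallow residual CNN that
#' restores local structure from the masked measurements, a patch-token
#' attention stage whose logits carry a mask-derived bias, a hierarchical
#' encoder-decoder of transposed-channel-attention (MDTA) and gated
#' feed-forward (GDFN) blocks for long-range context, and a shallow prediction
#' head that merges the two paths.
#'
#' @param patch_size Token patch extent `p` in px; inputs are zero-padded to a
#'   multiple of `p` and cropped back after folding.
#' @param token_dim Token dimension `d` (divisible by `token_heads`).
#' @param token_heads Heads in the token-attention stage.
#' @param levels Encoder levels of the deep path (downsampling by 2 between
#'   levels).
#' @param widths Feature channels per level (length `levels`).
#' @param mdta_heads Channel-attention heads per level (must divide `widths`).
#' @param blocks MDTA+GDFN blocks per level and side.
#' @param expansion Hidden-channel expansion factor of the GDFN.
#' @param phi Gating nonlinearity of the GDFN (`"gelu"`, `"relu"`,
#'   `"identity"`).
#' @param beta Mask-bias strength (>= 0): attention between token patches of
#'   different dominant modalities is penalized by `-beta` in the logits.
#'   Finite by default - cross-modality attention is discouraged, not
#'   forbidden.
#' @param shallow A [residual_cnn_config()] for the shallow path.
#' @param head_width Hidden channels of the prediction head.
#' @param seed Seed used by [hybrid_init()].
#' @return A `hybrid_config` list.
#' @export
hybrid_config <- function(patch_size = 2L, token_dim = 48L, token_heads = 2L,
                          levels = 3L, widths = c(48L, 96L, 192L),
                          mdta_heads = c(1L, 2L, 4L), blocks = 2L,
                          expansion = 2L, phi = "gelu", beta = 10,
                          shallow = residual_cnn_config(depth = 4L, width = 32L),
                          head_width = 16L, seed = 0L) {
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  widths <- rep_len(as.integer(widths), levels)
  mdta_heads <- rep_len(as.integer(mdta_heads), levels)
  if (token_dim %% token_heads != 0)
    stop("token_dim must be divisible by token_heads", call. = FALSE)
  if (any(widths %% mdta_heads != 0))
    stop("widths must be divisible by mdta_heads", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  structure(list(patch_size = as.integer(patch_size),
                 token_dim = as.integer(token_dim),
                 token_heads = as.integer(token_heads),
                 levels = as.integer(levels), widths = widths,
                 mdta_heads = mdta_heads, blocks = as.integer(blocks),
                 expansion = as.integer(expansion), phi = phi, beta = beta,
                 shallow = shallow, head_width = as.integer(head_width),
                 seed = as.integer(seed)),
            class = "hybrid_config")
}

#' Tiny hybrid configuration for scaled-down experiments
#'
#' The single-level, 16-dimensional preset used by the package's desk-scale
#' learning experiments and tests.
#'
#' @param seed Seed for [hybrid_init()].
#' @return A `hybrid_config`.
#' @export
hybrid_config_tiny <- function(seed = 0L) {
  hybrid_config(patch_size = 2L, token_dim = 16L, token_heads = 2L,
                levels = 1L, widths = 16L, mdta_heads = 1L, blocks = 1L,
                expansion = 2L, phi = "gelu", beta = 10,
                shallow = residual_cnn_config(depth = 3L, width = 16L),
                head_width = 8L, seed = seed)
}

.init_mdta <- function(w, prefix, C, heads) {
  w[[paste0(prefix, ".q_pw")]] <- init_weight(C, C, C)
  w[[paste0(prefix, ".q_dw")]] <- init_weight(9L, C, 9L)
  w[[paste0(prefix, ".k_pw")]] <- init_weight(C, C, C)
  w[[paste0(prefix, ".k_dw")]] <- init_weight(9L, C, 9L)
  w[[paste0(prefix, ".v_pw")]] <- init_weight(C, C, C)
  w[[paste0(prefix, ".v_dw")]] <- init_weight(9L, C, 9L)
  w[[paste0(prefix, ".alpha")]] <- rep(1, heads)
  w[[paste0(prefix, ".proj.w")]] <- init_weight(C, C, C, gain = 0.1)
  w[[paste0(prefix, ".proj.b")]] <- rep(0, C)
  w
}

.init_gdfn <- function(w, prefix, C, expansion) {
  hid <- C * expansion
  w[[paste0(prefix, ".w1_pw")]] <- init_weight(C, hid, C)
  w[[paste0(prefix, ".w1_dw")]] <- init_weight(9L, hid, 9L)
  w[[paste0(prefix, ".w2_pw")]] <- init_weight(C, hid, C)
  w[[paste0(prefix, ".w2_dw")]] <- init_weight(9L, hid, 9L)
  w[[paste0(prefix, ".w0.w")]] <- init_weight(hid, C, hid, gain = 0.1)
  w[[paste0(prefix, ".w0.b")]] <- rep(0, C)
  w
}

#' Initialize hybrid network weights
#'
#' Fan-in-scaled uniform initialization driven by the config's stored seed,
#' with two stability choices: the shallow path is warm-started at the
#' classical checkerboard interpolation (see [residual_cnn_init()]) and the
#' final projection of every residual stage (token fold, deep output,
#' prediction head) starts at zero, so the untrained network reproduces the
#' bilinear reconstruction exactly and training learns corrections on top of
#' it. Models are per-modality: they reconstruct 3 channels from a
#' 3-channel mosaic plus its mask slice.
#'
#' @param cfg A [hybrid_config()].
#' @return Named list of parameter arrays.
#' @export
hybrid_init <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  w <- list()
  # shallow residual CNN over [Y, S] (6 input channels -> 3)
  sw <- residual_cnn_init(cfg$shallow, channels = 3L)
  names(sw) <- paste0("shallow.", names(sw))
  w <- c(w, sw)
  # token stage
  p <- cfg$patch_size; d <- cfg$token_dim
  fin <- p * p * 6L
  w[["tok.win"]] <- init_weight(fin, d, fin)
  w[["tok.bin"]] <- rep(0, d)
  for (nm in c("tok.wq", "tok.wk", "tok.wv"))
    w[[nm]] <- init_weight(d, d, d)
  w[["tok.wo"]] <- init_weight(d, p * p * 3L, d, gain = 0)
  # deep path
  w[["deep.embed.w"]] <- init_weight(9L * 6L, cfg$widths[1], 9L * 6L)
  w[["deep.embed.b"]] <- rep(0, cfg$widths[1])
  for (l in seq_len(cfg$levels)) {
    C <- cfg$widths[l]
    for (b in seq_len(cfg$blocks)) {
      w <- .init_mdta(w, sprintf("deep.enc%d.blk%d.mdta", l, b), C,
                      cfg$mdta_heads[l])
      w <- .init_gdfn(w, sprintf("deep.enc%d.blk%d.gdfn", l, b), C,
                      cfg$expansion)
    }
    w[[sprintf("deep.enc%d.tail.w", l)]] <- init_weight(9L * C, C, 9L * C, gain = 0.1)
    w[[sprintf("deep.enc%d.tail.b", l)]] <- rep(0, C)
    if (l < cfg$levels) {
      Cn <- cfg$widths[l + 1]
      w[[sprintf("deep.down%d.w", l)]] <- init_weight(4L * C, Cn, 4L * C)
      w[[sprintf("deep.down%d.b", l)]] <- rep(0, Cn)
      w[[sprintf("deep.up%d.w", l)]] <- init_weight(4L * C, Cn, Cn)
      w[[sprintf("deep.up%d.b", l)]] <- rep(0, C)
      w[[sprintf("deep.fuse%d.w", l)]] <- init_weight(2L * C, C, 2L * C)
      w[[sprintf("deep.fuse%d.b", l)]] <- rep(0, C)
      for (b in seq_len(cfg$blocks)) {
        w <- .init_mdta(w, sprintf("deep.dec%d.blk%d.mdta", l, b), C,
                        cfg$mdta_heads[l])
        w <- .init_gdfn(w, sprintf("deep.dec%d.blk%d.gdfn", l, b), C,
                        cfg$expansion)
      }
      w[[sprintf("deep.dec%d.tail.w", l)]] <- init_weight(9L * C, C, 9L * C, gain = 0.1)
      w[[sprintf("deep.dec%d.tail.b", l)]] <- rep(0, C)
    }
  }
  w[["deep.out.w"]] <- init_weight(9L * cfg$widths[1], 3L, 9L * cfg$widths[1],
                                   gain = 0)
  w[["deep.out.b"]] <- rep(0, 3L)
  # prediction head over [F_HR, S]
  w[["head.conv1.w"]] <- init_weight(9L * 6L, cfg$head_width, 9L * 6L)
  w[["head.conv1.b"]] <- rep(0, cfg$head_width)
  w[["head.conv2.w"]] <- init_weight(9L * cfg$head_width, 3L,
                                     9L * cfg$head_width, gain = 0)
  w[["head.conv2.b"]] <- rep(0, 3L)
  w
}

# multiply by element i of a vector parameter node (learned per-head scale)
.ag_mul_alpha <- function(a, s, i) {
  av <- a$value; sv <- s$value[i]
  ag_node(av * sv, list(a, s),
          function(g) {
            ds <- rep(0, length(s$value)); ds[i] <- sum(g * av)
            list(g * sv, ds)
          })
}

## ---- tokenization ----

.pad_to_multiple <- function(h, w, m) {
  c((m - h %% m) %% m, (m - w %% m) %% m)
}

#' Tokenize a stack into patch tokens
#'
#' Partitions the image into nonoverlapping `p x p` patches (after zero
#' padding to a multiple of `p`) and flattens each into a token, optionally
#' followed by a learned linear projection to dimension `d`. Token order is
#' row-major over the patch grid.
#'
#' @param z `H x W x C` array (or `spectral_stack`).
#' @param s Optional mask array concatenated to `z` before projection.
#' @param p Patch size (>= 1).
#' @param weights Optional projection: list with `w` (`p^2*C_total x d`) and
#'   optional `b` (length `d`). `NULL` means the identity (raw patch pixels).
#' @return A `token_sequence`: list with `tokens` (`L x d` matrix), `p`,
#'   `grid` (patch-grid dims), `dims` (original dims of `z`), `padded`
#'   (padded spatial dims).
#' @export
tokenize <- function(z, s = NULL, p = 2L, weights = NULL) {
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  z <- unclass(z)
  d <- dim(z)
  pad <- .pad_to_multiple(d[1], d[2], p)
  zin <- if (!is.null(s)) {
    s <- unclass(s)
    arr <- array(0, dim = c(d[1], d[2], d[3] + dim(s)[3]))
    arr[, , seq_len(d[3])] <- z
    arr[, , d[3] + seq_len(dim(s)[3])] <- s
    arr
  } else z
  node <- ag_pad_hw(ag_const(zin), pad[1], pad[2])
  tok <- ag_unfold(node, p)
  if (!is.null(weights)) {
    tok <- ag_matmul(tok, ag_const(weights$w))
    if (!is.null(weights$b)) tok <- ag_add_bias(tok, ag_const(weights$b))
  }
  hp <- d[1] + pad[1]; wp <- d[2] + pad[2]
  structure(list(tokens = tok$value, p = as.integer(p),
                 grid = c(hp %/% p, wp %/% p),
                 dims = d, padded = c(hp, wp)),
            class = "token_sequence")
}

#' Fold identity tokens back into an image
#'
#' Inverse of [tokenize()] without projection: reshapes an `L x (p^2*C)`
#' token matrix back to an `H x W x C` array and crops away the padding.
#'
#' @param tseq A `token_sequence` whose `tokens` hold raw patch pixels
#'   (`d = p^2 * C`), or an `L x (p^2*C)` matrix with the remaining arguments
#'   given.
#' @param dims Original `c(H, W, C)`; taken from `tseq` when available.
#' @return `H x W x C` array.
#' @export
fold_tokens <- function(tseq, dims = NULL) {
  if (inherits(tseq, "token_sequence")) {
    tok <- tseq$tokens
    p <- tseq$p
    dims <- if (is.null(dims)) tseq$dims else dims
    hp <- tseq$padded[1]; wp <- tseq$padded[2]
  } else stop("fold_tokens expects a token_sequence", call. = FALSE)
  C <- ncol(tok) %/% (p * p)
  arr <- ag_fold(ag_const(tok), hp, wp, C, p)$value
  arr[seq_len(dims[1]), seq_len(dims[2]), , drop = FALSE]
}

#' Build the mask-derived attention bias
#'
#' Assigns each token patch a dominant modality (majority vote of the pixels
#' it covers) and places `-beta` in the attention logits between patches of
#' different dominant modalities, 0 otherwise. With the checkerboard pattern
#' and an even patch size, every patch covers both modalities equally; the
#' tie is broken uniformly, so the bias degenerates to all zeros (documented:
#' at even `p` the bias is inert).
#'
#' @param s A `sampling_mask` (6 channels; modality = visible/nir per pixel)
#'   or a 3-channel per-modality mask slice (classes: sampled/unsampled).
#' @param p Patch size.
#' @param beta Bias strength (>= 0).
#' @return An `attention_bias`: list with `bias` (`L x L` matrix with entries
#'   in `{0, -beta}`, symmetric, zero diagonal), `beta`, and `classes`
#'   (per-token dominant class).
#' @export
build_attention_bias <- function(s, p, beta) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  s <- unclass(s)
  d <- dim(s)
  cls_px <- if (d[3] == 6L) {
    (apply(s[, , 1:3, drop = FALSE], c(1, 2), sum) > 0) * 1
  } else {
    (apply(s, c(1, 2), sum) > 0) * 1
  }
  pad <- .pad_to_multiple(d[1], d[2], p)
  if (any(pad > 0)) {
    tmp <- matrix(0, d[1] + pad[1], d[2] + pad[2])
    tmp[seq_len(d[1]), seq_len(d[2])] <- cls_px
    cls_px <- tmp
  }
  frac <- ag_unfold(ag_const(array(cls_px, dim = c(dim(cls_px), 1L))), p)$value
  frac <- rowMeans(frac)
  classes <- ifelse(frac >= 0.5, 1L, 0L)  # ties -> class 1
  bias <- -beta * outer(classes, classes, "!=")
  structure(list(bias = bias, beta = beta, classes = classes),
            class = "attention_bias")
}

# shared multi-head token attention graph; t0 node, bias numeric matrix
.token_attention_graph <- function(t0, bias, wq, wk, wv, heads,
                                   collect = NULL) {
  d <- ncol(t0$value)
  dh <- d %/% heads
  q <- ag_matmul(t0, wq); k <- ag_matmul(t0, wk); v <- ag_matmul(t0, wv)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    qh <- ag_cols(q, idx); kh <- ag_cols(k, idx); vh <- ag_cols(v, idx)
    logits <- ag_scale(ag_matmul(qh, ag_t(kh)), 1 / sqrt(dh))
    a <- ag_softmax_rows(logits, bias)
    if (!is.null(collect)) collect[[length(collect) + 1L]] <- a$value
    outs[[h]] <- ag_matmul(a, vh)
  }
  attn <- ag_cbind(outs)
  list(tokens = ag_add(t0, attn), attention = collect)
}

#' Mask-biased token self-attention
#'
#' Scaled dot-product attention over patch tokens with the mask-derived
#' additive bias in the logits, and a residual connection:
#' `T' = T + softmax(Q K' / sqrt(d_h) + M(S)) V` per head.
#'
#' @param tseq A `token_sequence` (or plain `L x d` matrix).
#' @param bias An [build_attention_bias()] result, or `NULL` for no bias.
#' @param weights List with `wq`, `wk`, `wv` (`d x d` matrices).
#' @param heads Number of attention heads (divides `d`).
#' @param return_attention If `TRUE`, attach the per-head attention matrices
#'   as attribute `"attention"`.
#' @return Token matrix `L x d` (a `token_sequence` if one was supplied).
#' @export
masked_attention <- function(tseq, bias, weights, heads = 1L,
                             return_attention = FALSE) {
  tok <- if (inherits(tseq, "token_sequence")) tseq$tokens else tseq
  d <- ncol(tok)
  if (!all(vapply(weights[c("wq", "wk", "wv")],
                  function(w) all(dim(w) == c(d, d)), TRUE)))
    stop("attention weight shapes must be d x d", call. = FALSE)
  if (d %% heads != 0) stop("heads must divide d", call. = FALSE)
  bm <- if (is.null(bias)) NULL else bias$bias
  res <- .token_attention_graph(ag_const(tok), bm,
                                ag_const(weights$wq), ag_const(weights$wk),
                                ag_const(weights$wv), heads,
                                collect = if (return_attention) list() else NULL)
  out <- res$tokens$value
  if (inherits(tseq, "token_sequence")) {
    tseq$tokens <- out
    out <- tseq
  }
  if (return_attention) attr(out, "attention") <- res$attention
  out
}

## ---- MDTA / GDFN graphs ----

.mdta_graph <- function(x, params, prefix, heads) {
  d <- dim(x$value)
  C <- d[3]; N <- d[1] * d[2]
  pw <- function(sfx) params[[paste0(prefix, sfx)]]
  q <- ag_dwconv(ag_pwconv(x, pw(".q_pw")), pw(".q_dw"))
  k <- ag_dwconv(ag_pwconv(x, pw(".k_pw")), pw(".k_dw"))
  v <- ag_dwconv(ag_pwconv(x, pw(".v_pw")), pw(".v_dw"))
  qm <- ag_as_pixmat(q); km <- ag_as_pixmat(k); vm <- ag_as_pixmat(v)
  ch <- C %/% heads
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * ch + seq_len(ch)
    qh <- ag_cols(qm, idx); kh <- ag_cols(km, idx); vh <- ag_cols(vm, idx)
    # channel-wise (transposed) attention: logits are C_h x C_h, cost O(N C^2)
    logits <- ag_scale(ag_matmul(ag_t(qh), kh), 1 / N)
    logits <- .ag_mul_alpha(logits, pw(".alpha"), h)
    a <- ag_softmax_rows(logits)
    outs[[h]] <- ag_matmul(vh, ag_t(a))
  }
  attn <- ag_as_array(ag_cbind(outs), d)
  ag_add(x, ag_pwconv(attn, pw(".proj.w"), pw(".proj.b")))
}

.gdfn_graph <- function(x, params, prefix, phi) {
  act <- .ag_activation(phi)
  pw <- function(sfx) params[[paste0(prefix, sfx)]]
  b1 <- ag_dwconv(ag_pwconv(x, pw(".w1_pw")), pw(".w1_dw"))
  b2 <- ag_dwconv(ag_pwconv(x, pw(".w2_pw")), pw(".w2_dw"))
  gate <- ag_mul(act(b1), b2)
  ag_add(x, ag_pwconv(gate, pw(".w0.w"), pw(".w0.b")))
}

#' Transposed channel attention block (MDTA)
#'
#' Multi-head transposed attention: queries, keys and values are produced by
#' pointwise then depthwise convolutions, attention is computed between
#' channels (a `C_h x C_h` map per head, cost linear in pixel count), and the
#' attended values pass through a pointwise projection with a residual
#' connection. Logits are scaled by `alpha_h / N` with a learned per-head
#' temperature `alpha_h`.
#'
#' @param x `H x W x C` array.
#' @param weights Named list with elements `q_pw`, `q_dw`, `k_pw`, `k_dw`,
#'   `v_pw`, `v_dw` (convolution weights), `alpha` (length `heads`), `proj.w`,
#'   `proj.b`.
#' @param heads Number of channel-attention heads (divides `C`).
#' @return `H x W x C` array.
#' @export
mdta_block <- function(x, weights, heads = 1L) {
  x <- unclass(x)
  if (dim(x)[3] %% heads != 0) stop("heads must divide C", call. = FALSE)
  if (ncol(weights$q_pw) != dim(x)[3])
    stop("weight channel count does not match input", call. = FALSE)
  params <- lapply(weights, ag_const)
  names(params) <- paste0("w.", names(weights))
  .mdta_graph(ag_const(x), params, "w", heads)$value
}

#' Gated feed-forward block (GDFN)
#'
#' `X' = W0 (phi(W1 X) (*) W2 X) + X`, with `W1`, `W2` realized as pointwise
#' followed by depthwise convolutions and `W0` a pointwise projection.
#'
#' @param x `H x W x C` array.
#' @param weights Named list with `w1_pw`, `w1_dw`, `w2_pw`, `w2_dw`, `w0.w`,
#'   `w0.b`.
#' @param phi Gating nonlinearity name.
#' @return `H x W x C` array.
#' @export
gdfn_block <- function(x, weights, phi = "gelu") {
  x <- unclass(x)
  if (nrow(weights$w1_pw) != dim(x)[3])
    stop("weight channel count does not match input", call. = FALSE)
  params <- lapply(weights, ag_const)
  names(params) <- paste0("w.", names(weights))
  .gdfn_graph(ag_const(x), params, "w", phi)$value
}

## ---- deep path and full forward ----

.deep_graph <- function(fsf, s, cfg, params) {
  h <- ag_concat_ch(fsf, s)
  h <- ag_conv2d(h, params[["deep.embed.w"]], params[["deep.embed.b"]], k = 3L)
  skips <- vector("list", max(cfg$levels - 1L, 0L))
  for (l in seq_len(cfg$levels)) {
    for (b in seq_len(cfg$blocks)) {
      h <- .mdta_graph(h, params, sprintf("deep.enc%d.blk%d.mdta", l, b),
                       cfg$mdta_heads[l])
      h <- .gdfn_graph(h, params, sprintf("deep.enc%d.blk%d.gdfn", l, b),
                       cfg$phi)
    }
    h <- ag_add(h, ag_conv2d(h, params[[sprintf("deep.enc%d.tail.w", l)]],
                             params[[sprintf("deep.enc%d.tail.b", l)]], k = 3L))
    if (l < cfg$levels) {
      skips[[l]] <- h
      h <- ag_conv2d_down(h, params[[sprintf("deep.down%d.w", l)]],
                          params[[sprintf("deep.down%d.b", l)]], stride = 2L)
    }
  }
  for (l in rev(seq_len(cfg$levels - 1L))) {
    h <- ag_conv2d_up(h, params[[sprintf("deep.up%d.w", l)]],
                      params[[sprintf("deep.up%d.b", l)]], stride = 2L)
    h <- ag_pwconv(ag_concat_ch(h, skips[[l]]),
                   params[[sprintf("deep.fuse%d.w", l)]],
                   params[[sprintf("deep.fuse%d.b", l)]])
    for (b in seq_len(cfg$blocks)) {
      h <- .mdta_graph(h, params, sprintf("deep.dec%d.blk%d.mdta", l, b),
                       cfg$mdta_heads[l])
      h <- .gdfn_graph(h, params, sprintf("deep.dec%d.blk%d.gdfn", l, b),
                       cfg$phi)
    }
    h <- ag_add(h, ag_conv2d(h, params[[sprintf("deep.dec%d.tail.w", l)]],
                             params[[sprintf("deep.dec%d.tail.b", l)]], k = 3L))
  }
  ag_conv2d(h, params[["deep.out.w"]], params[["deep.out.b"]], k = 3L)
}

#' Hierarchical deep feature path
#'
#' Maps shallow features through the encoder-decoder of MDTA+GDFN blocks,
#' conditioned on the sampling mask, and returns the 3-channel deep feature
#' output. Inputs of arbitrary size are zero-padded to the required multiple
#' and cropped back.
#'
#' @param fsf `H x W x 3` shallow feature array.
#' @param s `H x W x 3` mask slice.
#' @param cfg A [hybrid_config()].
#' @param weights Parameter list from [hybrid_init()] (the `deep.*` entries
#'   are used).
#' @return `H x W x 3` array.
#' @export
deep_feature_path <- function(fsf, s, cfg, weights) {
  fsf <- unclass(fsf); s <- unclass(s)
  d <- dim(fsf)
  m <- 2L^(cfg$levels - 1L)
  pad <- .pad_to_multiple(d[1], d[2], m)
  params <- lapply(weights, ag_const)
  f <- ag_pad_hw(ag_const(fsf), pad[1], pad[2])
  sn <- ag_pad_hw(ag_const(s), pad[1], pad[2])
  out <- .deep_graph(f, sn, cfg, params)
  ag_crop_hw(out, d[1], d[2])$value
}

# full hybrid graph; y, s numeric arrays (H x W x 3); params: node list
.hybrid_graph <- function(y, s, cfg, params) {
  d <- dim(y)
  m <- cfg$patch_size * 2L^(cfg$levels - 1L)
  pad <- .pad_to_multiple(d[1], d[2], m)
  yn <- ag_pad_hw(ag_const(y), pad[1], pad[2])
  sn <- ag_pad_hw(ag_const(s), pad[1], pad[2])
  # shallow path (residual CNN, Z = Y + R([Y, S]))
  sp_params <- params[grep("^shallow\\.", names(params))]
  names(sp_params) <- sub("^shallow\\.", "", names(sp_params))
  z <- .rescnn_graph(yn, sn, cfg$shallow, sp_params)
  # token-attention refinement with mask bias
  sp <- dim(yn$value)
  bias <- build_attention_bias(sn$value, cfg$patch_size, cfg$beta)$bias
  feat <- ag_unfold(ag_concat_ch(z, sn), cfg$patch_size)
  t0 <- ag_add_bias(ag_matmul(feat, params[["tok.win"]]), params[["tok.bin"]])
  t1 <- .token_attention_graph(t0, bias, params[["tok.wq"]],
                               params[["tok.wk"]], params[["tok.wv"]],
                               cfg$token_heads)$tokens
  zr <- ag_matmul(t1, params[["tok.wo"]])
  zhat <- ag_add(z, ag_fold(zr, sp[1], sp[2], 3L, cfg$patch_size))
  # deep path on the refined shallow features, conditioned on the mask
  fdf <- .deep_graph(zhat, sn, cfg, params)
  fhr <- ag_add(zhat, fdf)  # merge shallow + deep features
  # prediction head, residual to the shallow output
  hh <- ag_conv2d(ag_concat_ch(fhr, sn), params[["head.conv1.w"]],
                  params[["head.conv1.b"]], k = 3L)
  hh <- ag_relu(hh)
  hh <- ag_conv2d(hh, params[["head.conv2.w"]], params[["head.conv2.b"]],
                  k = 3L)
  xhat <- ag_add(z, hh)
  list(xhat = ag_crop_hw(xhat, d[1], d[2]),
       z = ag_crop_hw(z, d[1], d[2]))
}

#' Hybrid CNN-transformer forward pass
#'
#' Full reconstruction pipeline for one modality: shallow residual CNN,
#' mask-biased token attention refinement, hierarchical MDTA/GDFN deep path,
#' shallow/deep merge, and a residual prediction head.
#'
#' @param y A `modality_mosaic` (3-channel measurements + mask slice from
#'   [extract_modality()]).
#' @param cfg A [hybrid_config()].
#' @param weights Parameter list from [hybrid_init()] or a trained
#'   checkpoint.
#' @return A 3-channel `spectral_stack`.
#' @export
hybrid_forward <- function(y, cfg, weights) {
  if (!inherits(y, "modality_mosaic"))
    stop("`y` must be a modality_mosaic (see extract_modality())",
         call. = FALSE)
  .check_hybrid_weights(cfg, weights)
  params <- lapply(weights, ag_const)
  out <- .hybrid_graph(y$data, unclass(y$mask), cfg, params)
  ch <- if (y$modality == "visible") hex_channels()[1:3] else hex_channels()[4:6]
  spectral_stack(out$xhat$value, channels = ch)
}

.check_hybrid_weights <- function(cfg, weights) {
  expect <- names(hybrid_init(cfg))
  if (!setequal(names(weights), expect)) {
    missing <- setdiff(expect, names(weights))
    extra <- setdiff(names(weights), expect)
    stop("weights do not match the hybrid config (missing: ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(utils::head(extra, 3), collapse = ", ")),
         ")", call. = FALSE)
  }
  invisible(TRUE)
}
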