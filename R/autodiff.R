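# Minimal reverse-mode autodiff on a dynamic tape. Nodes are environments
# holding a value, an accumulated gradient, parent links and a backward
# closure. Graphs are rebuilt per forward pass (define-by-run); the heavy
# operations (convolutions) call the C++ kernels and BLAS.
#
# Internal: none of this is exported; the network modules build on it.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  req <- FALSE
  for (p in parents) if (isTRUE(p$requires)) { req <- TRUE; break }
  e$requires <- req
  if (req) {
    e$parents <- parents
    e$backfn <- backfn
  } else {
    e$parents <- list()
    e$backfn <- NULL
  }
  .ag$counter <- .ag$counter + 1L
  e$idx <- .ag$counter
  e$grad <- NULL
  class(e) <- "ag_node"
  e
}

ag_param <- function(value, name = NULL) {
  e <- ag_node(value)
  e$requires <- TRUE
  e$name <- name
  e
}

ag_const <- function(value) ag_node(value)

as_ag <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

.ag_acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Reverse sweep from a scalar root. Gradients accumulate into every node
# with requires = TRUE; parameter nodes keep theirs until ag_zero_grad().
ag_backward <- function(root, seed_grad = 1) {
  if (!isTRUE(root$requires)) return(invisible(NULL))
  # collect reachable requiring nodes; visitation is marked on the node
  # itself (an env keyed by node id would grow R's permanent symbol table)
  stack <- list(root)
  nodes <- vector("list", 256L); nn <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (isTRUE(nd$vis)) next
    nd$vis <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) if (isTRUE(p$requires)) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$idx, 0L), decreasing = TRUE)
  .ag_acc(root, seed_grad)
  for (nd in nodes[ord]) {
    nd$vis <- NULL  # reset for the next sweep (param nodes persist)
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      if (isTRUE(ps[[i]]$requires) && !is.null(gs[[i]])) .ag_acc(ps[[i]], gs[[i]])
    }
    if (!is.null(nd$name)) next
    nd$grad <- NULL  # free intermediate gradients early
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- elementwise / linear algebra ops ----

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, s) {  # s plain numeric scalar
  ag_node(a$value * s, list(a), function(g) list(g * s))
}

# multiply by a scalar parameter node (learned temperature)
ag_mul_scalar <- function(a, s) {
  av <- a$value; sv <- s$value
  ag_node(av * sv, list(a, s), function(g) list(g * sv, sum(g * av)))
}

ag_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

ag_t <- function(a) ag_node(t(a$value), list(a), function(g) list(t(g)))

# add a per-channel bias (length C) to an (H, W, C) array or (N, C) matrix
ag_add_bias <- function(a, b) {
  av <- a$value
  if (length(dim(av)) == 3L) {
    d <- dim(av)
    out <- av + rep(b$value, each = d[1] * d[2])
    ag_node(out, list(a, b),
            function(g) list(g, colSums(matrix(g, d[1] * d[2], d[3]))))
  } else {
    out <- sweep(av, 2L, b$value, "+")
    ag_node(out, list(a, b), function(g) list(g, colSums(g)))
  }
}

## ---- activations ----

ag_relu <- function(a) {
  av <- a$value
  m <- av > 0
  ag_node(av * m, list(a), function(g) list(g * m))
}

ag_gelu <- function(a) {  # exact Gaussian-CDF form
  av <- a$value
  ph <- stats::pnorm(av)
  ag_node(av * ph, list(a),
          function(g) list(g * (ph + av * stats::dnorm(av))))
}

ag_identity_act <- function(a) a

.ag_activation <- function(name) {
  switch(name,
         relu = ag_relu,
         gelu = ag_gelu,
         identity = ag_identity_act,
         stop("unknown activation: ", name, call. = FALSE))
}

## ---- convolutions ----

# 2-d convolution, stride 1, "same" zero padding.
# x: (H, W, Cin) node; w: (k^2*Cin, Cout) matrix node; b: length-Cout node or NULL
ag_conv2d <- function(x, w, b = NULL, k = 3L) {
  xv <- x$value
  d <- dim(xv)
  pad <- (k - 1L) %/% 2L
  cols <- cpp_im2col(xv, d[1], d[2], d[3], k, 1L, pad)
  wm <- w$value
  out <- cols %*% wm
  cout <- ncol(wm)
  dim(out) <- c(d[1], d[2], cout)
  node <- ag_node(out, list(x, w),
                  function(g) {
                    dim(g) <- c(d[1] * d[2], cout)
                    dx <- cpp_col2im(g %*% t(wm), d[1], d[2], d[3], k, 1L, pad)
                    dim(dx) <- d
                    list(dx, crossprod(cols, g))
                  })
  if (!is.null(b)) node <- ag_add_bias(node, b) else node
}

# strided conv (downsampling), k = stride, pad 0; spatial dims must divide
ag_conv2d_down <- function(x, w, b = NULL, stride = 2L) {
  xv <- x$value
  d <- dim(xv)
  k <- stride
  cols <- cpp_im2col(xv, d[1], d[2], d[3], k, stride, 0L)
  wm <- w$value
  cout <- ncol(wm)
  ho <- d[1] %/% stride; wo <- d[2] %/% stride
  out <- cols %*% wm
  dim(out) <- c(ho, wo, cout)
  node <- ag_node(out, list(x, w),
                  function(g) {
                    dim(g) <- c(ho * wo, cout)
                    dx <- cpp_col2im(g %*% t(wm), d[1], d[2], d[3], k, stride, 0L)
                    dim(dx) <- d
                    list(dx, crossprod(cols, g))
                  })
  if (!is.null(b)) node <- ag_add_bias(node, b) else node
}

# transpose conv (upsampling by `stride`), kernel k = stride, pad 0.
# w: (k^2*Cout, Cin) matrix node (adjoint layout).
ag_conv2d_up <- function(x, w, b = NULL, stride = 2L) {
  xv <- x$value
  d <- dim(xv)
  k <- stride
  wm <- w$value
  cout <- nrow(wm) %/% (k * k)
  hb <- d[1] * stride; wb <- d[2] * stride
  xm <- xv
  dim(xm) <- c(d[1] * d[2], d[3])
  out <- cpp_col2im(xm %*% t(wm), hb, wb, cout, k, stride, 0L)
  dim(out) <- c(hb, wb, cout)
  node <- ag_node(out, list(x, w),
                  function(g) {
                    gcols <- cpp_im2col(g, hb, wb, cout, k, stride, 0L)
                    dx <- gcols %*% wm
                    dim(dx) <- d
                    list(dx, crossprod(gcols, xm))
                  })
  if (!is.null(b)) node <- ag_add_bias(node, b) else node
}

# depthwise k x k conv, stride 1, same padding; w: (k^2, C) matrix node
ag_dwconv <- function(x, w, k = 3L) {
  xv <- x$value
  d <- dim(xv)
  wm <- w$value
  out <- cpp_dwconv(xv, d[1], d[2], d[3], wm, k)
  dim(out) <- d
  ag_node(out, list(x, w),
          function(g) {
            dx <- cpp_dwconv_dx(g, d[1], d[2], d[3], wm, k)
            dim(dx) <- d
            list(dx, cpp_dwconv_dw(xv, g, d[1], d[2], d[3], k))
          })
}

# pointwise (1x1) convolution expressed as a matmul over pixels
ag_pwconv <- function(x, w, b = NULL) {
  xv <- x$value
  d <- dim(xv)
  wm <- w$value
  cout <- ncol(wm)
  xm <- xv
  dim(xm) <- c(d[1] * d[2], d[3])
  out <- xm %*% wm
  dim(out) <- c(d[1], d[2], cout)
  node <- ag_node(out, list(x, w),
                  function(g) {
                    dim(g) <- c(d[1] * d[2], cout)
                    dx <- g %*% t(wm)
                    dim(dx) <- d
                    list(dx, crossprod(xm, g))
                  })
  if (!is.null(b)) node <- ag_add_bias(node, b) else node
}

## ---- shape ops ----

ag_pad_hw <- function(x, hpad, wpad) {  # zero-pad bottom/right
  if (hpad == 0L && wpad == 0L) return(x)
  xv <- x$value
  d <- dim(xv)
  out <- array(0, dim = c(d[1] + hpad, d[2] + wpad, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- xv
  ag_node(out, list(x),
          function(g) list(g[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]))
}

ag_crop_hw <- function(x, h, w) {
  xv <- x$value
  d <- dim(xv)
  if (d[1] == h && d[2] == w) return(x)
  ag_node(xv[seq_len(h), seq_len(w), , drop = FALSE], list(x),
          function(g) {
            out <- array(0, dim = d)
            out[seq_len(h), seq_len(w), ] <- g
            list(out)
          })
}

ag_concat_ch <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- av
  out[, , da[3] + seq_len(db[3])] <- bv
  ag_node(out, list(a, b),
          function(g) list(g[, , seq_len(da[3]), drop = FALSE],
                           g[, , da[3] + seq_len(db[3]), drop = FALSE]))
}

# view (H, W, C) array as (H*W, C) matrix of pixels and back
ag_as_pixmat <- function(x) {
  xv <- x$value
  d <- dim(xv)
  dim(xv) <- c(d[1] * d[2], d[3])
  ag_node(xv, list(x),
          function(g) { dim(g) <- d; list(g) })
}

ag_as_array <- function(x, d) {
  xv <- x$value
  dm <- dim(xv)
  dim(xv) <- d
  ag_node(xv, list(x),
          function(g) { dim(g) <- dm; list(g) })
}

# column subset of a matrix (multi-head split)
ag_cols <- function(x, idx) {
  xv <- x$value
  ag_node(xv[, idx, drop = FALSE], list(x),
          function(g) {
            out <- matrix(0, nrow(xv), ncol(xv))
            out[, idx] <- g
            list(out)
          })
}

# horizontal concatenation of matrices (multi-head merge)
ag_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  ncols <- vapply(vals, ncol, 0L)
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ag_node(do.call(cbind, vals), nodes,
          function(g) lapply(seq_along(nodes),
                             function(i) g[, starts[i]:ends[i], drop = FALSE]))
}

## ---- patch unfold / fold ----

.unfold_memo <- new.env(parent = emptyenv())

unfold_index <- function(H, W, C, p) {
  key <- paste(H, W, C, p, sep = "_")
  got <- .unfold_memo[[key]]
  if (!is.null(got)) return(got)
  gh <- H %/% p; gw <- W %/% p
  # token order: row-major over the patch grid
  pi <- rep(0:(gh - 1), each = gw)
  pj <- rep(0:(gw - 1), times = gh)
  # feature order within a token: pixel (di fastest, then dj), then channel
  f <- 0:(p * p * C - 1)
  fc <- f %/% (p * p)
  fr <- f %% (p * p)
  fdj <- fr %/% p
  fdi <- fr %% p
  idx <- outer(pi * p + H * p * pj, fdi + H * fdj + H * W * fc, "+") + 1L
  .unfold_memo[[key]] <- idx
  idx
}

# (H, W, C) -> L x (p^2 C) token matrix; p must divide H and W
ag_unfold <- function(x, p) {
  xv <- x$value
  d <- dim(xv)
  idx <- unfold_index(d[1], d[2], d[3], p)
  out <- matrix(xv[idx], nrow(idx), ncol(idx))
  ag_node(out, list(x),
          function(g) {
            dx <- array(0, dim = d)
            dx[idx] <- g
            list(dx)
          })
}

# L x (p^2 C) -> (H, W, C)
ag_fold <- function(tok, H, W, C, p) {
  tv <- tok$value
  idx <- unfold_index(H, W, C, p)
  out <- array(0, dim = c(H, W, C))
  out[idx] <- tv
  ag_node(out, list(tok),
          function(g) list(matrix(g[idx], nrow(idx), ncol(idx))))
}

## ---- softmax and losses ----

# row-wise softmax of a matrix of logits, optional additive constant bias
ag_softmax_rows <- function(x, bias = NULL) {
  z <- x$value
  if (!is.null(bias)) z <- z + bias
  rmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - rmax)
  s <- e / rowSums(e)
  ag_node(s, list(x),
          function(g) list((g - rowSums(g * s)) * s))
}

# mean absolute difference; b may be a node or constant
ag_l1_mean <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  d <- a$value - b$value
  n <- length(d)
  sg <- sign(d)
  ag_node(mean(abs(d)), list(a, b),
          function(g) list(g * sg / n, -g * sg / n))
}

# L1 over sampled entries only: sum(|m * (a - y)|) / sum(m)
ag_l1_masked <- function(a, y, m) {
  av <- a$value
  d <- m * (av - y)
  ns <- sum(m)
  sg <- sign(d) * m
  ag_node(sum(abs(d)) / ns, list(a), function(g) list(g * sg / ns))
}

# forward-difference spatial gradient with replicate boundary (last row/col 0)
ag_fwd_diff <- function(x, axis) {
  xv <- x$value
  d <- dim(xv)
  out <- array(0, dim = d)
  if (axis == 1L) {
    out[-d[1], , ] <- xv[-1L, , , drop = FALSE] - xv[-d[1], , , drop = FALSE]
  } else {
    out[, -d[2], ] <- xv[, -1L, , drop = FALSE] - xv[, -d[2], , drop = FALSE]
  }
  ag_node(out, list(x),
          function(g) {
            dx <- array(0, dim = d)
            if (axis == 1L) {
              dx[-1L, , ] <- g[-d[1], , , drop = FALSE]
              dx[-d[1], , ] <- dx[-d[1], , , drop = FALSE] - g[-d[1], , , drop = FALSE]
            } else {
              dx[, -1L, ] <- g[, -d[2], , drop = FALSE]
              dx[, -d[2], ] <- dx[, -d[2], , drop = FALSE] - g[, -d[2], , drop = FALSE]
            }
            list(dx)
          })
}

ag_weighted_sum <- function(nodes, weights) {
  keep <- which(weights != 0)
  if (!length(keep)) return(ag_const(0))
  acc <- ag_scale(nodes[[keep[1]]], weights[keep[1]])
  for (i in keep[-1]) acc <- ag_add(acc, ag_scale(nodes[[i]], weights[i]))
  acc
}

## ---- parameter initialization and Adam ----

# fan-in scaled uniform init (He-style bound for conv/dense weights);
# residual-branch output projections use a small gain so each block starts
# near the identity and the network's initial output stays at signal scale
init_weight <- function(nrow, ncol, fan_in, gain = 1) {
  b <- gain * sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -b, b), nrow, ncol)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p$value * 0, v = p$value * 0))
}

adam_step <- function(params, state, lr, beta1, beta2, eps = 1e-8, t) {
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  state
}
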