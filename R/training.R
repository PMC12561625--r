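#' Optimizer configuration
#'
#' Adam settings used for all training in this package. The momentum
#' coefficients and initial learning rate follow the published protocol
#' (`beta1 = 0.9`, `beta2 = 0.99`, `lr = 0.001`); the learning rate is held
#' constant within curriculum stages. Batch size is a package default (the
#' protocol does not state one).
#'
#' @param beta1,beta2 Momentum coefficients in `[0, 1)`.
#' @param lr Initial learning rate (> 0).
#' @param batch_size Patches per optimizer step.
#' @param lr_schedule `"cosine"` (default): within each curriculum stage the
#'   learning rate decays from `lr` to `lr * lr_floor` on a half-cosine;
#'   `"constant"` holds `lr` throughout. With Adam and an L1 objective, a
#'   constant rate leaves gradient-noise jitter at the rate's scale and
#'   reconstruction error plateaus well above the model's capacity, so the
#'   decaying schedule is the default.
#' @param lr_floor Final fraction of `lr` under the cosine schedule.
#' @param seed Integer seed covering patch sampling, augmentation draws and
#'   any noise injection.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(beta1 = 0.9, beta2 = 0.99, lr = 0.001,
                             batch_size = 8L,
                             lr_schedule = c("cosine", "constant"),
                             lr_floor = 0.01, seed = 0L) {
  lr_schedule <- match.arg(lr_schedule)
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop("beta1 and beta2 must lie in [0, 1)", call. = FALSE)
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (lr_floor <= 0 || lr_floor > 1)
    stop("lr_floor must lie in (0, 1]", call. = FALSE)
  structure(list(beta1 = beta1, beta2 = beta2, lr = lr,
                 batch_size = as.integer(batch_size),
                 lr_schedule = lr_schedule, lr_floor = lr_floor,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

# stage-local learning rate under the configured schedule
.stage_lr <- function(opt, it, iters) {
  if (identical(opt$lr_schedule, "constant") || iters <= 1) return(opt$lr)
  frac <- (it - 1) / (iters - 1)
  opt$lr * (opt$lr_floor + (1 - opt$lr_floor) * 0.5 * (1 + cos(pi * frac)))
}

#' Progressive patch-size curriculum
#'
#' Ordered training stages of (patch size, iterations). The default is the
#' published schedule: 64 px for 5000 iterations, then 128 px for 2500, then
#' 256 px for 1000 - small patches first, harder large-context patches later.
#'
#' @param stages List of `c(patch_size, iterations)` pairs; patch sizes must
#'   be strictly increasing and iteration counts positive.
#' @return A `curriculum` data frame with columns `patch` and `iters`.
#' @export
curriculum <- function(stages = list(c(64, 5000), c(128, 2500), c(256, 1000))) {
  m <- do.call(rbind, lapply(stages, function(s) as.integer(s[1:2])))
  cur <- data.frame(patch = m[, 1], iters = m[, 2])
  if (any(diff(cur$patch) <= 0))
    stop("curriculum patch sizes must be strictly increasing", call. = FALSE)
  if (any(cur$iters <= 0))
    stop("curriculum iteration counts must be positive", call. = FALSE)
  class(cur) <- c("curriculum", "data.frame")
  cur
}

#' Augmentation configuration
#'
#' @param rotations Nonempty subset of `c(0, 45, 90, 135)` degrees.
#' @param random_crop Enable random cropping.
#' @param crop_size Crop side in px (required when `random_crop` and
#'   [augment()] is called directly; the training loop supplies the stage
#'   patch size).
#' @param seed Seed for the standalone [augment()] call.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(rotations = c(0, 45, 90, 135),
                                random_crop = TRUE, crop_size = NULL,
                                seed = 0L) {
  if (!length(rotations) || !all(rotations %in% c(0, 45, 90, 135)))
    stop("rotations must be a nonempty subset of {0, 45, 90, 135}",
         call. = FALSE)
  structure(list(rotations = rotations, random_crop = random_crop,
                 crop_size = crop_size, seed = as.integer(seed)),
            class = "augmentation_config")
}

# exact 90-degree rotation (index permutation); works per channel
.rot90_arr <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[2], d[1], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- t(x[d[1]:1, , c])
  out
}

# rotate by `deg` in {45, 135} with bilinear resampling, then center-crop to
# the largest axis-aligned square fully inside the rotated frame
.rot_bilinear <- function(x, deg) {
  d <- dim(x)
  side <- floor(min(d[1], d[2]) / sqrt(2))
  th <- deg * pi / 180
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  off <- (side - 1) / 2
  gy <- seq(-off, off, length.out = side)
  # inverse-rotate the output grid into source coordinates
  yy <- outer(gy, gy * 0, "+"); xx <- outer(gy * 0, gy, "+")
  sy <- cy + cos(th) * yy - sin(th) * xx
  sx <- cx + sin(th) * yy + cos(th) * xx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  y0 <- pmin(pmax(y0, 1), d[1] - 1); x0 <- pmin(pmax(x0, 1), d[2] - 1)
  out <- array(0, dim = c(side, side, d[3]))
  for (c in seq_len(d[3])) {
    z <- x[, , c]
    out[, , c] <-
      z[cbind(c(y0), c(x0))] * (1 - fy) * (1 - fx) +
      z[cbind(c(y0), c(x0 + 1))] * (1 - fy) * fx +
      z[cbind(c(y0 + 1), c(x0))] * fy * (1 - fx) +
      z[cbind(c(y0 + 1), c(x0 + 1))] * fy * fx
  }
  out
}

# one augmentation draw from the current RNG stream
.augment_draw <- function(x, rotations, crop = NULL) {
  deg <- if (length(rotations) == 1L) rotations else sample(rotations, 1L)
  x <- unclass(x)
  if (deg == 90) {
    x <- .rot90_arr(x)
  } else if (deg %in% c(45, 135)) {
    x <- .rot_bilinear(x, deg)
  }
  d <- dim(x)
  if (!is.null(crop)) {
    if (crop > d[1] || crop > d[2])
      stop("crop size exceeds image dimensions", call. = FALSE)
    oy <- sample.int(d[1] - crop + 1L, 1L) - 1L
    ox <- sample.int(d[2] - crop + 1L, 1L) - 1L
    x <- x[oy + seq_len(crop), ox + seq_len(crop), , drop = FALSE]
  }
  x
}

#' Augment a scene
#'
#' Random rotation (0/90 degrees as exact index permutations; 45/135 degrees
#' via bilinear resampling followed by a center crop to the largest fully
#' valid square, side `floor(min(H, W) / sqrt(2))`) and optional uniform
#' random crop. Seeded and reproducible.
#'
#' @param x A `spectral_stack` or array.
#' @param cfg An [augmentation_config()].
#' @return Augmented array (a `spectral_stack` when 6-channel).
#' @export
augment <- function(x, cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  crop <- if (isTRUE(cfg$random_crop)) cfg$crop_size else NULL
  out <- .augment_draw(x, cfg$rotations, crop)
  if (dim(out)[3] == 6L) spectral_stack(out) else out
}

## ---- model abstraction over the two trainable architectures ----

.model_kind <- function(net_cfg) {
  if (inherits(net_cfg, "hybrid_config")) "hybrid"
  else if (inherits(net_cfg, "rescnn_config")) "rescnn"
  else stop("net_cfg must be a hybrid_config or rescnn_config", call. = FALSE)
}

.model_init <- function(net_cfg) {
  switch(.model_kind(net_cfg),
         hybrid = hybrid_init(net_cfg),
         rescnn = residual_cnn_init(net_cfg, channels = 3L))
}

# builds the prediction graph from numeric y, s (H x W x 3) and node params
.model_graph <- function(net_cfg, y, s, params) {
  switch(.model_kind(net_cfg),
         hybrid = .hybrid_graph(y, s, net_cfg, params)$xhat,
         rescnn = .rescnn_graph(ag_const(y), ag_const(s), net_cfg, params))
}

# supervised loss graph mirroring total_loss() on a 3-channel modality patch
.loss_graph_supervised <- function(xhat, x, w, modality) {
  terms <- list(rec = ag_l1_mean(xhat, x))
  gy_h <- ag_fwd_diff(xhat, 1L); gx_h <- ag_fwd_diff(xhat, 2L)
  gy <- .spatial_grad(x)
  terms$edge <- ag_scale(ag_add(ag_l1_mean(gy_h, gy$gy),
                                ag_l1_mean(gx_h, gy$gx)), 0.5)
  weights <- c(w$rec, w$edge)
  nodes <- list(terms$rec, terms$edge)
  if (modality == "nir" && w$spec > 0) {
    d <- dim(x)
    ch <- function(i) ag_node(xhat$value[, , i, drop = FALSE], list(xhat),
                              local({ii <- i; function(g) {
                                out <- array(0, dim = d); out[, , ii] <- g; list(out)
                              }}))
    s12 <- ag_l1_mean(ch(1), ch(2))
    s23 <- ag_l1_mean(ch(2), ch(3))
    nodes <- c(nodes, list(ag_add(s12, s23)))
    weights <- c(weights, w$spec)
  }
  ag_weighted_sum(nodes, weights)
}

.checkpoint <- function(kind, net_cfg, weights, modality, log = NULL,
                        meta = list()) {
  structure(list(kind = kind, config = net_cfg, weights = weights,
                 modality = modality, log = log, meta = meta),
            class = "hex_checkpoint")
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle the architecture config, the flat named parameter list,
#' the modality the model reconstructs, and the training log. Round-trips are
#' bit-exact.
#'
#' @param ckpt A `hex_checkpoint`.
#' @param path File path.
#' @return `load_checkpoint` returns the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "hex_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "hex_checkpoint"))
    stop("not a hexdemosaic checkpoint: ", path, call. = FALSE)
  ckpt
}

#' Run a checkpoint on a mosaic
#'
#' @param ckpt A `hex_checkpoint`.
#' @param y A `modality_mosaic` matching the checkpoint's modality.
#' @return 3-channel `spectral_stack`.
#' @export
predict_checkpoint <- function(ckpt, y) {
  if (!is.null(ckpt$modality) && inherits(y, "modality_mosaic") &&
      !identical(y$modality, ckpt$modality))
    warning("mosaic modality differs from the checkpoint's")
  if (ckpt$kind == "hybrid") hybrid_forward(y, ckpt$config, ckpt$weights)
  else residual_cnn_demosaic(y, ckpt$config, ckpt$weights)
}

# evaluate mean supervised loss over scenes (eval mode, no gradients)
.validate <- function(net_cfg, weights, scenes, modality, w, noise,
                      mask_phase) {
  params <- lapply(weights, ag_const)
  vals <- vapply(scenes, function(sc) {
    d <- dim(unclass(sc))
    mask <- build_checkerboard_mask(d[1], d[2], phase = mask_phase)
    mos <- extract_modality(apply_forward_model(sc, mask, noise), modality)
    x3 <- unclass(extract_modality(sc, modality))
    g <- .model_graph(net_cfg, mos$data, unclass(mos$mask), params)
    .loss_graph_supervised(g, x3, w, modality)$value
  }, 0)
  mean(vals)
}

#' Train a per-modality demosaicing model
#'
#' Supervised training under the progressive patch-size curriculum: at each
#' stage, random patches of the stage size are drawn from the training scenes
#' (with rotation augmentation), mosaiced on the fly through the forward
#' model, and the multi-term objective is minimized with Adam. Validation
#' loss is computed at fixed intervals and the checkpoint with the lowest
#' validation loss is returned.
#'
#' @param dataset A [generate_dataset()] result (list with `scenes` and
#'   `split`), or any list of `spectral_stack`s plus a `split`.
#' @param modality `"visible"` or `"nir"`.
#' @param net_cfg A [hybrid_config()] or [residual_cnn_config()].
#' @param opt An [optimizer_config()].
#' @param cur A [curriculum()].
#' @param loss_w A [loss_weights()].
#' @param noise A [noise_model()] for on-the-fly mosaicing (default none).
#' @param aug An [augmentation_config()]; rotations that would leave the
#'   scene smaller than the stage patch are skipped for that draw.
#' @param val_interval Steps between validation evaluations.
#' @param mask_phase Checkerboard phase used for training mosaics.
#' @return A `hex_checkpoint` with the best-validation weights and a training
#'   `log` data frame (step, stage, patch, train loss and terms, val loss at
#'   evaluation steps).
#' @export
train_model <- function(dataset, modality = c("visible", "nir"), net_cfg,
                        opt = optimizer_config(), cur = curriculum(),
                        loss_w = loss_weights(),
                        noise = noise_model("none"),
                        aug = augmentation_config(rotations = c(0, 90),
                                                  random_crop = TRUE),
                        val_interval = 100L, mask_phase = "even") {
  modality <- match.arg(modality)
  scenes <- dataset$scenes
  split <- dataset$split
  if (is.null(scenes) || !length(scenes)) stop("empty dataset", call. = FALSE)
  if (is.null(split)) split <- list(train = seq_along(scenes),
                                    val = integer(0), test = integer(0))
  train_scenes <- scenes[split$train]
  if (!length(train_scenes)) stop("empty training split", call. = FALSE)
  val_scenes <- scenes[split$val]
  if (!length(val_scenes))
    val_scenes <- train_scenes[seq_len(min(4L, length(train_scenes)))]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(opt$seed)

  weights <- .model_init(net_cfg)
  params <- list()
  for (nm in names(weights)) params[[nm]] <- ag_param(weights[[nm]], nm)
  state <- adam_state(params)
  kind <- .model_kind(net_cfg)

  masks <- list()  # per patch size
  get_mask <- function(px) {
    key <- as.character(px)
    if (is.null(masks[[key]]))
      masks[[key]] <<- build_checkerboard_mask(px, px, phase = mask_phase)
    masks[[key]]
  }

  log <- list()
  best <- list(val = Inf, weights = weights)
  step <- 0L
  last_good <- weights
  for (si in seq_len(nrow(cur))) {
    px <- cur$patch[si]
    mask <- get_mask(px)
    ok_rot <- aug$rotations[vapply(aug$rotations, function(r) {
      dims <- dim(unclass(train_scenes[[1]])); side <- min(dims[1], dims[2])
      if (r %in% c(45, 135)) floor(side / sqrt(2)) >= px else side >= px
    }, TRUE)]
    if (!length(ok_rot)) ok_rot <- 0
    for (it in seq_len(cur$iters[si])) {
      step <- step + 1L
      ag_zero_grad(params)
      tloss <- 0
      terms <- c(rec = 0, edge = 0, spec = 0)
      for (b in seq_len(opt$batch_size)) {
        sc <- train_scenes[[sample.int(length(train_scenes), 1L)]]
        patch <- .augment_draw(sc, ok_rot, crop = px)
        x6 <- spectral_stack(array(patch, dim = c(px, px, 6L)))
        mos <- extract_modality(apply_forward_model(x6, mask, noise), modality)
        x3 <- unclass(extract_modality(x6, modality))
        g <- .model_graph(net_cfg, mos$data, unclass(mos$mask), params)
        lnode <- .loss_graph_supervised(g, x3, loss_w, modality)
        tloss <- tloss + lnode$value
        terms["rec"] <- terms["rec"] + reconstruction_l1(g$value, x3)
        terms["edge"] <- terms["edge"] + edge_l1(g$value, x3)
        if (modality == "nir")
          terms["spec"] <- terms["spec"] + spectral_coherence(g$value)
        ag_backward(lnode, seed_grad = 1 / opt$batch_size)
      }
      tloss <- tloss / opt$batch_size
      terms <- terms / opt$batch_size
      if (!is.finite(tloss)) {
        cond <- structure(
          class = c("hex_training_divergence", "error", "condition"),
          list(message = sprintf("non-finite training loss at step %d", step),
               call = sys.call(-1),
               checkpoint = .checkpoint(kind, net_cfg, last_good, modality,
                                        do.call(rbind, log))))
        stop(cond)
      }
      state <- adam_step(params, state, .stage_lr(opt, it, cur$iters[si]),
                         opt$beta1, opt$beta2, t = step)
      last_good <- lapply(params, function(p) p$value)
      vloss <- NA_real_
      if (step %% val_interval == 0L || step == sum(cur$iters)) {
        cw <- lapply(params, function(p) p$value)
        vloss <- .validate(net_cfg, cw, val_scenes, modality, loss_w, noise,
                           mask_phase)
        if (vloss < best$val) best <- list(val = vloss, weights = cw)
      }
      log[[length(log) + 1L]] <- data.frame(step = step, stage = si,
                                            patch = px, train = tloss,
                                            rec = terms[["rec"]],
                                            edge = terms[["edge"]],
                                            spec = terms[["spec"]],
                                            val = vloss)
    }
  }
  logdf <- do.call(rbind, log)
  if (!is.finite(best$val)) best$weights <- lapply(params, function(p) p$value)
  .checkpoint(kind, net_cfg, best$weights, modality, logdf,
              meta = list(opt = opt, curriculum = cur, loss_w = loss_w,
                          best_val = best$val, mask_phase = mask_phase))
}

#' Sensor-consistency fine-tuning
#'
#' Adapts a trained checkpoint to mosaics without ground truth by minimizing
#' the sensor-consistency L1 (plus, for NIR models, the spectral-coherence
#' term). Reports the per-mosaic consistency error before and after, and a
#' log of the mean error at every evaluation.
#'
#' @param ckpt A `hex_checkpoint`.
#' @param mosaics List of `modality_mosaic`s (shared mask geometry) matching
#'   the checkpoint's modality.
#' @param opt An [optimizer_config()].
#' @param loss_w A [loss_weights()].
#' @param steps Number of optimization steps (0 = no-op evaluation).
#' @param eval_interval Steps between logged evaluations.
#' @return Updated `hex_checkpoint`; `meta$consistency` holds the before /
#'   after per-mosaic errors and `meta$trace` the logged mean-error trend.
#' @export
finetune_sensor_consistency <- function(ckpt, mosaics,
                                        opt = optimizer_config(lr = 1e-4),
                                        loss_w = loss_weights(),
                                        steps = 200L, eval_interval = 50L) {
  stopifnot(inherits(ckpt, "hex_checkpoint"))
  if (!length(mosaics)) stop("no mosaics supplied", call. = FALSE)
  dims <- lapply(mosaics, function(m) dim(m$data))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("mosaics must share mask geometry", call. = FALSE)
  modality <- ckpt$modality
  net_cfg <- ckpt$config
  consistency_all <- function(weights) {
    params <- lapply(weights, ag_const)
    vapply(mosaics, function(m) {
      g <- .model_graph(net_cfg, m$data, unclass(m$mask), params)
      sensor_consistency(g$value, m)
    }, 0)
  }
  before <- consistency_all(ckpt$weights)
  if (steps == 0L) {
    ckpt$meta$consistency <- list(before = before, after = before)
    ckpt$meta$trace <- data.frame(step = 0L, mean_error = mean(before))
    return(ckpt)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(opt$seed)
  params <- list()
  for (nm in names(ckpt$weights)) params[[nm]] <- ag_param(ckpt$weights[[nm]], nm)
  state <- adam_state(params)
  trace <- list(data.frame(step = 0L, mean_error = mean(before)))
  for (t in seq_len(steps)) {
    ag_zero_grad(params)
    nb <- min(opt$batch_size, length(mosaics))
    pick <- sample.int(length(mosaics), nb)
    for (i in pick) {
      m <- mosaics[[i]]
      g <- .model_graph(net_cfg, m$data, unclass(m$mask), params)
      nodes <- list(ag_l1_masked(g, m$data, unclass(m$mask)))
      ws <- c(loss_w$mos)
      if (modality == "nir" && loss_w$spec > 0) {
        d <- dim(m$data)
        ch <- function(i2) ag_node(g$value[, , i2, drop = FALSE], list(g),
                                   local({ii <- i2; function(gg) {
                                     out <- array(0, dim = d); out[, , ii] <- gg
                                     list(out)
                                   }}))
        nodes <- c(nodes, list(ag_add(ag_l1_mean(ch(1), ch(2)),
                                      ag_l1_mean(ch(2), ch(3)))))
        ws <- c(ws, loss_w$spec)
      }
      lnode <- ag_weighted_sum(nodes, ws)
      ag_backward(lnode, seed_grad = 1 / nb)
    }
    state <- adam_step(params, state, opt$lr, opt$beta1, opt$beta2, t = t)
    if (t %% eval_interval == 0L || t == steps) {
      cw <- lapply(params, function(p) p$value)
      trace[[length(trace) + 1L]] <- data.frame(step = t,
                                                mean_error = mean(consistency_all(cw)))
    }
  }
  weights <- lapply(params, function(p) p$value)
  after <- consistency_all(weights)
  out <- .checkpoint(ckpt$kind, net_cfg, weights, modality, ckpt$log,
                     meta = ckpt$meta)
  out$meta$consistency <- list(before = before, after = after)
  out$meta$trace <- do.call(rbind, trace)
  out
}
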