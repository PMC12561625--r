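#' Scene specification for the synthetic generator
#'
#' Describes a six-channel test scene. The generator emulates the image
#' content the demosaicing methods are evaluated on: piecewise-smooth regions,
#' sharp edges and high-frequency bar patterns (resolution-chart-like), and
#' NIR fluorescent blobs whose locations are spatially correlated with visible
#' structure, mimicking a labeled tumor on visible anatomy.
#'
#' @param kind One of `"flat"`, `"ramp"`, `"bars"`, `"blobs"`, `"composite"`,
#'   `"mix"` (`"mix"` draws bars or blobs at random per scene; used for
#'   training corpora).
#' @param height,width Scene dimensions in pixels.
#' @param params Kind-specific parameter list, see Details.
#' @param seed Integer seed; identical specs generate identical scenes.
#'
#' @details Kind-specific `params`:
#' \describe{
#'   \item{flat}{`value`: scalar or length-6 vector in `[0,1]` (default 0.5).}
#'   \item{ramp}{`gradients`: 6 x 2 matrix of per-channel (row, col) gradients;
#'     `offsets`: length-6 intercepts. Values are not clipped, so callers must
#'     keep the affine field inside `[0,1]`.}
#'   \item{bars}{`period`: bar period in px (>= 2); `orientation`:
#'     `"vertical"` or `"horizontal"`; `levels`: c(lo, hi).}
#'   \item{blobs}{`n_blobs`; `radius` (px, >= 1); `amplitude`; `rho`: in
#'     `[0,1]`, fraction of blob sites echoed as visible-intensity features
#'     (cross-band geometric correlation); `background`: NIR floor.}
#'   \item{composite}{quadrant tiling of flat / ramp / bars / blobs.}
#' }
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(kind = c("flat", "ramp", "bars", "blobs", "composite",
                                "mix"),
                       height = 64L, width = 64L, params = list(),
                       seed = 0L) {
  kind <- match.arg(kind)
  if (height < 2 || width < 2) stop("scene dims must be >= 2", call. = FALSE)
  def <- switch(kind,
    flat = list(value = 0.5),
    ramp = list(gradients = cbind(rep(0, 6), rep(1 / (width - 1), 6)),
                offsets = rep(0, 6)),
    bars = list(period = 8L, orientation = "vertical", levels = c(0.15, 0.85)),
    blobs = list(n_blobs = 3L, radius = 3, amplitude = 0.6, rho = 0.7,
                 background = 0.1),
    composite = list(),
    mix = list())
  params <- utils::modifyList(def, params)
  if (kind == "bars" && params$period < 2)
    stop("bar period must be >= 2 px", call. = FALSE)
  if (kind == "blobs") {
    if (params$radius < 1) stop("blob radius must be >= 1 px", call. = FALSE)
    if (params$rho < 0 || params$rho > 1)
      stop("rho must be in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, height = as.integer(height),
                 width = as.integer(width), params = params,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# smooth random field in [lo, hi]: bilinear upsample of a coarse uniform grid
.smooth_field <- function(h, w, lo, hi, cells = 4L) {
  g <- matrix(runif((cells + 1)^2), cells + 1, cells + 1)
  ry <- seq(1, cells + 1, length.out = h)
  rx <- seq(1, cells + 1, length.out = w)
  y0 <- pmin(floor(ry), cells); x0 <- pmin(floor(rx), cells)
  fy <- ry - y0; fx <- rx - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  cc <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fym <- matrix(rep(fy, w), h, w); fxm <- matrix(rep(fx, each = h), h, w)
  f <- matrix(a, h, w) * (1 - fym) * (1 - fxm) +
    matrix(b, h, w) * (1 - fym) * fxm +
    matrix(cc, h, w) * fym * (1 - fxm) +
    matrix(d, h, w) * fym * fxm
  lo + (hi - lo) * f
}

# place n blob centers with a minimum pairwise separation, margin from border
.place_centers <- function(n, h, w, min_sep, margin) {
  centers <- matrix(0, 0, 2)
  tries <- 0L
  while (nrow(centers) < n && tries < 5000L) {
    cand <- c(runif(1, 1 + margin, h - margin), runif(1, 1 + margin, w - margin))
    ok <- nrow(centers) == 0 ||
      all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                         byrow = TRUE))^2)) >= min_sep)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1L
  }
  if (nrow(centers) < n)
    stop("could not place ", n, " separated blobs in a ", h, "x", w, " scene",
         call. = FALSE)
  centers
}

.gaussian_bump <- function(h, w, cy, cx, radius) {
  ry <- (seq_len(h) - cy)^2
  rx <- (seq_len(w) - cx)^2
  exp(-(outer(ry, rx, "+")) / (2 * radius^2))
}

#' Generate a synthetic six-channel scene
#'
#' @param spec A [scene_spec()].
#' @return A `spectral_stack` with values in `[0, 1]`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width; p <- spec$params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  x <- array(0, dim = c(h, w, 6L))
  kind <- spec$kind
  if (kind == "mix") {
    kind <- sample(c("bars", "blobs"), 1L)
    if (kind == "bars") {
      p <- list(period = sample(2:8, 1L),
                orientation = sample(c("vertical", "horizontal"), 1L),
                levels = sort(runif(2, 0.05, 0.95)))
    } else {
      # radius/count chosen so separated blobs always fit the scene
      side <- min(spec$height, spec$width)
      radius <- runif(1, 1.5, max(1.5, min(4, side / 16)))
      nmax <- max(1L, min(3L, floor((side - 4 * radius) / (5 * radius))^2))
      p <- list(n_blobs = sample.int(nmax, 1L), radius = radius,
                amplitude = runif(1, 0.4, 0.7), rho = 0.7,
                background = runif(1, 0.05, 0.2))
    }
  }
  switch(kind,
    flat = {
      v <- rep(p$value, length.out = 6)
      for (c in 1:6) x[, , c] <- v[c]
    },
    ramp = {
      ri <- matrix(seq_len(h) - 1, h, w)
      ci <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
      for (c in 1:6)
        x[, , c] <- p$offsets[c] + p$gradients[c, 1] * ri + p$gradients[c, 2] * ci
    },
    bars = {
      idx <- if (p$orientation == "vertical") {
        matrix(seq_len(w) - 1, h, w, byrow = TRUE)
      } else {
        matrix(seq_len(h) - 1, h, w)
      }
      half <- p$period / 2
      hi <- (idx %% p$period) < half
      for (c in 1:6) x[, , c] <- ifelse(hi, p$levels[2], p$levels[1])
    },
    blobs = {
      margin <- 2 * p$radius
      centers <- .place_centers(p$n_blobs, h, w, min_sep = 5 * p$radius,
                                margin = margin)
      # visible anatomy: smooth background, plus bumps at a rho-fraction of
      # blob sites (shared geometry) and independent distractor bumps
      for (c in 1:3) x[, , c] <- .smooth_field(h, w, 0.2, 0.6)
      shared <- runif(p$n_blobs) < p$rho
      for (i in seq_len(p$n_blobs)) {
        if (shared[i]) {
          amp <- runif(1, 0.15, 0.3)
          b <- .gaussian_bump(h, w, centers[i, 1], centers[i, 2],
                              1.5 * p$radius)
          for (c in 1:3) x[, , c] <- x[, , c] + amp * b
        }
      }
      # NIR: near-constant floor plus fluorescent blobs; per-band amplitude
      # scaling emulates the distinct broadband quantum efficiencies
      band_gain <- c(1, 0.8, 0.6)
      for (c in 1:3) x[, , 3 + c] <- p$background
      for (i in seq_len(p$n_blobs)) {
        b <- .gaussian_bump(h, w, centers[i, 1], centers[i, 2], p$radius)
        for (c in 1:3)
          x[, , 3 + c] <- x[, , 3 + c] + p$amplitude * band_gain[c] * b
      }
      attr(x, "blob_centers") <- centers
    },
    composite = {
      h2 <- h %/% 2; w2 <- w %/% 2
      sub <- function(k, hh, ww, prm = list())
        unclass(generate_scene(scene_spec(k, hh, ww, prm,
                                          seed = spec$seed + match(k, c("flat", "ramp", "bars", "blobs")))))
      x[seq_len(h2), seq_len(w2), ] <- sub("flat", h2, w2)
      x[seq_len(h2), (w2 + 1):w, ] <-
        sub("ramp", h2, w - w2,
            list(gradients = cbind(rep(0, 6), rep(1 / max(w - w2 - 1, 1), 6))))
      x[(h2 + 1):h, seq_len(w2), ] <- sub("bars", h - h2, w2,
                                          list(period = 4L))
      if (h - h2 >= 20 && w - w2 >= 20) {
        x[(h2 + 1):h, (w2 + 1):w, ] <- sub("blobs", h - h2, w - w2,
                                           list(n_blobs = 1L, radius = 2))
      } else {
        x[(h2 + 1):h, (w2 + 1):w, ] <- sub("flat", h - h2, w - w2,
                                           list(value = 0.3))
      }
    })
  cent <- attr(x, "blob_centers")
  x <- pmin(pmax(x, 0), 1)
  out <- spectral_stack(array(x, dim = c(h, w, 6L)))
  attr(out, "blob_centers") <- cent
  attr(out, "resolved_kind") <- kind
  out
}

#' Split scene indices into train/validation/test sets
#'
#' @param n Number of scenes.
#' @param fractions Length-3 nonnegative vector (train, val, test) summing
#'   to 1.
#' @param seed Integer seed for the shuffle.
#' @return List with integer index vectors `train`, `val`, `test` (disjoint,
#'   covering `1:n`).
#' @export
split_dataset <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be 3 nonnegative numbers summing to 1", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  perm <- sample.int(n)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_val <- min(n_val, n - n_train)
  list(train = sort(perm[seq_len(n_train)]),
       val = if (n_val > 0) sort(perm[n_train + seq_len(n_val)]) else integer(0),
       test = if (n_train + n_val < n) sort(perm[(n_train + n_val + 1):n]) else integer(0))
}

#' Generate a seeded synthetic dataset
#'
#' Produces `n` scenes from a template spec with per-scene derived seeds, plus
#' a disjoint train/validation/test split. Stands in for an external training
#' corpus: the scenes supply spatial structure only.
#'
#' @param n Number of scenes (`>= 1`).
#' @param spec_template A [scene_spec()]; its `seed` is ignored, per-scene
#'   seeds are `seed + 1000 * i`.
#' @param seed Master seed.
#' @param fractions Split fractions passed to [split_dataset()].
#' @return List with `scenes` (list of `spectral_stack`), `specs`, and
#'   `split`.
#' @export
generate_dataset <- function(n, spec_template = scene_spec("mix", 64, 64),
                             seed = 0L, fractions = c(0.8, 0.1, 0.1)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  specs <- lapply(seq_len(n), function(i) {
    sp <- spec_template
    sp$seed <- as.integer(seed + 1000L * i)
    sp
  })
  scenes <- lapply(specs, generate_scene)
  list(scenes = scenes, specs = specs,
       split = split_dataset(n, fractions, seed = seed))
}
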