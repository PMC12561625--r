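#' @useDynLib hexdemosaic, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois quantile sd runif
NULL

#' Channel names of a hexachromatic stack
#'
#' The sensor delivers three visible channels (red, green, blue from the
#' vertically stacked photodiodes under the visible filter) and three broadband
#' near-infrared channels with short/medium/long-biased quantum efficiencies.
#' All six-channel arrays in this package use this fixed channel order.
#'
#' @return Character vector of length 6.
#' @export
hex_channels <- function() {
  c("V-R", "V-G", "V-B", "NIR-S", "NIR-M", "NIR-L")
}

#' Modality of each channel
#'
#' @return Factor-free character vector: `"visible"` for channels 1-3,
#'   `"nir"` for channels 4-6.
#' @export
hex_modalities <- function() {
  c(rep("visible", 3), rep("nir", 3))
}

#' Construct a spectral stack
#'
#' A spectral stack is an `H x W x 6` numeric array of normalized radiance.
#' Ground-truth stacks must lie in `[0, 1]`; reconstructions may transiently
#' exceed that range and are only clipped at export time.
#'
#' @param data Numeric array, `H x W x 6` (or `H x W x 3` with
#'   `channels` given).
#' @param channels Channel names; defaults to [hex_channels()] for 6-channel
#'   input.
#' @param check_range If `TRUE`, error unless all values lie in `[0, 1]`.
#' @return A `spectral_stack` (numeric array with attributes).
#' @export
spectral_stack <- function(data, channels = NULL, check_range = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (H x W x C)", call. = FALSE)
  d <- dim(data)
  if (d[1] < 2L || d[2] < 2L)
    stop("stack height and width must be >= 2", call. = FALSE)
  if (is.null(channels)) {
    if (d[3] != 6L)
      stop("`channels` must be given for non-6-channel stacks", call. = FALSE)
    channels <- hex_channels()
  }
  if (length(channels) != d[3])
    stop("length(channels) must match dim(data)[3]", call. = FALSE)
  if (any(!is.finite(data)))
    stop("stack values must all be finite", call. = FALSE)
  if (check_range && (min(data) < 0 || max(data) > 1))
    stop("ground-truth stack values must lie in [0, 1]", call. = FALSE)
  structure(data, channels = channels, class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<spectral_stack %d x %d x %d> channels: %s\n", d[1], d[2], d[3],
              paste(attr(x, "channels"), collapse = ", ")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Build the checkerboard sampling mask
#'
#' Encodes which channels the sensor observes at each pixel. Pixels alternate
#' between the visible and NIR modality in a checkerboard: every 4-adjacent
#' pair of pixels carries opposite modalities, so each modality is sampled at
#' half density and reconstruction is a 2x (not 4x) upsampling problem.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"modality-triplet"`}{the default; the three stacked photodiodes at
#'     a pixel observe all three channels of that pixel's modality (per-pixel
#'     channel sum 3). This matches the physical sensor, which reads three
#'     spectral observations per pixel.}
#'   \item{`"strict-single-channel"`}{exactly one channel per pixel (per-pixel
#'     channel sum 1). Within each modality the channel cycles with the pixel
#'     position: among same-modality pixels, channel index is
#'     `(floor(row/1) + 2*floor(col/1)) %% 3` applied to the modality triplet
#'     along checkerboard diagonals. This sub-pattern is a package convention;
#'     no standard layout exists for it.}
#' }
#'
#' @param height,width Positive integers, both `>= 2`.
#' @param dialect `"modality-triplet"` (default) or `"strict-single-channel"`.
#' @param phase `"even"` (pixel (1,1) visible, default) or `"odd"`.
#' @return A `sampling_mask`: binary `H x W x 6` array with attributes
#'   `dialect` and `phase`.
#' @export
build_checkerboard_mask <- function(height, width,
                                    dialect = c("modality-triplet",
                                                "strict-single-channel"),
                                    phase = c("even", "odd")) {
  dialect <- match.arg(dialect)
  phase <- match.arg(phase)
  if (length(height) != 1L || length(width) != 1L ||
      !is.finite(height) || !is.finite(width) ||
      height < 2 || width < 2 || height != round(height) || width != round(width))
    stop("height and width must be integers >= 2", call. = FALSE)
  height <- as.integer(height); width <- as.integer(width)
  ri <- matrix(seq_len(height) - 1L, height, width)
  ci <- matrix(seq_len(width) - 1L, height, width, byrow = TRUE)
  par <- (ri + ci) %% 2L
  vis <- if (phase == "even") par == 0L else par == 1L  # visible pixels
  m <- array(0, dim = c(height, width, 6L))
  if (dialect == "modality-triplet") {
    for (c in 1:3) m[, , c][vis] <- 1
    for (c in 4:6) m[, , c][!vis] <- 1
  } else {
    # one channel per pixel: cycle the triplet along the same-modality
    # diagonal index floor((row + col) / 2) + row, a fixed package convention
    sub <- (ri + (ri + ci) %/% 2L) %% 3L  # 0, 1, 2 within each modality
    for (k in 0:2) {
      m[, , k + 1L][vis & sub == k] <- 1
      m[, , k + 4L][(!vis) & sub == k] <- 1
    }
  }
  structure(m, dialect = dialect, phase = phase, class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<sampling_mask %d x %d x %d> dialect: %s, phase: %s\n",
              d[1], d[2], d[3], attr(x, "dialect"), attr(x, "phase")))
  invisible(x)
}

#' Per-pixel modality map of a mask
#'
#' @param s A `sampling_mask`.
#' @return `H x W` character matrix of `"visible"` / `"nir"`.
#' @export
mask_modality_map <- function(s) {
  vis <- apply(s[, , 1:3, drop = FALSE], c(1, 2), sum) > 0
  out <- matrix("nir", dim(s)[1], dim(s)[2])
  out[vis] <- "visible"
  out
}

#' Noise model for the acquisition forward model
#'
#' The additive term of the sensing model `Y = S (*) X + N`. The hardware
#' description does not pin down a noise parameterization, so three simple
#' kinds are provided; noise is applied only at sampled entries so the mosaic
#' stays exactly zero outside the mask.
#'
#' @param kind `"none"`, `"gaussian"` or `"poisson-gaussian"`.
#' @param sigma Gaussian standard deviation in normalized radiance units.
#' @param gain Photon scaling for the Poisson component (counts = value * gain).
#' @param seed Integer seed; the same model applied to the same data is
#'   bit-reproducible.
#' @return A `noise_model` list.
#' @export
noise_model <- function(kind = c("none", "gaussian", "poisson-gaussian"),
                        sigma = 0, gain = 1000, seed = 0L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, gain = gain,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Apply the acquisition forward model
#'
#' Computes the raw mosaic `Y = S (*) X + N`: at each pixel only the channels
#' indicated by the mask are observed, all other entries are zero. Noise is
#' realized only at sampled entries.
#'
#' @param x A `spectral_stack` (ground truth).
#' @param s A `sampling_mask` of the same spatial dims.
#' @param noise A [noise_model()]; default none.
#' @return A `raw_mosaic`: list with `data` (`H x W x 6` array, zero outside
#'   the mask) and `mask`.
#' @export
apply_forward_model <- function(x, s, noise = noise_model("none")) {
  if (!identical(dim(x)[1:2], dim(s)[1:2]) || dim(x)[3] != dim(s)[3])
    stop("shape mismatch between stack and mask", call. = FALSE)
  y <- unclass(x) * unclass(s)
  if (noise$kind != "none") {
    idx <- which(s == 1)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(noise$seed)
    v <- y[idx]
    if (noise$kind == "gaussian") {
      v <- v + rnorm(length(idx), 0, noise$sigma)
    } else { # poisson-gaussian
      v <- rpois(length(idx), pmax(v, 0) * noise$gain) / noise$gain
      if (noise$sigma > 0) v <- v + rnorm(length(idx), 0, noise$sigma)
    }
    y[idx] <- v
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  structure(list(data = y, mask = s), class = "raw_mosaic")
}

#' @export
print.raw_mosaic <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raw_mosaic %d x %d x %d> dialect: %s\n", d[1], d[2], d[3],
              attr(x$mask, "dialect")))
  invisible(x)
}

#' Extract one modality from a stack or mosaic
#'
#' Returns the 3 channels of the requested modality (visible = channels 1-3,
#' NIR = channels 4-6). For a `raw_mosaic` the matching 3-channel mask slice is
#' carried along, so per-modality models can be run independently.
#'
#' @param x A `spectral_stack` or `raw_mosaic`.
#' @param modality `"visible"` or `"nir"`.
#' @return For a stack: a 3-channel `spectral_stack`. For a mosaic: a list
#'   with `data` (`H x W x 3`) and `mask` (`H x W x 3`, dialect/phase kept).
#' @export
extract_modality <- function(x, modality = c("visible", "nir")) {
  modality <- match.arg(modality)
  ch <- if (modality == "visible") 1:3 else 4:6
  if (inherits(x, "raw_mosaic")) {
    m3 <- x$mask[, , ch, drop = FALSE]
    attr(m3, "dialect") <- attr(x$mask, "dialect")
    attr(m3, "phase") <- attr(x$mask, "phase")
    attr(m3, "modality") <- modality
    structure(list(data = x$data[, , ch, drop = FALSE], mask = m3,
                   modality = modality),
              class = "modality_mosaic")
  } else {
    spectral_stack(unclass(x)[, , ch, drop = FALSE],
                   channels = hex_channels()[ch])
  }
}

#' Combine per-modality stacks into a six-channel stack
#'
#' Inverse of [extract_modality()] on stacks: concatenates a visible and an
#' NIR 3-channel stack back into the canonical channel order.
#'
#' @param visible,nir 3-channel arrays of identical spatial dims.
#' @return A 6-channel `spectral_stack`.
#' @export
combine_modalities <- function(visible, nir) {
  if (!identical(dim(visible)[1:2], dim(nir)[1:2]))
    stop("shape mismatch between modalities", call. = FALSE)
  out <- array(0, dim = c(dim(visible)[1:2], 6L))
  out[, , 1:3] <- unclass(visible)
  out[, , 4:6] <- unclass(nir)
  spectral_stack(out)
}
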