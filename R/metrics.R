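#' Mean squared error of one channel
#'
#' @param xhat,x Arrays of identical shape (`H x W` or `H x W x C`).
#' @param channel Channel index when inputs are 3-d; `NULL` averages over all
#'   channels.
#' @return Scalar MSE.
#' @export
mse <- function(xhat, x, channel = NULL) {
  xhat <- .as_arr(xhat); x <- .as_arr(x)
  .check_same_shape(xhat, x)
  if (!is.null(channel) && length(dim(xhat)) == 3L) {
    xhat <- xhat[, , channel]; x <- x[, , channel]
  }
  mean((xhat - x)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB; `Inf` when the MSE is exactly zero. The
#' package convention on normalized data is `peak = 1`.
#'
#' @param xhat,x Arrays of identical shape.
#' @param channel Optional channel index.
#' @param peak Signal peak (> 0).
#' @return Scalar in dB (possibly `Inf`).
#' @export
psnr <- function(xhat, x, channel = NULL, peak = 1) {
  if (peak <= 0) stop("peak must be > 0", call. = FALSE)
  m <- mse(xhat, x, channel)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

# normalized 1-d Gaussian window
.gauss_win <- function(size = 11L, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  w <- exp(-r^2 / (2 * sigma^2))
  w / sum(w)
}

# separable "valid" correlation of a matrix with an outer-product window
.filter_valid <- function(x, w) {
  k <- length(w)
  H <- nrow(x); W <- ncol(x)
  if (H < k || W < k) stop("image smaller than the SSIM window", call. = FALSE)
  # rows: (H-k+1) x H band matrix times x
  Kr <- matrix(0, H - k + 1L, H)
  for (i in seq_len(H - k + 1L)) Kr[i, i:(i + k - 1L)] <- w
  Kc <- matrix(0, W - k + 1L, W)
  for (i in seq_len(W - k + 1L)) Kc[i, i:(i + k - 1L)] <- w
  Kr %*% x %*% t(Kc)
}

#' Per-pixel SSIM map of one channel
#'
#' Gaussian-weighted SSIM (window 11 x 11, sigma 1.5, K1 = 0.01, K2 = 0.03,
#' dynamic range `peak`), evaluated on the valid interior (no padding), so
#' the map is `(H-10) x (W-10)`.
#'
#' @param a,b Matrices of identical shape.
#' @param peak Dynamic range (1 for normalized data).
#' @param window,sigma Window size and Gaussian width.
#' @return SSIM map matrix.
#' @export
ssim_map <- function(a, b, peak = 1, window = 11L, sigma = 1.5) {
  .check_same_shape(a, b)
  w <- .gauss_win(window, sigma)
  c1 <- (0.01 * peak)^2
  c2 <- (0.03 * peak)^2
  mu_a <- .filter_valid(a, w)
  mu_b <- .filter_valid(b, w)
  va <- .filter_valid(a * a, w) - mu_a^2
  vb <- .filter_valid(b * b, w) - mu_b^2
  cab <- .filter_valid(a * b, w) - mu_a * mu_b
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

.modality_channels <- function(x, modality) {
  d3 <- dim(.as_arr(x))[3]
  if (d3 == 6L) { if (modality == "visible") 1:3 else 4:6 }
  else seq_len(d3)
}

#' 95th-percentile structural dissimilarity
#'
#' DSSIM is `(1 - SSIM) / 2` per pixel; the summary statistic is the 95th
#' percentile over all valid pixels of the modality's three channels
#' (percentiles use linear interpolation between order statistics).
#'
#' @param xhat,x Stacks of identical shape (3- or 6-channel).
#' @param modality `"visible"` or `"nir"` (selects channels of a 6-channel
#'   stack).
#' @param prob Percentile level (default 0.95).
#' @return Scalar in `[0, 1]`.
#' @export
dssim_p95 <- function(xhat, x, modality = c("visible", "nir"), prob = 0.95) {
  modality <- match.arg(modality)
  xhat <- .as_arr(xhat); x <- .as_arr(x)
  .check_same_shape(xhat, x)
  ch <- .modality_channels(x, modality)
  dvals <- unlist(lapply(ch, function(c) {
    (1 - ssim_map(xhat[, , c], x[, , c])) / 2
  }))
  unname(quantile(dvals, prob, type = 7))
}

#' CIEDE2000 color difference (vectorized)
#'
#' The standard perceptual color-difference formula computed in CIE Lab.
#' Verified against the published 34 verification pairs.
#'
#' @param lab1,lab2 `n x 3` matrices of L, a, b values.
#' @return Numeric vector of length n.
#' @export
delta_e00 <- function(lab1, lab2) {
  lab1 <- matrix(lab1, ncol = 3); lab2 <- matrix(lab2, ncol = 3)
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  cbar <- (sqrt(a1^2 + b1^2) + sqrt(a2^2 + b2^2)) / 2
  g <- 0.5 * (1 - sqrt(cbar^7 / (cbar^7 + 25^7)))
  ap1 <- (1 + g) * a1; ap2 <- (1 + g) * a2
  cp1 <- sqrt(ap1^2 + b1^2); cp2 <- sqrt(ap2^2 + b2^2)
  hp1 <- ifelse(cp1 == 0, 0, atan2(b1, ap1) %% (2 * pi)) * 180 / pi
  hp2 <- ifelse(cp2 == 0, 0, atan2(b2, ap2) %% (2 * pi)) * 180 / pi
  dL <- L2 - L1
  dC <- cp2 - cp1
  # eps guards the |dh| = 180 branch boundary against rounding in atan2;
  # the published verification pairs 9-12 sit exactly on it
  eps <- 1e-9
  dh <- hp2 - hp1
  dh <- ifelse(cp1 * cp2 == 0, 0,
               ifelse(dh > 180 + eps, dh - 360,
                      ifelse(dh < -(180 + eps), dh + 360, dh)))
  dH <- 2 * sqrt(cp1 * cp2) * sin(dh / 2 * pi / 180)
  Lbar <- (L1 + L2) / 2
  Cbar <- (cp1 + cp2) / 2
  hsum <- hp1 + hp2
  habs <- abs(hp1 - hp2)
  hbar <- ifelse(cp1 * cp2 == 0, hsum,
                 ifelse(habs <= 180 + eps, hsum / 2,
                        ifelse(hsum < 360, (hsum + 360) / 2,
                               (hsum - 360) / 2)))
  t <- 1 - 0.17 * cos((hbar - 30) * pi / 180) +
    0.24 * cos(2 * hbar * pi / 180) +
    0.32 * cos((3 * hbar + 6) * pi / 180) -
    0.20 * cos((4 * hbar - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbar - 275) / 25)^2)
  rc <- 2 * sqrt(Cbar^7 / (Cbar^7 + 25^7))
  sl <- 1 + 0.015 * (Lbar - 50)^2 / sqrt(20 + (Lbar - 50)^2)
  sc <- 1 + 0.045 * Cbar
  sh <- 1 + 0.015 * Cbar * t
  rt <- -sin(2 * dtheta * pi / 180) * rc
  sqrt((dL / sl)^2 + (dC / sc)^2 + (dH / sh)^2 + rt * (dC / sc) * (dH / sh))
}

# map a 3-channel triplet in [0,1] to Lab through sRGB (D65). NIR triplets
# take the same pseudo-RGB path used for false-color display.
.triplet_to_lab <- function(arr3) {
  d <- dim(arr3)
  rgb <- matrix(pmin(pmax(arr3, 0), 1) * 255, d[1] * d[2], 3)
  farver::convert_colour(rgb, from = "rgb", to = "lab")
}

#' 95th-percentile CIEDE2000 color difference
#'
#' Maps the modality's 3-channel triplet through the sRGB (D65) to Lab
#' transform and computes the per-pixel CIEDE2000 difference between
#' reconstruction and truth, summarized by its 95th percentile. For NIR the
#' triplet is treated as the false-color display RGB; this is a documented
#' convention, not a colorimetric claim.
#'
#' @param xhat,x Stacks of identical shape.
#' @param modality `"visible"` or `"nir"`.
#' @param prob Percentile level.
#' @return Scalar (>= 0).
#' @export
delta_e00_p95 <- function(xhat, x, modality = c("visible", "nir"),
                          prob = 0.95) {
  modality <- match.arg(modality)
  xhat <- .as_arr(xhat); x <- .as_arr(x)
  .check_same_shape(xhat, x)
  ch <- .modality_channels(x, modality)
  if (length(ch) != 3L)
    stop("delta_e00_p95 needs a 3-channel modality", call. = FALSE)
  lab1 <- .triplet_to_lab(xhat[, , ch, drop = FALSE])
  lab2 <- .triplet_to_lab(x[, , ch, drop = FALSE])
  unname(quantile(delta_e00(lab1, lab2), prob, type = 7))
}

#' Per-pixel error map
#'
#' Mean absolute error across channels at each pixel; the standard
#' visualization for localizing reconstruction artifacts.
#'
#' @param xhat,x Stacks of identical shape.
#' @return `H x W` matrix.
#' @export
error_map <- function(xhat, x) {
  xhat <- .as_arr(xhat); x <- .as_arr(x)
  .check_same_shape(xhat, x)
  apply(abs(xhat - x), c(1, 2), mean)
}

# jet-style colormap ramp: dark blue -> cyan -> yellow -> red
.jet <- function(n = 256L) {
  grDevices::colorRampPalette(c("#00007F", "blue", "cyan", "yellow",
                                "red", "#7F0000"))(n)
}

#' Export an error map as a colormapped PNG
#'
#' @param emap Matrix from [error_map()].
#' @param path Output PNG path.
#' @param max_value Value mapped to the top of the colormap (defaults to the
#'   map's maximum; 0-range maps render as the lowest color).
#' @return Invisibly, the path.
#' @export
export_error_map <- function(emap, path, max_value = NULL) {
  if (is.null(max_value)) max_value <- max(emap)
  idx <- if (max_value > 0) {
    pmin(pmax(round(emap / max_value * 255) + 1L, 1L), 256L)
  } else matrix(1L, nrow(emap), ncol(emap))
  cols <- .jet(256L)[idx]
  rgbv <- grDevices::col2rgb(cols) / 255
  img <- array(0, dim = c(nrow(emap), ncol(emap), 3L))
  img[, , 1] <- matrix(rgbv[1, ], nrow(emap))
  img[, , 2] <- matrix(rgbv[2, ], nrow(emap))
  img[, , 3] <- matrix(rgbv[3, ], nrow(emap))
  png::writePNG(img, path)
  invisible(path)
}

#' Contrast-to-noise ratio between two regions
#'
#' `(mean_fg - mean_bg) / sd_bg` with the population standard deviation
#' (divide by n, not n-1) - the task-based detectability measure used for
#' tumor-to-background assessment in the relevant NIR band.
#'
#' @param image Matrix (one channel).
#' @param roi_fg,roi_bg Index matrices (`n x 2` of row, col) or logical masks;
#'   nonempty and disjoint.
#' @return Scalar CNR.
#' @export
cnr <- function(image, roi_fg, roi_bg) {
  pick <- function(roi) {
    if (is.logical(roi)) which(roi) else {
      if (is.null(dim(roi)) || ncol(roi) != 2) stop("ROI must be n x 2 or logical", call. = FALSE)
      (roi[, 2] - 1L) * nrow(image) + roi[, 1]
    }
  }
  ifg <- pick(roi_fg); ibg <- pick(roi_bg)
  if (!length(ifg) || !length(ibg))
    stop("ROIs must be nonempty", call. = FALSE)
  if (length(intersect(ifg, ibg)))
    stop("ROIs must be disjoint", call. = FALSE)
  fg <- image[ifg]; bg <- image[ibg]
  sd_pop <- sqrt(mean((bg - mean(bg))^2))
  if (sd_pop == 0) stop("background ROI has zero variance", call. = FALSE)
  (mean(fg) - mean(bg)) / sd_pop
}

#' 10-90% rise distance of an edge profile
#'
#' Normalizes a 1-d profile by its asymptotic endpoints and returns the
#' linearly interpolated distance (in samples) between the 10% and 90%
#' crossings - the task-based edge-acuity measure.
#'
#' @param profile Numeric vector crossing both the 10% and 90% levels of its
#'   asymptotic range.
#' @return Rise distance in px.
#' @export
rise_distance <- function(profile) {
  n <- length(profile)
  if (n < 2) stop("profile too short", call. = FALSE)
  lo <- profile[1]; hi <- profile[n]
  if (hi == lo) stop("profile has no rise", call. = FALSE)
  z <- (profile - lo) / (hi - lo)
  crossing <- function(level) {
    above <- z >= level
    i <- which(!above[-n] & above[-1])
    if (!length(i)) return(NA_real_)
    i <- i[1]
    i + (level - z[i]) / (z[i + 1] - z[i])
  }
  x10 <- crossing(0.1); x90 <- crossing(0.9)
  if (is.na(x10) || is.na(x90))
    stop("profile does not cross the 10% and 90% levels", call. = FALSE)
  abs(x90 - x10)
}

#' Assemble a per-image metric report
#'
#' One row of the standard comparison table: per-channel PSNR and MSE, and
#' per-modality 95th-percentile DSSIM and CIEDE2000; optional task-based
#' entries. The PSNR-MSE identity `PSNR = 10 log10(peak^2 / MSE)` holds for
#' every row by construction.
#'
#' @param xhat Reconstructed `spectral_stack` (6-channel).
#' @param x Ground-truth `spectral_stack`, or `NULL` for the
#'   sensor-consistency-only mode.
#' @param y Raw mosaic (required when `x` is `NULL`).
#' @param image_id,method Metadata strings.
#' @param peak PSNR peak.
#' @return A one-row `data.frame` (`metric_report`).
#' @export
metric_report <- function(xhat, x = NULL, y = NULL, image_id = "image",
                          method = "method", peak = 1) {
  base <- data.frame(image_id = image_id, method = method,
                     stringsAsFactors = FALSE)
  if (is.null(x)) {
    if (is.null(y)) stop("need ground truth x or mosaic y", call. = FALSE)
    base$consistency <- sensor_consistency(.as_arr(xhat), y)
    class(base) <- c("metric_report", "data.frame")
    return(base)
  }
  nm <- c("vis_r", "vis_g", "vis_b", "nir_s", "nir_m", "nir_l")
  for (c in 1:6) {
    base[[paste0("mse_", nm[c])]] <- mse(xhat, x, c)
    base[[paste0("psnr_", nm[c])]] <- psnr(xhat, x, c, peak = peak)
  }
  base$dssim_p95_vis <- dssim_p95(xhat, x, "visible")
  base$dssim_p95_nir <- dssim_p95(xhat, x, "nir")
  base$de00_p95_vis <- delta_e00_p95(xhat, x, "visible")
  base$de00_p95_nir <- delta_e00_p95(xhat, x, "nir")
  if (!is.null(y)) base$consistency <- sensor_consistency(.as_arr(xhat), y)
  class(base) <- c("metric_report", "data.frame")
  base
}
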