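# Minimal multi-plane TIFF I/O (little-endian, uncompressed, one strip per
# plane; 32-bit IEEE float for radiance stacks, 8-bit for mask label images).
# Hand-rolled because no TIFF package is available in the target R stack;
# the reader handles exactly this baseline dialect.

.tiff_tag <- function(id, type, count, value_or_offset) {
  c(id = id, type = type, count = count, value = value_or_offset)
}

.write_tiff_planes <- function(path, planes, bits, sample_format,
                               description = NULL) {
  H <- nrow(planes[[1]]); W <- ncol(planes[[1]])
  n <- length(planes)
  bytes_px <- bits %/% 8L
  strip_bytes <- H * W * bytes_px
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  desc_raw <- if (!is.null(description)) {
    r <- charToRaw(description)
    if (length(r) %% 2 == 1) r <- c(r, as.raw(0)) else c(r, as.raw(0), as.raw(0))
  } else raw(0)
  # layout: header(8) | description | strips | IFDs
  desc_off <- 8L
  strips_off <- desc_off + length(desc_raw)
  ifd0_off <- strips_off + n * strip_bytes
  writeBin(as.integer(ifd0_off), con, size = 4, endian = "little")
  if (length(desc_raw)) writeBin(desc_raw, con)
  for (p in planes) {
    v <- as.numeric(t(p))  # TIFF strips are row-major
    if (bits == 32L) writeBin(v, con, size = 4, endian = "little")
    else writeBin(as.integer(round(v)), con, size = 1, endian = "little")
  }
  n_base <- 9L
  for (i in seq_len(n)) {
    tags <- list(
      .tiff_tag(256L, 3L, 1L, W),                      # ImageWidth
      .tiff_tag(257L, 3L, 1L, H),                      # ImageLength
      .tiff_tag(258L, 3L, 1L, bits),                   # BitsPerSample
      .tiff_tag(259L, 3L, 1L, 1L),                     # Compression: none
      .tiff_tag(262L, 3L, 1L, 1L),                     # Photometric: minIsBlack
      .tiff_tag(273L, 4L, 1L, strips_off + (i - 1L) * strip_bytes),
      .tiff_tag(278L, 3L, 1L, H),                      # RowsPerStrip
      .tiff_tag(279L, 4L, 1L, strip_bytes),
      .tiff_tag(339L, 3L, 1L, sample_format))
    if (i == 1L && length(desc_raw))
      tags <- append(tags, list(.tiff_tag(270L, 2L, length(desc_raw),
                                          desc_off)), after = 4L)
    tags <- tags[order(vapply(tags, function(t) t[["id"]], 0))]
    writeBin(length(tags), con, size = 2, endian = "little")
    for (tg in tags) {
      writeBin(as.integer(tg[["id"]]), con, size = 2, endian = "little")
      writeBin(as.integer(tg[["type"]]), con, size = 2, endian = "little")
      writeBin(as.integer(tg[["count"]]), con, size = 4, endian = "little")
      if (tg[["type"]] == 3L && tg[["count"]] == 1L) {
        writeBin(as.integer(tg[["value"]]), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(tg[["value"]]), con, size = 4, endian = "little")
      }
    }
    this_ifd_bytes <- 2L + length(tags) * 12L + 4L
    next_off <- if (i < n) {
      # offsets of earlier IFDs differ if tag counts differ; recompute running
      ifd0_off + i * this_ifd_bytes +
        (if (length(desc_raw) && i == 1L) 0L else 0L)
    } else 0L
    # note: IFD i=1 may be 12 bytes longer (description tag); account for it
    if (i < n && length(desc_raw)) {
      ifd1_bytes <- 2L + 10L * 12L + 4L
      ifdk_bytes <- 2L + 9L * 12L + 4L
      next_off <- ifd0_off + ifd1_bytes + (i - 1L) * ifdk_bytes
    }
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

.read_u <- function(raw, off, size) {
  v <- 0
  for (i in seq_len(size)) v <- v + as.numeric(raw[off + i]) * 256^(i - 1)
  v
}

.read_tiff_planes <- function(path) {
  rawv <- readBin(path, "raw", file.size(path))
  if (rawToChar(rawv[1:2]) != "II" || .read_u(rawv, 2, 2) != 42)
    stop("not a little-endian TIFF: ", path, call. = FALSE)
  ifd_off <- .read_u(rawv, 4, 4)
  planes <- list()
  description <- NULL
  while (ifd_off != 0) {
    ntags <- .read_u(rawv, ifd_off, 2)
    tags <- list()
    for (t in seq_len(ntags)) {
      base <- ifd_off + 2 + (t - 1) * 12
      id <- .read_u(rawv, base, 2)
      type <- .read_u(rawv, base + 2, 2)
      count <- .read_u(rawv, base + 4, 4)
      val <- if (type == 3 && count == 1) .read_u(rawv, base + 8, 2)
             else .read_u(rawv, base + 8, 4)
      tags[[as.character(id)]] <- list(type = type, count = count, value = val)
    }
    g <- function(id, default = NULL) {
      tg <- tags[[as.character(id)]]
      if (is.null(tg)) default else tg$value
    }
    W <- g(256); H <- g(257); bits <- g(258, 8)
    if (g(259, 1) != 1) stop("compressed TIFF not supported", call. = FALSE)
    off <- g(273); nbytes <- g(279)
    sfmt <- g(339, 1)
    if (!is.null(tags[["270"]]) && is.null(description)) {
      dt <- tags[["270"]]
      dr <- rawv[dt$value + seq_len(dt$count)]
      description <- rawToChar(dr[dr != as.raw(0)])
    }
    buf <- rawv[off + seq_len(nbytes)]
    v <- if (bits == 32 && sfmt == 3) {
      readBin(buf, "double", n = H * W, size = 4, endian = "little")
    } else if (bits == 8) {
      as.numeric(readBin(buf, "integer", n = H * W, size = 1, signed = FALSE,
                         endian = "little"))
    } else stop("unsupported TIFF sample layout", call. = FALSE)
    planes[[length(planes) + 1L]] <- t(matrix(v, W, H))  # strips are row-major
    ifd_off <- .read_u(rawv, ifd_off + 2 + ntags * 12, 4)
  }
  list(planes = planes, description = description)
}

#' Write a spectral stack or mosaic data to multi-plane TIFF
#'
#' Six 32-bit float planes in the canonical channel order, recorded in the
#' file's ImageDescription. Values are written as-is (reconstructions should
#' be clipped by the caller if desired).
#'
#' @param x A `spectral_stack` or plain `H x W x C` array.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_stack <- function(x, path) {
  arr <- .as_arr(x)
  ch <- attr(x, "channels")
  if (is.null(ch)) ch <- if (dim(arr)[3] == 6L) hex_channels() else
    paste0("ch", seq_len(dim(arr)[3]))
  planes <- lapply(seq_len(dim(arr)[3]), function(c) arr[, , c])
  .write_tiff_planes(path, planes, 32L, 3L,
                     description = paste0("channels=",
                                          paste(ch, collapse = ",")))
  invisible(path)
}

#' Read a multi-plane TIFF stack
#'
#' @param path TIFF written by [write_stack()].
#' @return A `spectral_stack` (6 planes) or plain array otherwise.
#' @export
read_stack <- function(path) {
  got <- .read_tiff_planes(path)
  n <- length(got$planes)
  arr <- array(0, dim = c(dim(got$planes[[1]]), n))
  for (c in seq_len(n)) arr[, , c] <- got$planes[[c]]
  ch <- NULL
  if (!is.null(got$description) && startsWith(got$description, "channels="))
    ch <- strsplit(sub("^channels=", "", got$description), ",")[[1]]
  if (n == 6L) spectral_stack(arr) else
    structure(arr, channels = ch)
}

#' Write a sampling mask
#'
#' The mask is stored as an 8-bit single-plane TIFF of per-pixel labels
#' (modality-triplet dialect: 1 = visible, 0 = NIR; strict dialect: the
#' sampled channel index 1-6) plus a sidecar text header recording the
#' dialect and phase.
#'
#' @param s A `sampling_mask`.
#' @param path Output TIFF path; the header is written to `paste0(path,
#'   ".hdr")`.
#' @return Invisibly, the path.
#' @export
write_mask <- function(s, path) {
  dialect <- attr(s, "dialect")
  lab <- if (dialect == "modality-triplet") {
    (mask_modality_map(s) == "visible") * 1
  } else {
    apply(unclass(s), c(1, 2), which.max)
  }
  .write_tiff_planes(path, list(lab), 8L, 1L)
  writeLines(c(paste0("dialect: ", dialect),
               paste0("phase: ", attr(s, "phase"))),
             paste0(path, ".hdr"))
  invisible(path)
}

#' Read a sampling mask
#'
#' @param path TIFF path written by [write_mask()].
#' @return A `sampling_mask`.
#' @export
read_mask <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  get <- function(key) sub(paste0("^", key, ": "), "",
                           hdr[startsWith(hdr, paste0(key, ":"))])
  dialect <- get("dialect"); phase <- get("phase")
  lab <- .read_tiff_planes(path)$planes[[1]]
  d <- dim(lab)
  m <- array(0, dim = c(d[1], d[2], 6L))
  if (dialect == "modality-triplet") {
    for (c in 1:3) m[, , c][lab == 1] <- 1
    for (c in 4:6) m[, , c][lab == 0] <- 1
  } else {
    for (c in 1:6) m[, , c][lab == c] <- 1
  }
  structure(m, dialect = dialect, phase = phase, class = "sampling_mask")
}

#' Read a raw mosaic from its data and mask files
#'
#' @param data_path Stack TIFF of measurements.
#' @param mask_path Mask TIFF (with sidecar header).
#' @return A `raw_mosaic`.
#' @export
read_mosaic <- function(data_path, mask_path) {
  y <- unclass(read_stack(data_path))
  s <- read_mask(mask_path)
  structure(list(data = array(y, dim = dim(y)), mask = s),
            class = "raw_mosaic")
}
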