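## 2D image helpers. Images are numeric matrices: rows = y (top to bottom),
## columns = x. Pixel coordinates are 0-based with origin at the top-left,
## x = column, y = row, matching the depth-unprojection (i, j) convention.

#' Validate a 2D image matrix
#'
#' @param img numeric matrix of intensities.
#' @param min_size minimum height/width in pixels.
#' @param name argument name used in error messages.
#' @return the image, invisibly.
#' @keywords internal
check_image2d <- function(img, min_size = 1L, name = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(name, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(img) < min_size || ncol(img) < min_size) {
    stop(name, " must be at least ", min_size, "x", min_size, call. = FALSE)
  }
  invisible(img)
}

#' 2D Hann window
#'
#' Separable Hann taper used before FFTs to suppress edge wrap-around
#' artifacts for non-circular content.
#'
#' @param h,w window dimensions in pixels.
#' @return an \code{h x w} matrix with values in \code{[0, 1]}.
#' @export
hann_window <- function(h, w) {
  wy <- 0.5 - 0.5 * cos(2 * pi * seq_len(h) / (h + 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  outer(wy, wx)
}

## Move the DC bin to the matrix center (index N/2 + 1, 1-based, for even N).
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(seq.int(floor(h / 2) + 1L, h), seq_len(floor(h / 2)))
  ci <- c(seq.int(floor(w / 2) + 1L, w), seq_len(floor(w / 2)))
  m[ri, ci, drop = FALSE]
}

#' Bilinear interpolation at continuous pixel coordinates
#'
#' @param img numeric matrix.
#' @param x,y 0-based continuous coordinates (x = column, y = row).
#' @param fill value returned outside the image domain.
#' @return numeric vector of sampled values.
#' @keywords internal
interp_bilinear <- function(img, x, y, fill = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  ## clamp the upper neighbor so points on the last row/col interpolate flat
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  out <- rep(fill, length(x))
  i <- which(inside)
  if (length(i)) {
    v00 <- img[cbind(y0[i] + 1, x0[i] + 1)]
    v01 <- img[cbind(y0[i] + 1, x1[i] + 1)]
    v10 <- img[cbind(y1[i] + 1, x0[i] + 1)]
    v11 <- img[cbind(y1[i] + 1, x1[i] + 1)]
    out[i] <- (1 - fy[i]) * ((1 - fx[i]) * v00 + fx[i] * v01) +
      fy[i] * ((1 - fx[i]) * v10 + fx[i] * v11)
  }
  out
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multichannel inputs are reduced by the channel mean. Values are returned
#' on the scale stored in the file (PNG: \code{[0, 1]}).
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix.
#' @export
read_image_gray <- function(path) {
  arr <- read_image_any(path)
  if (length(dim(arr)) == 3L) {
    nc <- min(dim(arr)[3], 3L)  # drop alpha from the mean
    arr <- apply(arr[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  arr
}

read_image_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, all = FALSE)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
}

#' Read / write a 16-bit depth image in millimeters
#'
#' Depth is stored as a 16-bit grayscale PNG whose integer sample values are
#' millimeters (0 = invalid).
#'
#' @param path PNG file path.
#' @param depth_mm numeric matrix of depths in millimeters.
#' @return \code{read_depth_png} returns a numeric matrix in millimeters.
#' @export
read_depth_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * 65535)
}

## CRC-32 (IEEE 802.3) over raw bytes, table-driven; PNG chunk checksums.
.crc_env <- new.env(parent = emptyenv())
crc32_bytes <- function(bytes) {
  if (is.null(.crc_env$table)) {
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
        } else bitwShiftR(c, 1L)
      }
      tab[n + 1] <- c
    }
    .crc_env$table <- tab
  }
  tab <- .crc_env$table
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

int32_be <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L), bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L), bitwAnd(x, 255L)))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int32_be(length(data)), body, int32_be(crc32_bytes(body)))
}

#' @rdname read_depth_png
#' @export
write_depth_png <- function(depth_mm, path) {
  depth_mm[!is.finite(depth_mm)] <- 0
  v <- pmin(pmax(round(depth_mm), 0), 65535)
  h <- nrow(v); w <- ncol(v)
  ## 16-bit grayscale scanlines (big-endian samples, filter byte 0 per row)
  vt <- t(v)  # row-major traversal
  hi <- as.raw(vt %/% 256L)
  lo <- as.raw(vt %% 256L)
  samples <- as.raw(rbind(hi, lo))  # interleave high/low byte
  rows <- matrix(samples, nrow = 2L * w)
  scan <- as.raw(rbind(raw(1), rows))  # prepend filter 0 to each scanline
  ihdr <- c(int32_be(w), int32_be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(as.raw(scan), "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
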