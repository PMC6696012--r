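## Minimal PLY writer/reader for spectral point clouds. Binary
## little-endian by default (float32 coordinates/reflectance, uchar colors,
## int32 view id), with an ascii fallback. Only the vertex element is
## supported, which is all this pipeline produces.

ply_property_spec <- function(cloud) {
  cols <- names(cloud)
  type_of <- function(cc) {
    if (cc %in% c("red", "green", "blue")) "uchar"
    else if (cc %in% c("view_id", "pixel_i", "pixel_j")) "int"
    else "float"
  }
  data.frame(name = cols, type = vapply(cols, type_of, ""),
             stringsAsFactors = FALSE)
}

#' Write a spectral point cloud as PLY
#'
#' Vertex properties follow the cloud's columns: \code{x, y, z} and
#' reflectance/index columns as \code{float}, \code{red, green, blue} as
#' \code{uchar}, \code{view_id} and pixel provenance as \code{int}. NA
#' reflectance is stored as NaN.
#'
#' @param cloud \code{spectral_point_cloud}.
#' @param path output path.
#' @param binary write \code{binary_little_endian} (default) or ascii.
#' @return the path, invisibly.
#' @export
write_ply <- function(cloud, path, binary = TRUE) {
  spec <- ply_property_spec(cloud)
  fmt <- if (binary) "binary_little_endian 1.0" else "ascii 1.0"
  header <- c(
    "ply",
    paste("format", fmt),
    "comment multispectral plant point cloud",
    paste("element vertex", nrow(cloud)),
    paste("property", spec$type, spec$name),
    "end_header"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  n <- nrow(cloud)
  if (n == 0) return(invisible(path))
  if (binary) {
    ## interleave per-vertex records through a raw buffer
    sizes <- ifelse(spec$type == "uchar", 1L, 4L)
    offs <- c(0L, cumsum(sizes))
    rec <- sum(sizes)
    buf <- raw(rec * n)
    for (k in seq_len(nrow(spec))) {
      v <- cloud[[spec$name[k]]]
      bytes <- switch(spec$type[k],
        uchar = as.raw(pmin(pmax(round(v), 0), 255)),
        int = writeBin(as.integer(v), raw(), size = 4L, endian = "little"),
        float = {
          v <- as.numeric(v); v[is.na(v)] <- NaN
          writeBin(v, raw(), size = 4L, endian = "little")
        })
      src <- matrix(bytes, nrow = sizes[k])
      pos <- outer(seq_len(sizes[k]), (seq_len(n) - 1L) * rec,
                   function(a, b) a + b + offs[k])
      buf[as.integer(pos)] <- as.raw(src)
    }
    writeBin(buf, con)
  } else {
    df <- as.data.frame(cloud)
    for (k in which(spec$type != "float")) {
      df[[spec$name[k]]] <- as.integer(round(df[[spec$name[k]]]))
    }
    utils::write.table(format(df, scientific = FALSE, trim = TRUE,
                              digits = 9),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a PLY point cloud written by \code{\link{write_ply}}
#'
#' Supports ascii and binary little-endian vertex-only PLY with uchar, int
#' and float properties.
#'
#' @param path PLY file path.
#' @return a \code{spectral_point_cloud}.
#' @export
read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  read_line_raw <- function(con) {
    bytes <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0 || b == as.raw(10L)) break
      bytes <- c(bytes, b)
    }
    rawToChar(bytes)
  }
  header <- character()
  repeat {
    line <- read_line_raw(con)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 200) stop("malformed PLY header", call. = FALSE)
  }
  fmt <- sub("^format ", "", grep("^format ", header, value = TRUE))
  binary <- grepl("binary_little_endian", fmt)
  n <- as.integer(sub("^element vertex ", "",
                      grep("^element vertex ", header, value = TRUE)))
  props <- strsplit(grep("^property ", header, value = TRUE), " ")
  types <- vapply(props, `[`, "", 2)
  nms <- vapply(props, `[`, "", 3)
  out <- vector("list", length(nms))
  names(out) <- nms
  if (binary) {
    sizes <- ifelse(types == "uchar", 1L, 4L)
    rec <- sum(sizes)
    buf <- readBin(con, "raw", n = rec * n)
    offs <- c(0L, cumsum(sizes))
    for (k in seq_along(nms)) {
      pos <- outer(seq_len(sizes[k]), (seq_len(n) - 1L) * rec,
                   function(a, b) a + b + offs[k])
      bytes <- buf[as.integer(pos)]
      out[[k]] <- switch(types[k],
        uchar = as.numeric(as.integer(bytes)),
        int = readBin(bytes, "integer", n = n, size = 4L, endian = "little"),
        float = readBin(bytes, "numeric", n = n, size = 4L,
                        endian = "little"))
    }
  } else {
    txt <- rawToChar(readBin(con, "raw", n = file.size(path)))
    tab <- utils::read.table(text = txt, nrows = n)
    names(tab) <- nms
    for (k in seq_along(nms)) out[[k]] <- tab[[k]]
  }
  df <- as.data.frame(out)
  for (k in which(types == "float")) df[[k]][is.nan(df[[k]])] <- NA_real_
  for (k in which(types == "int")) df[[k]] <- as.integer(df[[k]])
  class(df) <- c("spectral_point_cloud", "data.frame")
  df
}
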