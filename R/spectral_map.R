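## Multiband reflectance cubes and their mapping onto the depth grid.

#' Default reflectance band set
#'
#' Band names and center wavelengths (nm) of the five characteristic bands
#' used for vegetation-index work: Blue 466.93, Green 564.91, Red 696.32,
#' Red-edge 722.94, Nir 841.4.
#'
#' @return named numeric vector of center wavelengths.
#' @export
default_bands <- function() {
  c(Blue = 466.93, Green = 564.91, Red = 696.32,
    `Red-edge` = 722.94, Nir = 841.4)
}

## rho_* column names used on point clouds, in band order
band_columns <- function(bands = names(default_bands())) {
  paste0("rho_", gsub("-", "", tolower(bands)))
}

#' Construct a spectral reflectance cube
#'
#' @param planes named list of numeric matrices (one per band), values in
#'   \code{[0, 1]} or NA; all planes must share one shape.
#' @param wavelengths_nm named numeric vector of band centers; defaults to
#'   \code{\link{default_bands}} subset to the plane names.
#' @return object of class \code{spectral_cube}.
#' @export
spectral_cube <- function(planes, wavelengths_nm = NULL) {
  stopifnot(is.list(planes), length(planes) >= 1, !is.null(names(planes)))
  if (anyDuplicated(names(planes))) stop("band names must be unique", call. = FALSE)
  shp <- dim(planes[[1]])
  for (nm in names(planes)) {
    check_image2d(planes[[nm]], name = paste0("band ", nm))
    if (!all(dim(planes[[nm]]) == shp)) {
      stop("all bands must share one shape", call. = FALSE)
    }
  }
  if (is.null(wavelengths_nm)) {
    db <- default_bands()
    wavelengths_nm <- db[intersect(names(planes), names(db))]
  }
  rng <- range(unlist(planes), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    warning("reflectance outside [0, 1]; values clipped", call. = FALSE)
    planes <- lapply(planes, function(p) pmin(pmax(p, 0), 1))
  }
  structure(list(planes = planes, wavelengths_nm = wavelengths_nm),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  shp <- dim(x$planes[[1]])
  cat(sprintf("spectral cube: %d bands (%s), %d x %d px\n",
              length(x$planes), paste(names(x$planes), collapse = ", "),
              shp[1], shp[2]))
  invisible(x)
}

#' Register every band of a cube onto the depth grid
#'
#' Applies one calibrated similarity transform to all bands so reflectance
#' lands on the depth camera's pixel grid. Pixels with no source coverage
#' are NA.
#'
#' @param cube \code{spectral_cube}.
#' @param t \code{reg_transform2d} estimated between the spectral imager's
#'   grayscale view (moving) and the depth camera's grayscale view
#'   (reference) for this rig.
#' @param depth_shape c(height, width) of the depth grid.
#' @return a \code{spectral_cube} on the depth grid (the registered
#'   reflectance stack).
#' @export
register_cube <- function(cube, t, depth_shape) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(t, "reg_transform2d"))
  planes <- lapply(cube$planes, function(p) {
    warp_similarity(p, t, out_shape = depth_shape, fill = NA_real_)
  })
  suppressWarnings(spectral_cube(planes, cube$wavelengths_nm))
}

#' Attach per-pixel reflectance to a point cloud
#'
#' Samples each registered band at every point's source pixel
#' (nearest-neighbor by provenance: one pixel, one point) and stores it as a
#' \code{rho_*} column. Geometry and color are untouched; missing coverage
#' gives NA.
#'
#' @param cloud \code{spectral_point_cloud} with \code{pixel_i},
#'   \code{pixel_j} provenance columns (0-based).
#' @param stack registered \code{spectral_cube} on the depth grid.
#' @return the cloud with one \code{rho_*} column per band.
#' @export
attach_reflectance <- function(cloud, stack) {
  stopifnot(inherits(cloud, "spectral_point_cloud"),
            inherits(stack, "spectral_cube"))
  if (!all(c("pixel_i", "pixel_j") %in% names(cloud))) {
    stop("cloud lacks pixel provenance (pixel_i / pixel_j)", call. = FALSE)
  }
  idx <- cbind(cloud$pixel_j + 1L, cloud$pixel_i + 1L)
  cols <- band_columns(names(stack$planes))
  for (k in seq_along(stack$planes)) {
    cloud[[cols[k]]] <- stack$planes[[k]][idx]
  }
  cloud
}

#' Read / write a spectral cube as multiband TIFF plus band metadata JSON
#'
#' The TIFF stores one 32-bit float plane per band. Because the TIFF layer
#' clamps samples to \code{[0, 1]}, reflectance x is stored as
#' \code{(x + 1) / 2} with 0 reserved for missing values; the reader
#' inverts the encoding. The sidecar JSON (same path with extension
#' \code{.json}) records band names and center wavelengths.
#'
#' @param cube \code{spectral_cube}.
#' @param path TIFF file path.
#' @return \code{read_cube_tiff} returns a \code{spectral_cube}.
#' @export
write_cube_tiff <- function(cube, path) {
  planes <- lapply(cube$planes, function(p) {
    enc <- (p + 1) / 2
    enc[is.na(p)] <- 0
    enc
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(bands = names(cube$planes),
               wavelengths_nm = as.list(cube$wavelengths_nm))
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cube_tiff
#' @export
read_cube_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  names(planes) <- meta$bands
  planes <- lapply(planes, function(p) {
    dec <- 2 * p - 1
    dec[p == 0] <- NA_real_
    dec
  })
  suppressWarnings(spectral_cube(planes, unlist(meta$wavelengths_nm)))
}
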