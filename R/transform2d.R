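## 2D similarity transforms between two sensor pixel grids.
##
## A transform t maps moving-image coordinates onto reference-image
## coordinates, acting about the grid centers:
##
##   p_ref = sigma * R(theta0) * (p_mov - c_mov) + c_ref + (dx, dy)
##
## where c_* = ((w-1)/2, (h-1)/2) of the respective grids and R rotates in
## the x-right / y-down pixel frame. Angles are degrees, sigma is the
## moving-to-reference magnification.

#' Construct a 2D similarity transform
#'
#' @param dx,dy translation in reference-grid pixels.
#' @param theta0 rotation angle, degrees.
#' @param sigma scale factor (> 0).
#' @param peak_response normalized phase-correlation peak height associated
#'   with the estimate, if any.
#' @return an object of class \code{reg_transform2d}.
#' @export
transform2d <- function(dx = 0, dy = 0, theta0 = 0, sigma = 1,
                        peak_response = NA_real_) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(theta0), is.finite(sigma))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(
    list(dx = dx, dy = dy, theta0 = theta0, sigma = sigma,
         peak_response = peak_response),
    class = "reg_transform2d"
  )
}

#' @export
print.reg_transform2d <- function(x, ...) {
  cat(sprintf(
    "2D similarity transform: dx=%.3f px, dy=%.3f px, theta0=%.3f deg, sigma=%.4f",
    x$dx, x$dy, x$theta0, x$sigma))
  if (is.finite(x$peak_response)) {
    cat(sprintf(" (peak response %.3f)", x$peak_response))
  }
  cat("\n")
  invisible(x)
}

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

grid_center <- function(shape) c((shape[2] - 1) / 2, (shape[1] - 1) / 2)

#' Invert a similarity transform
#'
#' Valid for transforms between grids treated as sharing one center (the
#' usual equal-shape registration setting).
#'
#' @param t a \code{reg_transform2d}.
#' @return the inverse \code{reg_transform2d}.
#' @export
invert_transform2d <- function(t) {
  Rinv <- rot2(-t$theta0) / t$sigma
  d <- -Rinv %*% c(t$dx, t$dy)
  transform2d(d[1], d[2], -t$theta0, 1 / t$sigma,
              peak_response = t$peak_response)
}

#' Warp an image by a similarity transform
#'
#' Inverse-maps every output pixel through \code{t} and samples the input by
#' bilinear interpolation, so that \code{warp_similarity(mov, t)} lies on the
#' reference grid when \code{t} maps \code{mov} onto that grid.
#'
#' @param img numeric matrix (moving image).
#' @param t \code{reg_transform2d}.
#' @param out_shape integer c(height, width) of the output grid; defaults to
#'   the input shape.
#' @param fill value for pixels mapping outside the input domain.
#' @return numeric matrix of dimension \code{out_shape}.
#' @export
warp_similarity <- function(img, t, out_shape = dim(img), fill = NA_real_) {
  check_image2d(img)
  stopifnot(inherits(t, "reg_transform2d"))
  h <- out_shape[1]; w <- out_shape[2]
  c_out <- grid_center(out_shape)
  c_in <- grid_center(dim(img))
  px <- rep(seq_len(w) - 1, each = h)
  py <- rep(seq_len(h) - 1, times = w)
  Rinv <- rot2(-t$theta0) / t$sigma
  ux <- px - c_out[1] - t$dx
  uy <- py - c_out[2] - t$dy
  qx <- Rinv[1, 1] * ux + Rinv[1, 2] * uy + c_in[1]
  qy <- Rinv[2, 1] * ux + Rinv[2, 2] * uy + c_in[2]
  matrix(interp_bilinear(img, qx, qy, fill = fill), h, w)
}

#' Apply a similarity transform to pixel coordinates
#'
#' @param t \code{reg_transform2d}.
#' @param xy two-column matrix of 0-based (x, y) moving-grid coordinates.
#' @param shape_mov,shape_ref grid shapes c(height, width) defining centers.
#' @return two-column matrix of reference-grid coordinates.
#' @export
apply_transform2d <- function(t, xy, shape_mov, shape_ref = shape_mov) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  c_in <- grid_center(shape_mov); c_out <- grid_center(shape_ref)
  R <- rot2(t$theta0) * t$sigma
  sweep(t(R %*% t(sweep(xy, 2, c_in))), 2,
        -(c_out + c(t$dx, t$dy)))
}

#' Serialize / load a similarity transform as JSON
#'
#' Keys: \code{dx}, \code{dy}, \code{theta0_deg}, \code{sigma},
#' \code{peak_response}.
#'
#' @param t \code{reg_transform2d}.
#' @param path JSON file path.
#' @return \code{read_transform2d} returns a \code{reg_transform2d}.
#' @export
write_transform2d <- function(t, path) {
  jsonlite::write_json(
    list(dx = t$dx, dy = t$dy, theta0_deg = t$theta0, sigma = t$sigma,
         peak_response = t$peak_response),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform2d
#' @export
read_transform2d <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform2d(x$dx, x$dy, x$theta0_deg, x$sigma,
              peak_response = if (is.null(x$peak_response)) NA_real_
                              else as.numeric(x$peak_response))
}
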