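## Turntable axis self-calibration from two colored calibration stickers
## observed at two table rotations 180 degrees apart. The midpoint of a
## sticker's two positions lies on the rotation axis; the axis normal is
## orthogonal to the table plane through the four sticker centers.

#' HSV color specification for sticker detection
#'
#' Ranges are on the \code{grDevices::rgb2hsv} scale: h, s, v all in
#' \code{[0, 1]} (h = hue angle / 360). A wrap-around hue range (e.g. red)
#' is expressed with \code{h[1] > h[2]}.
#'
#' @param h,s,v length-2 numeric ranges.
#' @return object of class \code{color_spec}.
#' @export
color_spec <- function(h, s = c(0.4, 1), v = c(0.3, 1)) {
  stopifnot(length(h) == 2, length(s) == 2, length(v) == 2)
  structure(list(h = h, s = s, v = v), class = "color_spec")
}

#' Default sticker color specifications
#'
#' @return named list with \code{yellow} and \code{red} \code{color_spec}s
#'   (disjoint hue ranges).
#' @export
sticker_colors <- function() {
  list(yellow = color_spec(h = c(0.10, 0.22)),
       red = color_spec(h = c(0.95, 0.05)))
}

hsv_mask <- function(cloud, spec) {
  if (!all(c("red", "green", "blue") %in% names(cloud))) {
    stop("cloud has no RGB attributes", call. = FALSE)
  }
  hsv <- rgb2hsv(t(cbind(cloud$red, cloud$green, cloud$blue)), maxColorValue = 255)
  h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  in_h <- if (spec$h[1] <= spec$h[2]) {
    h >= spec$h[1] & h <= spec$h[2]
  } else {
    h >= spec$h[1] | h <= spec$h[2]  # wrap-around (red)
  }
  in_h & s >= spec$s[1] & s <= spec$s[2] & v >= spec$v[1] & v <= spec$v[2]
}

#' Detect the 3D center of a colored calibration sticker
#'
#' Thresholds the cloud's RGB attributes in HSV space and returns the
#' centroid of the inlier points.
#'
#' @param cloud \code{spectral_point_cloud} with RGB.
#' @param spec \code{color_spec} for the sticker color.
#' @param min_inliers minimum inlier count below which detection fails
#'   (default 20).
#' @return list with \code{center} (xyz, meters) and \code{n_inliers}.
#' @export
detect_sticker_center <- function(cloud, spec, min_inliers = 20L) {
  m <- hsv_mask(cloud, spec)
  n <- sum(m)
  if (n < min_inliers) {
    stop("sticker detection failure: ", n, " inlier points (minimum ",
         min_inliers, ")", call. = FALSE)
  }
  list(center = colMeans(as_xyz(cloud[m, , drop = FALSE])), n_inliers = n)
}

new_rotary_calibration <- function(center, normal, residual,
                                   n_inliers = NULL) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(center = as.numeric(center), normal = as.numeric(normal),
                 residual = residual, n_inliers = n_inliers),
            class = "rotary_calibration")
}

#' @export
print.rotary_calibration <- function(x, ...) {
  cat(sprintf(
    "turntable axis: center (%.4f, %.4f, %.4f) m, normal (%.4f, %.4f, %.4f), residual %.2e m\n",
    x$center[1], x$center[2], x$center[3],
    x$normal[1], x$normal[2], x$normal[3], x$residual))
  invisible(x)
}

#' Estimate the turntable rotation axis from sticker centers
#'
#' Given the 3D centers of the yellow and red stickers at table rotation 0
#' (\code{Y1}, \code{R1}) and after a 180-degree rotation (\code{Y2},
#' \code{R2}), the axis center M is the mean of the two sticker midpoints
#' (each midpoint lies on the axis for a 180-degree rotation) and the axis
#' normal is the unit normal of the table plane through the four centers:
#' the average of (R1-M) x (Y1-M) and (R2-M) x (Y2-M), oriented to within
#' 90 degrees of the camera +Y axis. With more than two views (list input),
#' midpoints of all opposite-view pairs are averaged and the plane is
#' fitted to all centers by total least squares.
#'
#' @param Y1,R1,Y2,R2 xyz sticker centers, meters. Alternatively \code{Y1}
#'   and \code{R1} may be matrices with one row per view (views 180/k apart
#'   in opposite pairs), with \code{Y2}, \code{R2} omitted.
#' @return a \code{rotary_calibration} with \code{center}, unit
#'   \code{normal} and \code{residual} (RMS plane distance of the sticker
#'   centers, meters).
#' @export
estimate_axis <- function(Y1, R1, Y2 = NULL, R2 = NULL) {
  if (is.matrix(Y1) && is.null(Y2)) {
    return(estimate_axis_multi(Y1, R1))
  }
  Y1 <- as.numeric(Y1); R1 <- as.numeric(R1)
  Y2 <- as.numeric(Y2); R2 <- as.numeric(R2)
  if (sqrt(sum((Y1 - Y2)^2)) < 0.005 || sqrt(sum((R1 - R2)^2)) < 0.005) {
    stop("degenerate geometry: sticker on the rotation axis", call. = FALSE)
  }
  M <- (0.5 * (Y1 + Y2) + 0.5 * (R1 + R2)) / 2
  pts <- rbind(Y1, R1, Y2, R2)
  if (collinear_within(pts, 0.001)) {
    stop("degenerate geometry: sticker centers nearly collinear",
         call. = FALSE)
  }
  n1 <- cross3(R1 - M, Y1 - M)
  n2 <- cross3(R2 - M, Y2 - M)
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  normal <- n1 + n2
  if (sqrt(sum(normal^2)) < 1e-12) normal <- n1
  normal <- normal / sqrt(sum(normal^2))
  if (normal[2] < 0) normal <- -normal  # orient toward camera +Y
  resid <- sqrt(mean((sweep(pts, 2, M) %*% normal)^2))
  new_rotary_calibration(M, normal, resid)
}

estimate_axis_multi <- function(Y, R) {
  stopifnot(is.matrix(Y), is.matrix(R), nrow(Y) == nrow(R), nrow(Y) >= 2,
            nrow(Y) %% 2 == 0)
  k <- nrow(Y) / 2
  mids <- rbind((Y[seq_len(k), , drop = FALSE] +
                   Y[seq_len(k) + k, , drop = FALSE]) / 2,
                (R[seq_len(k), , drop = FALSE] +
                   R[seq_len(k) + k, , drop = FALSE]) / 2)
  M <- colMeans(mids)
  pts <- rbind(Y, R)
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)
  normal <- sv$v[, 3]
  if (normal[2] < 0) normal <- -normal
  resid <- sqrt(mean((sweep(pts, 2, M) %*% normal)^2))
  new_rotary_calibration(M, normal, resid)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

collinear_within <- function(pts, tol) {
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)
  ## distance from the best-fit line: second singular value scaled by sqrt(n)
  sv$d[2] / sqrt(nrow(pts)) < tol
}

#' Serialize / load a turntable calibration as JSON
#'
#' @param calib \code{rotary_calibration}.
#' @param path JSON file path.
#' @return \code{read_calibration} returns a \code{rotary_calibration}.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(
    list(center_m = calib$center, normal = calib$normal,
         residual_m = calib$residual, n_inliers = calib$n_inliers),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_rotary_calibration(x$center_m, x$normal, x$residual_m, x$n_inliers)
}
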