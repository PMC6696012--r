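## Spectral point clouds: data.frame-backed container with XYZ (meters),
## 8-bit RGB, per-band reflectance, pixel provenance and view id.

#' Camera intrinsics
#'
#' Pinhole parameters of the depth camera.
#'
#' @param cx,cy principal point, pixels.
#' @param fx,fy focal lengths, pixels (> 0).
#' @return object of class \code{camera_intrinsics}.
#' @export
camera_intrinsics <- function(cx, cy, fx, fy) {
  stopifnot(is.finite(cx), is.finite(cy), fx > 0, fy > 0)
  structure(list(cx = cx, cy = cy, fx = fx, fy = fy),
            class = "camera_intrinsics")
}

#' Construct a spectral point cloud
#'
#' @param xyz n x 3 matrix of finite coordinates, meters.
#' @param rgb n x 3 matrix of 8-bit colors (0-255), optional.
#' @param ... further per-point columns (reflectance \code{rho_*},
#'   \code{pixel_i}, \code{pixel_j}, \code{view_id}, indices); each of
#'   length n.
#' @return a \code{spectral_point_cloud} (data.frame with columns
#'   \code{x, y, z} plus the supplied attributes).
#' @export
spectral_point_cloud <- function(xyz, rgb = NULL, ...) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (nrow(xyz) > 0 && !all(is.finite(xyz))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  df <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  if (!is.null(rgb)) {
    rgb <- matrix(as.numeric(rgb), ncol = 3)
    stopifnot(nrow(rgb) == nrow(df))
    df$red <- rgb[, 1]; df$green <- rgb[, 2]; df$blue <- rgb[, 3]
  }
  extra <- list(...)
  for (nm in names(extra)) {
    stopifnot(length(extra[[nm]]) == nrow(df))
    df[[nm]] <- extra[[nm]]
  }
  class(df) <- c("spectral_point_cloud", "data.frame")
  df
}

#' @export
print.spectral_point_cloud <- function(x, ...) {
  cat(sprintf("spectral point cloud: %d points, columns: %s\n",
              nrow(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

as_xyz <- function(cloud) cbind(cloud$x, cloud$y, cloud$z)

set_xyz <- function(cloud, xyz) {
  cloud$x <- xyz[, 1]; cloud$y <- xyz[, 2]; cloud$z <- xyz[, 3]
  cloud
}

#' Unproject a depth image to a point cloud
#'
#' Pinhole back-projection of each valid depth pixel (i = column, j = row,
#' 0-based):
#' \deqn{x = (i - c_x) z / f_x,\quad y = -(j - c_y) z / f_y,\quad
#'       z = Depth(i, j) / 1000}
#' The y sign flip makes +Y point up in the camera frame. Pixels with depth
#' 0, NA, or outside the sensor's valid range produce no point.
#'
#' @param depth_mm numeric matrix of depths in millimeters.
#' @param K \code{camera_intrinsics}.
#' @param rgb optional height x width x 3 array in \code{[0, 1]} supplying
#'   point colors.
#' @param view_id integer view index recorded per point.
#' @param z_range valid depth range in meters (sensor detection range);
#'   default c(0.5, 4.5).
#' @return \code{spectral_point_cloud} with pixel provenance.
#' @export
unproject <- function(depth_mm, K, rgb = NULL, view_id = 0L,
                      z_range = c(0.5, 4.5)) {
  check_image2d(depth_mm, name = "depth_mm")
  stopifnot(inherits(K, "camera_intrinsics"))
  h <- nrow(depth_mm); w <- ncol(depth_mm)
  z <- as.numeric(depth_mm) / 1000
  valid <- is.finite(z) & z >= z_range[1] & z <= z_range[2]
  j <- rep(seq_len(h) - 1L, times = w)  # row
  i <- rep(seq_len(w) - 1L, each = h)   # column
  i <- i[valid]; j <- j[valid]; z <- z[valid]
  x <- (i - K$cx) * z / K$fx
  y <- -(j - K$cy) * z / K$fy
  col <- NULL
  if (!is.null(rgb)) {
    idx <- cbind(j + 1L, i + 1L)
    col <- cbind(rgb[, , 1][idx], rgb[, , 2][idx], rgb[, , 3][idx]) * 255
    col <- round(col)
  }
  spectral_point_cloud(cbind(x, y, z), rgb = col,
                       pixel_i = i, pixel_j = j,
                       view_id = rep(as.integer(view_id), length(z)))
}

#' Project cloud points back to depth-image coordinates
#'
#' Inverse of \code{\link{unproject}}; used for round-trip checks.
#'
#' @param cloud \code{spectral_point_cloud} in the camera frame.
#' @param K \code{camera_intrinsics}.
#' @return data.frame with columns \code{i}, \code{j} (pixels) and
#'   \code{depth_mm}.
#' @export
project_points <- function(cloud, K) {
  z <- cloud$z
  data.frame(i = K$cx + cloud$x * K$fx / z,
             j = K$cy - cloud$y * K$fy / z,
             depth_mm = z * 1000)
}

## Rotation taking the calibrated axis normal to +Y: Rz(beta) %*% Rx(alpha)
## with cos a = b/s, sin a = c/s (s = sqrt(b^2+c^2)) and cos b = s, sin b = a
## for the unit normal (a, b, c).
axis_alignment_rotation <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- n[1]; b <- n[2]; c <- n[3]
  s <- sqrt(b^2 + c^2)
  if (s < 1e-12) {
    stop("degenerate axis: normal parallel to camera X", call. = FALSE)
  }
  Rx <- matrix(c(1, 0, 0,
                 0, b / s, -c / s,
                 0, c / s, b / s), 3, 3)  # column-major: maps (b,c)->(s,0)
  Rz <- matrix(c(s, a, 0,
                 -a, s, 0,
                 0, 0, 1), 3, 3)          # maps (a,s,0)->(0,1,0)
  Rz %*% Rx
}

#' Rotation about +Y by the per-view inverse table angle
#'
#' @param gamma_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_y <- function(gamma_deg) {
  g <- gamma_deg * pi / 180
  matrix(c(cos(g), 0, sin(g),
           0, 1, 0,
           -sin(g), 0, cos(g)), 3, 3)
}

#' Transform a view's cloud into the common turntable frame
#'
#' Rough registration: translate the axis center to the origin, rotate the
#' axis normal onto +Y (one rotation about X, one about Z), then rotate
#' about Y by the view's inverse table angle gamma so all views share one
#' frame.
#'
#' @param cloud \code{spectral_point_cloud} in the camera frame.
#' @param calib \code{rotary_calibration} (see \code{\link{estimate_axis}}).
#' @param gamma_deg inverse rotation angle about +Y, degrees; for view k of
#'   V_N equally spaced views this is \code{spin_sign * k * 360 / V_N}.
#' @return the transformed cloud.
#' @export
to_common_frame <- function(cloud, calib, gamma_deg = 0) {
  stopifnot(inherits(calib, "rotary_calibration"))
  R <- rotation_y(gamma_deg) %*% axis_alignment_rotation(calib$normal)
  xyz <- sweep(as_xyz(cloud), 2, calib$center)
  set_xyz(cloud, xyz %*% t(R))
}

#' Crop a cloud to an axis-aligned box
#'
#' @param cloud \code{spectral_point_cloud}.
#' @param box list or vector with \code{xmin, xmax, ymin, ymax, zmin, zmax}
#'   in meters (the plant region of interest in the common frame).
#' @return the cropped cloud; attributes preserved.
#' @export
crop_roi <- function(cloud, box) {
  b <- as.list(box)
  stopifnot(b$xmin < b$xmax, b$ymin < b$ymax, b$zmin < b$zmax)
  keep <- cloud$x >= b$xmin & cloud$x <= b$xmax &
    cloud$y >= b$ymin & cloud$y <= b$ymax &
    cloud$z >= b$zmin & cloud$z <= b$zmax
  cloud[keep, , drop = FALSE]
}

#' Keep canopy points above the pot top
#'
#' In the common frame (axis center at the origin, +Y up) the canopy is
#' separated from pot and table by a height cut.
#'
#' @param cloud \code{spectral_point_cloud} in the common frame.
#' @param pot_top_height pot-top height, meters.
#' @return points with \code{y > pot_top_height}.
#' @export
extract_canopy <- function(cloud, pot_top_height) {
  cloud[cloud$y > pot_top_height, , drop = FALSE]
}

#' Statistical outlier removal
#'
#' Discards points whose mean distance to their k nearest neighbors exceeds
#' the global mean by more than \code{std_ratio} standard deviations.
#'
#' @param cloud \code{spectral_point_cloud} with more than
#'   \code{k_neighbors} points.
#' @param k_neighbors neighborhood size (default 20).
#' @param std_ratio threshold in global standard deviations (default 2).
#' @return the filtered cloud.
#' @export
remove_outliers <- function(cloud, k_neighbors = 20L, std_ratio = 2.0) {
  n <- nrow(cloud)
  if (n <= k_neighbors) {
    stop("cloud must have more than k_neighbors points", call. = FALSE)
  }
  d <- cpp_knn_mean_dist(as_xyz(cloud), as.integer(k_neighbors))
  thr <- mean(d) + std_ratio * sd(d)
  cloud[d <= thr, , drop = FALSE]
}

#' Voxel-grid downsampling
#'
#' Averages XYZ, RGB and reflectance (NA-aware) within each occupied voxel
#' and majority-votes integer attributes (view id, pixel provenance).
#'
#' @param cloud \code{spectral_point_cloud}.
#' @param voxel voxel edge length, meters (default 0.002).
#' @return the downsampled cloud (one point per occupied voxel).
#' @export
voxel_downsample <- function(cloud, voxel = 0.002) {
  stopifnot(voxel > 0)
  if (nrow(cloud) == 0) return(cloud)
  dt <- data.table::as.data.table(as.data.frame(cloud))
  dt$`.vx` <- floor(cloud$x / voxel)
  dt$`.vy` <- floor(cloud$y / voxel)
  dt$`.vz` <- floor(cloud$z / voxel)
  num_cols <- setdiff(names(cloud)[vapply(cloud, is.double, TRUE)], character())
  int_cols <- names(cloud)[vapply(cloud, is.integer, TRUE)]
  mode_int <- function(v) {
    tb <- tabulate(match(v, unique(v)))
    unique(v)[which.max(tb)]
  }
  agg <- dt[, c(lapply(.SD[, num_cols, with = FALSE],
                       function(v) mean(v, na.rm = TRUE)),
                lapply(.SD[, int_cols, with = FALSE], mode_int)),
            by = c(".vx", ".vy", ".vz")]
  agg <- as.data.frame(agg)[, c(num_cols, int_cols), drop = FALSE]
  for (cc in num_cols) agg[[cc]][is.nan(agg[[cc]])] <- NA_real_
  class(agg) <- c("spectral_point_cloud", "data.frame")
  agg
}
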