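## Synthetic turntable scenes with full ground truth: a leafy plant in a
## pot on a rotating table disc carrying two colored calibration stickers,
## imaged by a pinhole RGB-D camera plus a co-mounted reflectance imager
## whose pixel grid differs from the depth grid by a known 2D similarity
## transform. Every latent quantity (axis, per-view poses, similarity
## transform, per-point SPAD and labels) is exposed for validation.
##
## The scene lives in the "table frame": rotation-axis center at the
## origin, +Y along the axis normal. The camera pose maps this frame into
## camera coordinates.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Default synthetic-scene parameters
#'
#' Geometry emulates the physical rig: a 20 cm turntable disc with two 5 cm
#' calibration stickers, a potted plant, a depth camera about 1 m away
#' (within its 0.5-4.5 m range) viewing the table from circa 30 degrees
#' elevation, and a reflectance imager offset from the depth grid by the
#' fixture similarity transform (dx = 8 px, dy = -5 px, theta = 4 deg,
#' sigma = 0.85). Depth noise defaults to 1.5 mm (typical time-of-flight
#' jitter); per-point SPAD is uniform over the observed range
#' [31.46, 60.90] and band reflectance is generated by inverting the
#' published CIG calibration, plus band noise.
#'
#' @return named list of parameters.
#' @export
scene_params <- function() {
  list(
    ## plant
    n_leaves = 8L, leaf_points = 600L, stem_points = 250L,
    stem_top = 0.30, stem_radius = 0.004,
    ## pot and table
    pot_points = 900L, pot_radius = 0.03, pot_height = 0.06,
    table_points = 6000L, table_radius = 0.10,
    sticker_points = 800L, sticker_radius = 0.025,
    sticker_pos_radius = 0.07, sticker_azimuths_deg = c(45, 135),
    ## camera
    image_width = 224L, image_height = 200L,
    fx = 300, fy = 300, cx = 112, cy = 100,
    axis_center_cam = c(0.02, -0.10, 1.05),
    elevation_deg = 30, axis_tilt_x = 0.03, yaw_deg = 0,
    ## spectral offset fixture
    reg_dx = 8, reg_dy = -5, reg_theta = 4, reg_sigma = 0.85,
    ## noise and physiology
    depth_sigma_mm = 1.5, band_sigma = 0.01,
    spad_range = c(31.46, 60.90), spad_model_index = "CIG",
    wall_reflectance = 0.85
  )
}

## Uniform points on a horizontal disc at height y.
disc_points <- function(n, radius, center_xz = c(0, 0), y = 0) {
  r <- radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  cbind(center_xz[1] + r * cos(a), rep(y, n), center_xz[2] + r * sin(a))
}

cylinder_side_points <- function(n, radius, y0, y1) {
  a <- runif(n, 0, 2 * pi)
  y <- runif(n, y0, y1)
  cbind(radius * cos(a), y, radius * sin(a))
}

## Random layout of parametric leaves around the stem (golden-angle
## phyllotaxis with jitter).
draw_leaf_layout <- function(n_leaves, stem_top) {
  if (n_leaves == 0) return(list())
  lapply(seq_len(n_leaves), function(l) {
    list(
      azimuth = (137.508 * l + runif(1, -15, 15)) * pi / 180,
      base_y = 0.12 + (l - 1) / max(n_leaves - 1, 1) * (stem_top - 0.14) +
        runif(1, -0.01, 0.01),
      length = runif(1, 0.07, 0.12),
      width = runif(1, 0.015, 0.025),
      elev = runif(1, 5, 35) * pi / 180,  # upward pitch of the leaf axis
      droop = runif(1, 0.00, 0.015)       # quadratic tip droop, meters
    )
  })
}

sample_leaf <- function(layout, n) {
  u <- runif(n)           # along the leaf axis
  v <- runif(n, -1, 1)    # across
  d <- c(cos(layout$elev) * cos(layout$azimuth), sin(layout$elev),
         cos(layout$elev) * sin(layout$azimuth))
  s <- c(-sin(layout$azimuth), 0, cos(layout$azimuth))
  base <- c(0, layout$base_y, 0)
  halfw <- layout$width * sin(pi * u)
  xyz <- matrix(base, n, 3, byrow = TRUE) +
    outer(u * layout$length, d) + outer(v * halfw, s)
  xyz[, 2] <- xyz[, 2] - layout$droop * u^2
  xyz
}

## Sample all scene surfaces; `factor` scales point density (used to build
## denser ground-truth surfaces for distance measurements).
scene_sample_points <- function(p, layout, factor = 1, seed = 0L) {
  with_seed(seed, {
    parts <- list()
    lab <- character(0)
    add <- function(xyz, label) {
      parts[[length(parts) + 1]] <<- xyz
      lab <<- c(lab, rep(label, nrow(xyz)))
    }
    az <- p$sticker_azimuths_deg * pi / 180
    st1 <- p$sticker_pos_radius * c(cos(az[1]), sin(az[1]))
    st2 <- p$sticker_pos_radius * c(cos(az[2]), sin(az[2]))
    add(disc_points(round(p$table_points * factor), p$table_radius), "table")
    ## stickers ride 0.2 mm above the disc so they win the z-buffer
    add(disc_points(round(p$sticker_points * factor), p$sticker_radius,
                    st1, y = 2e-4), "sticker_yellow")
    add(disc_points(round(p$sticker_points * factor), p$sticker_radius,
                    st2, y = 2e-4), "sticker_red")
    add(cylinder_side_points(round(p$pot_points * factor), p$pot_radius,
                             0, p$pot_height), "pot")
    add(cylinder_side_points(round(p$stem_points * factor), p$stem_radius,
                             p$pot_height, p$stem_top), "stem")
    for (lf in layout) {
      add(sample_leaf(lf, round(p$leaf_points * factor)), "leaf")
    }
    list(xyz = do.call(rbind, parts), labels = lab)
  })
}

## Per-point SPAD, band reflectance and RGB color for every scene point.
scene_attributes <- function(p, xyz, labels, seed) {
  with_seed(seed, {
    n <- nrow(xyz)
    spad <- rep(NA_real_, n)
    refl <- matrix(NA_real_, n, 5,
                   dimnames = list(NULL, band_columns()))
    col <- matrix(0, n, 3)
    plant <- labels %in% c("leaf", "stem")
    np <- sum(plant)
    spad[plant] <- runif(np, p$spad_range[1], p$spad_range[2])
    ## invert the published calibration so index <-> SPAD is well-posed
    gen <- spad_paper_model(p$spad_model_index)
    cig <- log10(spad[plant] / gen$coefficients[1]) / gen$coefficients[2]
    g <- runif(np, 0.10, 0.20)
    nir <- (cig + 1) * g
    refl[plant, ] <- cbind(runif(np, 0.03, 0.06),      # blue
                           g,                          # green
                           runif(np, 0.04, 0.08),      # red
                           (nir + runif(np, 0.04, 0.08)) / 2,  # red-edge
                           nir)
    fixed_refl <- list(
      table = c(0.35, 0.15, 0.08, 0.07, 0.06),
      sticker_yellow = c(0.08, 0.55, 0.60, 0.55, 0.50),
      sticker_red = c(0.05, 0.08, 0.55, 0.50, 0.45),
      pot = c(0.30, 0.30, 0.30, 0.30, 0.30))
    for (nm in names(fixed_refl)) {
      idx <- labels == nm
      if (any(idx)) {
        refl[idx, ] <- matrix(fixed_refl[[nm]], sum(idx), 5, byrow = TRUE)
      }
    }
    refl <- refl + matrix(rnorm(n * 5, 0, p$band_sigma), n, 5)
    refl <- pmin(pmax(refl, 0), 1)
    ## colors: leaf green darkens with SPAD; table blue; stickers saturated
    if (any(labels == "leaf")) {
      col[labels == "leaf", ] <- cbind(
        60, 170 - 2 * (spad[labels == "leaf"] - p$spad_range[1]), 50)
    }
    fixed_col <- list(stem = c(70, 140, 60), table = c(40, 70, 200),
                      sticker_yellow = c(250, 210, 30),
                      sticker_red = c(220, 40, 40), pot = c(120, 120, 120))
    for (nm in names(fixed_col)) {
      sel <- labels == nm
      if (any(sel)) {
        col[sel, ] <- matrix(fixed_col[[nm]], sum(sel), 3, byrow = TRUE)
      }
    }
    list(spad = spad, reflectance = refl, rgb = col)
  })
}

## Camera pose: rotation whose columns are the table-frame axes expressed
## in camera coordinates (column 2 = axis normal P).
scene_camera_pose <- function(p) {
  E <- p$elevation_deg * pi / 180
  P <- c(p$axis_tilt_x, cos(E), -sin(E))
  P <- P / sqrt(sum(P^2))
  ex <- cross3(P, c(0, 0, 1))
  ex <- ex / sqrt(sum(ex^2))
  ez <- cross3(ex, P)
  R <- cbind(ex, P, ez) %*% rotation_y(-p$yaw_deg)
  list(R = R, t = p$axis_center_cam, normal = P)
}

#' Generate a synthetic turntable scene
#'
#' @param params parameter list; defaults from \code{\link{scene_params}},
#'   entries may be overridden.
#' @param seed integer seed; scenes are reproducible from (params, seed).
#' @return object of class \code{synthetic_scene}: point set with labels,
#'   SPAD, reflectance and colors in the table frame, plus camera pose,
#'   intrinsics and the true spectral-to-depth similarity transform.
#' @export
make_scene <- function(params = list(), seed = 1L) {
  p <- modifyList(scene_params(), params)
  stopifnot(p$n_leaves >= 0, p$spad_range[1] < p$spad_range[2],
            p$pot_height < p$stem_top, p$table_radius > 0)
  layout <- with_seed(seed, draw_leaf_layout(p$n_leaves, p$stem_top))
  geom <- scene_sample_points(p, layout, factor = 1, seed = seed + 1L)
  attrs <- scene_attributes(p, geom$xyz, geom$labels, seed = seed + 2L)
  pose <- scene_camera_pose(p)
  structure(list(
    params = p, seed = seed, layout = layout,
    xyz = geom$xyz, labels = geom$labels,
    spad = attrs$spad, reflectance = attrs$reflectance, rgb = attrs$rgb,
    intrinsics = camera_intrinsics(p$cx, p$cy, p$fx, p$fy),
    pose = pose,
    reg_transform = transform2d(p$reg_dx, p$reg_dy, p$reg_theta,
                                p$reg_sigma)
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic scene: %d surface points (%d leaves), seed %d\n",
    nrow(x$xyz), x$params$n_leaves, x$seed))
  invisible(x)
}

#' Densely resampled ground-truth surface of a scene
#'
#' Regenerates the scene's surfaces (same layout) at \code{factor} times
#' the default point density, in the table frame. Used as the reference
#' surface for reconstruction-error measurements.
#'
#' @param scene \code{synthetic_scene}.
#' @param factor density multiplier.
#' @return list with \code{xyz} and \code{labels}.
#' @export
scene_surface_points <- function(scene, factor = 4) {
  scene_sample_points(scene$params, scene$layout, factor = factor,
                      seed = scene$seed + 3L)
}

## Right-handed rotation about the table axis (+Y in the table frame).
rotation_y_rh <- function(gamma_deg) t(rotation_y(gamma_deg))

#' Ground truth of a synthetic scene
#'
#' @param scene \code{synthetic_scene}.
#' @return list with \code{axis} (center, unit normal, in camera
#'   coordinates), \code{view_rigid} (function of the table angle returning
#'   the 4 x 4 table-to-camera transform), \code{similarity} (the true
#'   spectral-to-depth transform) and \code{labels}.
#' @export
ground_truth <- function(scene) {
  pose <- scene$pose
  view_rigid <- function(gamma_table_deg) {
    T <- diag(4)
    T[1:3, 1:3] <- pose$R %*% rotation_y_rh(gamma_table_deg)
    T[1:3, 4] <- pose$t
    T
  }
  list(axis = list(center = pose$t, normal = pose$normal),
       view_rigid = view_rigid,
       similarity = scene$reg_transform,
       labels = scene$labels)
}

#' Render one view of a synthetic scene
#'
#' Rotates the scene about the true axis by the table angle, projects every
#' point through the pinhole model with z-buffering (nearest surface wins
#' each pixel), adds Gaussian depth noise and quantizes depth to integer
#' millimeters. The reflectance cube is rendered on the depth grid and then
#' resampled onto the spectral imager's grid through the inverse of the
#' scene's true similarity transform; pixels with no scene surface show the
#' white imaging-room wall.
#'
#' @param scene \code{synthetic_scene}.
#' @param gamma_table_deg table rotation angle, degrees.
#' @param noise_sigma_mm depth noise standard deviation; defaults to the
#'   scene parameter.
#' @param noise_seed seed for the noise realization; defaults to a value
#'   derived from the scene seed and the table angle.
#' @return list with \code{rgb} (h x w x 3 array in [0, 1]), \code{depth}
#'   (matrix, millimeters, 0 = no return), \code{cube}
#'   (\code{spectral_cube} on the spectral grid), and \code{point_id}
#'   (matrix of winning scene-point indices, NA at background).
#' @export
render_view <- function(scene, gamma_table_deg, noise_sigma_mm = NULL,
                        noise_seed = NULL) {
  p <- scene$params
  if (is.null(noise_sigma_mm)) noise_sigma_mm <- p$depth_sigma_mm
  if (is.null(noise_seed)) {
    noise_seed <- (scene$seed * 997L + as.integer(round(gamma_table_deg)) %%
                     360L) %% .Machine$integer.max
  }
  pose <- scene$pose
  R <- pose$R %*% rotation_y_rh(gamma_table_deg)
  xyz_cam <- sweep(scene$xyz %*% t(R), 2, -pose$t)
  K <- scene$intrinsics
  h <- p$image_height; w <- p$image_width
  z <- xyz_cam[, 3]
  i <- round(K$cx + xyz_cam[, 1] * K$fx / z)
  j <- round(K$cy - xyz_cam[, 2] * K$fy / z)
  ok <- which(z > 0 & i >= 0 & i < w & j >= 0 & j < h)
  ## z-buffer with footprint averaging: the nearest surface wins each
  ## pixel, and its depth is the mean over that surface's samples inside
  ## the pixel (within 3 mm of the minimum), emulating how a time-of-flight
  ## pixel integrates over its footprint rather than taking the nearest
  ## sample (which would bias every point toward the footprint's near edge)
  dt <- data.table::data.table(pix = j[ok] * w + i[ok], z = z[ok], id = ok)
  data.table::setorder(dt, pix, z)
  agg <- dt[, {
    gate <- z <= z[1] + 0.003
    zm <- mean(z[gate])
    ## attribute the pixel to the surface sample nearest the footprint
    ## mean, not the nearest-in-depth sample, which would shift the
    ## apparent surface boundary by half a footprint
    list(zmean = zm, id = id[gate][which.min(abs(z[gate] - zm))])
  }, by = "pix"]
  depth <- matrix(0, h, w)
  win <- matrix(NA_integer_, h, w)
  idx <- cbind(agg$pix %/% w + 1L, agg$pix %% w + 1L)
  depth[idx] <- agg$zmean * 1000
  win[idx] <- agg$id
  valid <- which(depth > 0)
  if (noise_sigma_mm > 0) {
    noise <- with_seed(noise_seed,
                       rnorm(length(valid), 0, noise_sigma_mm))
    depth[valid] <- depth[valid] + noise
  }
  depth[valid] <- pmax(round(depth[valid]), 0)
  ## RGB on the depth grid; background is the white imaging-room wall
  rgb <- array(235 / 255, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[valid] <- scene$rgb[win[valid], ch] / 255
    rgb[, , ch] <- plane
  }
  ## reflectance planes on the depth grid, then onto the spectral grid
  t_inv <- invert_transform2d(scene$reg_transform)
  planes <- lapply(seq_len(5), function(b) {
    pl <- matrix(p$wall_reflectance, h, w)
    pl[valid] <- scene$reflectance[win[valid], b]
    warp_similarity(pl, t_inv, out_shape = c(h, w), fill = NA_real_)
  })
  names(planes) <- names(default_bands())
  cube <- suppressWarnings(spectral_cube(planes))
  list(rgb = rgb, depth = depth, cube = cube, point_id = win)
}

#' Write a rendered view to disk
#'
#' Writes \code{rgb.png} (8-bit), \code{depth.png} (16-bit, millimeters)
#' and \code{cube.tiff} (+ band-list JSON) into a directory.
#'
#' @param view a \code{\link{render_view}} result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_view <- function(view, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(view$rgb, file.path(dir, "rgb.png"))
  write_depth_png(view$depth, file.path(dir, "depth.png"))
  write_cube_tiff(view$cube, file.path(dir, "cube.tiff"))
  invisible(dir)
}

#' Read a view directory written by \code{\link{write_view}}
#'
#' @param dir directory with \code{rgb.png}, \code{depth.png},
#'   \code{cube.tiff}.
#' @return list with \code{rgb}, \code{depth}, \code{cube}.
#' @export
read_view <- function(dir) {
  list(rgb = png::readPNG(file.path(dir, "rgb.png")),
       depth = read_depth_png(file.path(dir, "depth.png")),
       cube = read_cube_tiff(file.path(dir, "cube.tiff")))
}
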