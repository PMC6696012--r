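# Depth unprojection, frame transforms, cropping, outlier removal,
# downsampling and PLY round-trips.

test_that("unprojection evaluates the pinhole model", {
  K <- camera_intrinsics(cx = 10, cy = 8, fx = 50, fy = 40)
  depth <- matrix(0, 20, 24)
  depth[9, 11] <- 1500    # pixel (i=10, j=8): the principal-point ray
  cl <- unproject(depth, K)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$x, cl$y, cl$z), c(0, 0, 1.5))

  depth2 <- matrix(0, 60, 70)
  K2 <- camera_intrinsics(cx = 10, cy = 8, fx = 50, fy = 40)
  depth2[9, 61] <- 1000   # i = cx + fx
  depth2[49, 11] <- 1000  # j = cy + fy
  cl2 <- unproject(depth2, K2)
  cl2 <- cl2[order(cl2$pixel_i), ]
  expect_equal(c(cl2$x[2], cl2$y[2], cl2$z[2]), c(1, 0, 1))
  expect_equal(c(cl2$x[1], cl2$y[1], cl2$z[1]), c(0, -1, 1))

  expect_equal(nrow(unproject(matrix(0, 10, 10), K)), 0L)
  # depths outside the sensor range are invalid
  expect_equal(nrow(unproject(matrix(100, 4, 4), K)), 0L)
})

test_that("projection inverts unprojection exactly for valid pixels", {
  K <- camera_intrinsics(cx = 112, cy = 100, fx = 300, fy = 300)
  set.seed(5)
  depth <- matrix(0, 50, 60)
  pix <- cbind(sample(50, 30), sample(60, 30))
  depth[pix] <- sample(600:3000, 30)
  cl <- unproject(depth, K)
  back <- project_points(cl, K)
  expect_equal(back$i, cl$pixel_i, tolerance = 1e-12)
  expect_equal(back$j, cl$pixel_j, tolerance = 1e-12)
  expect_equal(back$depth_mm, depth[cbind(cl$pixel_j + 1, cl$pixel_i + 1)],
               tolerance = 1e-12)
})

test_that("common-frame mapping sends the axis normal to +Y and is rigid", {
  # identity case
  cal <- ms3d:::new_rotary_calibration(c(0, 0, 0), c(0, 1, 0), 0)
  cl <- spectral_point_cloud(matrix(rnorm(30), 10, 3))
  out <- to_common_frame(cl, cal, gamma_deg = 0)
  expect_equal(cloud_xyz(out), cloud_xyz(cl), tolerance = 1e-12)

  # per-view Y rotation: gamma = 90 maps (1,0,0) to (0,0,1)
  one <- spectral_point_cloud(cbind(1, 0, 0))
  rot <- to_common_frame(one, cal, gamma_deg = 90)
  expect_equal(cloud_xyz(rot)[1, ], c(0, 0, 1), tolerance = 1e-12)

  set.seed(33)
  for (k in 1:50) {
    n <- random_unit_normal()
    ctr <- rnorm(3, sd = 0.5)
    calk <- ms3d:::new_rotary_calibration(ctr, n, 0)
    tip <- spectral_point_cloud(rbind(ctr + n, ctr))
    out <- to_common_frame(tip, calk, gamma_deg = 0)
    expect_equal(cloud_xyz(out)[1, ] - cloud_xyz(out)[2, ], c(0, 1, 0),
                 tolerance = 1e-9)
    expect_equal(cloud_xyz(out)[2, ], c(0, 0, 0), tolerance = 1e-12)

    pts <- spectral_point_cloud(matrix(rnorm(60, sd = 0.3), 20, 3))
    outp <- to_common_frame(pts, calk, gamma_deg = runif(1, -180, 180))
    expect_equal(as.numeric(dist(cloud_xyz(outp))),
                 as.numeric(dist(cloud_xyz(pts))), tolerance = 1e-9)
  }

  # axis along camera X is degenerate
  calx <- ms3d:::new_rotary_calibration(c(0, 0, 0), c(1, 0, 0), 0)
  expect_error(to_common_frame(cl, calx, 0), "degenerate")
})

test_that("crop_roi keeps exactly the points inside the box", {
  set.seed(7)
  cl <- spectral_point_cloud(matrix(runif(3000), 1000, 3))
  all_box <- list(xmin = -1, xmax = 2, ymin = -1, ymax = 2, zmin = -1, zmax = 2)
  expect_equal(nrow(crop_roi(cl, all_box)), 1000L)
  none <- list(xmin = 5, xmax = 6, ymin = 5, ymax = 6, zmin = 5, zmax = 6)
  expect_equal(nrow(crop_roi(cl, none)), 0L)
  half <- list(xmin = 0, xmax = 0.5, ymin = -1, ymax = 2, zmin = -1, zmax = 2)
  n_half <- nrow(crop_roi(cl, half))
  # binomial(1000, 0.5) 99% band
  expect_gt(n_half, 500 - 2.58 * sqrt(250))
  expect_lt(n_half, 500 + 2.58 * sqrt(250))
})

test_that("extract_canopy applies the height cut exactly", {
  lower <- matrix(c(runif(40, -0.1, 0.0)), 40)
  upper <- matrix(c(runif(60, 0.2, 0.4)), 60)
  xyz <- rbind(cbind(0, lower, 0), cbind(0, upper, 0))
  cl <- spectral_point_cloud(xyz)
  expect_equal(nrow(extract_canopy(cl, -1)), 100L)
  expect_equal(nrow(extract_canopy(cl, 0.1)), 60L)
})

test_that("statistical outlier removal discards displaced points", {
  set.seed(11)
  cluster <- matrix(rnorm(900, sd = 0.01), 300, 3)
  displaced <- c(0.5, 0.5, 0.5)  # ~10x the cluster diameter away
  cl <- spectral_point_cloud(rbind(cluster, displaced))
  out <- remove_outliers(cl, k_neighbors = 20, std_ratio = 2)
  expect_equal(nrow(out), 300L)
  expect_lt(max(abs(cloud_xyz(out))), 0.1)

  # a regular grid loses nothing when every point's k nearest neighbors
  # sit at the lattice spacing (k = 3: identical distances, zero spread)
  g <- as.matrix(expand.grid(x = 1:6, y = 1:6, z = 1:6)) * 1.0
  grid_cl <- spectral_point_cloud(g)
  expect_equal(nrow(remove_outliers(grid_cl, 3, 1.0)), nrow(grid_cl))

  expect_error(remove_outliers(spectral_point_cloud(cluster[1:5, ]), 20),
               "k_neighbors")
})

test_that("labeled far outliers are removed and inliers kept", {
  set.seed(13)
  inl <- matrix(rnorm(3 * 800, sd = 0.02), 800, 3)
  out_pts <- matrix(runif(3 * 40, 0.5, 1.0), 40, 3)
  cl <- spectral_point_cloud(rbind(inl, out_pts),
                             view_id = rep(c(0L, 1L), c(800, 40)))
  res <- remove_outliers(cl, k_neighbors = 20, std_ratio = 2)
  kept_outliers <- sum(res$view_id == 1L)
  removed_inliers <- 800 - sum(res$view_id == 0L)
  expect_lte(kept_outliers, 2)       # >= 95% of injected outliers removed
  expect_lte(removed_inliers, 8)     # <= 1% of inliers removed
})

test_that("voxel downsampling averages attributes and votes view ids", {
  xyz <- rbind(c(0.0101, 0, 0), c(0.0109, 0, 0),   # same 2 mm voxel
               c(0.05, 0, 0))
  cl <- spectral_point_cloud(xyz, rgb = cbind(c(10, 20, 30), 0, 0),
                             rho_nir = c(0.2, NA, 0.6),
                             view_id = c(1L, 1L, 2L))
  ds <- voxel_downsample(cl, voxel = 0.002)
  ds <- ds[order(ds$x), ]
  expect_equal(nrow(ds), 2L)
  expect_equal(ds$x[1], 0.0105)
  expect_equal(ds$red[1], 15)
  expect_equal(ds$rho_nir, c(0.2, 0.6))  # NA-aware mean
  expect_identical(ds$view_id, c(1L, 2L))
})

test_that("PLY round-trips binary and ascii with NA reflectance", {
  set.seed(17)
  cl <- spectral_point_cloud(matrix(rnorm(60), 20, 3),
                             rgb = matrix(sample(0:255, 60, TRUE), 20, 3),
                             rho_nir = c(runif(19), NA),
                             view_id = sample(0:3, 20, TRUE))
  for (binary in c(TRUE, FALSE)) {
    path <- tempfile(fileext = ".ply")
    write_ply(cl, path, binary = binary)
    back <- read_ply(path)
    expect_s3_class(back, "spectral_point_cloud")
    expect_equal(cloud_xyz(back), cloud_xyz(cl), tolerance = 1e-6)
    expect_equal(back$red, cl$red)
    expect_equal(back$rho_nir, cl$rho_nir, tolerance = 1e-6)
    expect_identical(back$view_id, cl$view_id)
    expect_true(is.na(back$rho_nir[20]))
  }
})
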