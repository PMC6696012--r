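# Synthetic scene generator: determinism, ground truth, rendering.

test_that("scenes are reproducible from (params, seed)", {
  s1 <- make_scene(seed = 9)
  s2 <- make_scene(seed = 9)
  expect_identical(s1$xyz, s2$xyz)
  expect_identical(s1$reflectance, s2$reflectance)
  expect_identical(s1$spad, s2$spad)
  s3 <- make_scene(seed = 10)
  expect_false(identical(s1$xyz, s3$xyz))
})

test_that("a zero-leaf scene contains only stem, pot, table and stickers", {
  s <- make_scene(list(n_leaves = 0L), seed = 2)
  expect_false("leaf" %in% s$labels)
  expect_setequal(unique(s$labels),
                  c("table", "sticker_yellow", "sticker_red", "pot", "stem"))
})

test_that("generated reflectance is consistent with the generating SPAD model", {
  s <- fixture_scene()
  plant <- s$labels %in% c("leaf", "stem")
  cig <- s$reflectance[plant, "rho_nir"] / s$reflectance[plant, "rho_green"] - 1
  gen <- spad_paper_model(s$params$spad_model_index)
  spad_implied <- spad_predict(gen, cig)
  # errors come only from the injected band noise (sigma = 0.01 on green
  # reflectance of ~0.1-0.2 propagates to a few SPAD units per point)
  expect_gt(cor(spad_implied, s$spad[plant]), 0.8)
  expect_lt(median(abs(spad_implied - s$spad[plant])), 5)
})

test_that("labels partition the scene and ground truth echoes the inputs", {
  s <- fixture_scene()
  gt <- ground_truth(s)
  expect_equal(gt$axis$center, s$params$axis_center_cam)
  expect_equal(sqrt(sum(gt$axis$normal^2)), 1, tolerance = 1e-12)
  expect_identical(gt$labels, s$labels)
  expect_equal(sort(unique(s$labels)),
               sort(c("table", "sticker_yellow", "sticker_red", "pot",
                      "stem", "leaf")))

  # per-view rigid transform at 90 degrees: pose composed with the
  # right-handed table rotation
  T90 <- gt$view_rigid(90)
  p <- c(0.05, 0.01, -0.02)
  ryh <- t(rotation_y(90))
  expect_equal(as.numeric(T90 %*% c(p, 1))[1:3],
               as.numeric(s$pose$R %*% (ryh %*% p) + s$pose$t),
               tolerance = 1e-12)
})

test_that("rendering is deterministic and the seed changes only the noise", {
  s <- fixture_scene()
  v1 <- render_view(s, 90)
  v2 <- render_view(s, 90)
  expect_identical(v1$depth, v2$depth)
  expect_identical(v1$rgb, v2$rgb)
  # 0 vs 360 degrees: same geometry, same noise seed
  expect_identical(render_view(s, 0)$depth, render_view(s, 360)$depth)
  # different noise seed: same winners, different depth values
  v3 <- render_view(s, 90, noise_seed = 123456)
  expect_identical(v1$point_id, v3$point_id)
  expect_false(identical(v1$depth, v3$depth))
  expect_identical(v1$rgb, v3$rgb)
})

test_that("projection of a known point matches the closed-form pinhole model", {
  s <- fixture_scene()
  v <- render_view(s, 0, noise_sigma_mm = 0)
  K <- s$intrinsics
  # take scene points that won a pixel and verify the projection equations
  valid <- which(!is.na(v$point_id))[1:50]
  ids <- v$point_id[valid]
  cam <- sweep(s$xyz[ids, , drop = FALSE] %*% t(s$pose$R), 2, -s$pose$t)
  i_exp <- round(K$cx + cam[, 1] * K$fx / cam[, 3])
  j_exp <- round(K$cy - cam[, 2] * K$fy / cam[, 3])
  expect_equal(j_exp + 1 + (i_exp) * nrow(v$depth), valid)
  # pixel depth is the footprint average of the winning surface: within
  # the 3 mm surface gate of the winner's own depth
  expect_lt(max(abs(v$depth[valid] - cam[, 3] * 1000)), 3.5)
})

test_that("the z-buffer keeps the nearest surface per pixel", {
  s <- make_scene(list(table_points = 1500L, leaf_points = 300L), seed = 4)
  v <- render_view(s, 0, noise_sigma_mm = 0)
  K <- s$intrinsics
  cam <- sweep(s$xyz %*% t(s$pose$R), 2, -s$pose$t)
  i <- round(K$cx + cam[, 1] * K$fx / cam[, 3])
  j <- round(K$cy - cam[, 2] * K$fy / cam[, 3])
  h <- nrow(v$depth); w <- ncol(v$depth)
  ok <- cam[, 3] > 0 & i >= 0 & i < w & j >= 0 & j < h
  # brute-force per-pixel minimum depth
  key <- (j[ok]) * w + i[ok]
  zz <- cam[ok, 3]
  zref <- tapply(seq_along(key), key, function(sel) {
    zmin <- min(zz[sel])
    mean(zz[sel][zz[sel] <= zmin + 0.003])  # footprint mean of near surface
  })
  set.seed(61)
  sel <- sample(length(zref), 300)
  for (s_idx in sel) {
    kk <- as.integer(names(zref)[s_idx])
    jj <- kk %/% w; ii <- kk %% w
    expect_equal(v$depth[jj + 1, ii + 1], round(zref[[s_idx]] * 1000))
  }
})

test_that("occluded rear surfaces are absent from the depth image", {
  s <- fixture_scene()
  v <- render_view(s, 0, noise_sigma_mm = 0)
  cam <- sweep(s$xyz %*% t(s$pose$R), 2, -s$pose$t)
  ids <- v$point_id[!is.na(v$point_id)]
  # every winner must belong to the nearest surface on its pixel: within
  # the 3 mm footprint gate of the minimum candidate depth, so occluded
  # rear surfaces (e.g. the stem behind a leaf) can never win
  K <- s$intrinsics
  i <- round(K$cx + cam[, 1] * K$fx / cam[, 3])
  j <- round(K$cy - cam[, 2] * K$fy / cam[, 3])
  key <- j * ncol(v$depth) + i
  zmin_by_key <- tapply(cam[, 3], key, min)
  winner_keys <- as.character(j[ids] * ncol(v$depth) + i[ids])
  expect_true(all(cam[ids, 3] - zmin_by_key[winner_keys] < 0.003 + 1e-12))
})

test_that("view IO round-trips through PNG and TIFF", {
  s <- fixture_scene()
  v <- fixture_views()[[2]]
  dir <- tempfile()
  write_view(v, dir)
  back <- read_view(dir)
  expect_equal(back$depth, v$depth)
  expect_equal(back$rgb, v$rgb, tolerance = 1 / 255)
  expect_equal(back$cube$planes$Nir, v$cube$planes$Nir, tolerance = 1e-6)
})
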