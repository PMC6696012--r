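# Fourier registration: phase correlation, log-polar rotation/scale, full
# similarity estimation and warping.

test_that("phase correlation recovers the identity and circular shifts", {
  a <- smooth_texture(seed = 7)
  pc <- phase_correlation(a, a)
  expect_lt(abs(pc$dx), 0.05)
  expect_lt(abs(pc$dy), 0.05)
  expect_gt(pc$peak_response, 0.3)

  b <- circular_shift(a, 5, -3)
  pc <- phase_correlation(a, b)
  expect_identical(c(round(pc$dx), round(pc$dy)), c(5, -3))
  # without windowing the circular shift gives an exact impulse
  pc0 <- phase_correlation(a, b, window = FALSE)
  expect_equal(c(pc0$dx, pc0$dy), c(5, -3), tolerance = 1e-9)
  expect_gt(pc0$peak_response, 0.3)  # band-limited texture: peak mass = spectral support
})

test_that("integer-shift estimates match the brute-force cross-correlation argmax", {
  a <- smooth_texture(n = 32, cutoff = 0.4, seed = 3)
  am <- a - mean(a)
  set.seed(41)
  for (k in 1:6) {
    s <- sample(-12:12, 2)
    b <- circular_shift(a, s[1], s[2])
    # exhaustive spatial-domain circular cross-correlation
    best <- c(NA, NA); bv <- -Inf
    bm <- b - mean(b)
    for (dx in -15:16) for (dy in -15:16) {
      v <- sum(am * circular_shift(bm, -dx, -dy))
      if (v > bv) { bv <- v; best <- c(dx, dy) }
    }
    expect_identical(best, s)
    pc <- phase_correlation(a, b, window = FALSE)
    expect_equal(c(pc$dx, pc$dy), best, tolerance = 1e-9)
  }
})

test_that("sub-pixel translation is recovered within half a pixel", {
  a <- smooth_texture(seed = 11)
  t0 <- transform2d(12.25, 4.5, 0, 1)
  b <- make_moving(a, t0)
  pc <- phase_correlation(a, b)
  est <- c(-pc$dx, -pc$dy)  # alignment translation is minus the shift
  expect_lt(abs(est[1] - 12.25), 0.5)
  expect_lt(abs(est[2] - 4.5), 0.5)
  # oracle: normalized cross-correlation over a fine local grid of shifts
  wnd <- hann_window(128, 128)
  aw <- (a - mean(a)) * wnd
  ncc <- function(dx, dy) {
    bw <- warp_similarity(b, transform2d(dx, dy, 0, 1), fill = 0)
    bw <- (bw - mean(bw)) * wnd
    sum(aw * bw) / sqrt(sum(aw^2) * sum(bw^2))
  }
  grid <- expand.grid(dx = seq(11, 13.5, 0.25), dy = seq(3.5, 5.5, 0.25))
  vals <- mapply(ncc, grid$dx, grid$dy)
  oracle <- unlist(grid[which.max(vals), ])
  expect_lt(abs(est[1] - oracle[["dx"]]), 0.5)
  expect_lt(abs(est[2] - oracle[["dy"]]), 0.5)
})

test_that("degenerate and mismatched inputs are rejected", {
  a <- smooth_texture(seed = 1)
  expect_error(phase_correlation(a, matrix(0.5, 128, 128)), "degenerate")
  expect_error(phase_correlation(a, a[1:64, ]), "shapes")
  expect_error(logpolar_magnitude(a, n_rho = 16), ">= 32")
  # gratings whose period ratio implies a scale of 5 (impulse magnitude
  # spectra make the log-radius shift unambiguous)
  g <- outer(seq_len(128), seq_len(128), function(y, x) cos(2 * pi * x / 4))
  g5 <- outer(seq_len(128), seq_len(128), function(y, x) cos(2 * pi * x / 20))
  expect_error(estimate_rotation_scale(g, g5), "outside")
})

test_that("log-polar spectrum turns rotation and scale into axis shifts", {
  a <- smooth_texture(seed = 13)
  lpa <- logpolar_magnitude(a)
  # identity: identical spectra
  lpa2 <- logpolar_magnitude(a)
  expect_equal(lpa$values, lpa2$values)

  rot <- make_moving(a, transform2d(0, 0, 30, 1))
  lpr <- logpolar_magnitude(rot)
  pc <- phase_correlation(lpa$values, lpr$values, window = FALSE)
  theta_bins <- -pc$dx
  expect_lt(abs(theta_bins * 180 / lpa$n_theta - 30), 180 / lpa$n_theta)

  sc <- make_moving(a, transform2d(0, 0, 0, 1.2))
  lps <- logpolar_magnitude(sc)
  pcs <- phase_correlation(lpa$values, lps$values, window = FALSE)
  expect_lt(abs(pcs$dy - log(1.2) / log(lpa$rho_base)), 1)
})

test_that("rotation and scale are estimated within tolerance", {
  a <- smooth_texture(seed = 17)
  expect_equal(estimate_rotation_scale(a, a)$theta0, 0, tolerance = 0.2)
  expect_equal(estimate_rotation_scale(a, a)$sigma, 1, tolerance = 0.005)

  rot <- make_moving(a, transform2d(0, 0, 25, 1))
  rs <- estimate_rotation_scale(a, rot)
  expect_lt(abs(rs$theta0 - 25), 1)
  # oracle: grid search over rotation maximizing NCC after de-rotation
  wnd <- hann_window(128, 128)
  aw <- (a - mean(a)) * wnd
  ncc_at <- function(th) {
    bw <- warp_similarity(rot, transform2d(0, 0, th, 1), fill = 0)
    bw <- (bw - mean(bw)) * wnd
    sum(aw * bw) / sqrt(sum(aw^2) * sum(bw^2))
  }
  grid <- seq(20, 30, 0.25)
  oracle <- grid[which.max(vapply(grid, ncc_at, 0))]
  expect_lt(abs(rs$theta0 - oracle), 1)

  sc <- make_moving(a, transform2d(0, 0, 0, 1.25))
  rs2 <- estimate_rotation_scale(a, sc)
  expect_lt(abs(rs2$sigma / 1.25 - 1), 0.03)
  ncc_sc <- function(s) {
    bw <- warp_similarity(sc, transform2d(0, 0, 0, s), fill = 0)
    bw <- (bw - mean(bw)) * wnd
    sum(aw * bw) / sqrt(sum(aw^2) * sum(bw^2))
  }
  sgrid <- seq(1.1, 1.4, 0.01)
  soracle <- sgrid[which.max(vapply(sgrid, ncc_sc, 0))]
  expect_lt(abs(rs2$sigma / soracle - 1), 0.03)
})

test_that("full similarity estimation recovers a known transform", {
  a <- smooth_texture(seed = 19)
  est0 <- estimate_similarity(a, a)
  expect_equal(c(est0$dx, est0$dy, est0$theta0), c(0, 0, 0), tolerance = 0.1)
  expect_equal(est0$sigma, 1, tolerance = 0.005)

  tt <- transform2d(10, -6, 15, 1.1)
  b <- make_moving(a, tt)
  est <- estimate_similarity(a, b)
  expect_lt(abs(est$dx - 10), 0.5)
  expect_lt(abs(est$dy - -6), 0.5)
  expect_lt(abs(est$theta0 - 15), 1)
  expect_lt(abs(est$sigma / 1.1 - 1), 0.03)
})

test_that("plant-silhouette views register like the textures", {
  scene <- fixture_scene()
  v <- fixture_views()[[1]]
  ga <- (v$rgb[, , 1] + v$rgb[, , 2] + v$rgb[, , 3]) / 3
  gb <- v$cube$planes$Nir
  gb[is.na(gb)] <- 0
  est <- estimate_similarity(ga, gb)
  tt <- ground_truth(scene)$similarity
  expect_lt(abs(est$dx - tt$dx), 0.5)
  expect_lt(abs(est$dy - tt$dy), 0.5)
  expect_lt(abs(est$theta0 - tt$theta0), 1)
  expect_lt(abs(est$sigma / tt$sigma - 1), 0.03)
  # registered band covers most of the depth grid (differences confined to
  # the unmapped margins)
  reg <- warp_similarity(gb, est, out_shape = dim(ga), fill = NA)
  expect_gt(mean(!is.na(reg)), 0.65)  # sigma < 1: the moving grid covers ~sigma^2 of the reference
})

test_that("warp_similarity honors identity, fill and inversion", {
  a <- smooth_texture(seed = 23, cutoff = 0.08)
  expect_equal(warp_similarity(a, transform2d()), a, tolerance = 1e-12)
  # constant image stays constant wherever defined
  const <- matrix(0.7, 64, 64)
  w <- warp_similarity(const, transform2d(3, -2, 10, 1.05), fill = NA)
  expect_true(all(w[!is.na(w)] == 0.7))
  # round trip on a smooth texture reproduces interior pixels
  tt <- transform2d(4.5, -3.25, 12, 1.08)
  w1 <- warp_similarity(a, tt, fill = NA)
  w2 <- warp_similarity(w1, invert_transform2d(tt), fill = NA)
  interior <- 33:96
  err <- abs(w2[interior, interior] - a[interior, interior])
  expect_lt(max(err, na.rm = TRUE), 0.02)   # double bilinear resampling
  expect_lt(mean(err, na.rm = TRUE), 0.005)
})

test_that("transform inversion and serialization round-trip", {
  tt <- transform2d(7.5, -2.25, 18, 1.15, peak_response = 0.5)
  ti <- invert_transform2d(tt)
  xy <- cbind(runif(20, 0, 127), runif(20, 0, 127))
  fwd <- apply_transform2d(tt, xy, c(128, 128))
  back <- apply_transform2d(ti, fwd, c(128, 128))
  expect_lt(max(abs(back - xy)), 1e-6)

  path <- tempfile(fileext = ".json")
  write_transform2d(tt, path)
  t2 <- read_transform2d(path)
  expect_equal(t2[c("dx", "dy", "theta0", "sigma")],
               tt[c("dx", "dy", "theta0", "sigma")])
})
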