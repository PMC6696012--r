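# Shared fixtures: band-limited random textures for registration tests,
# a cached default synthetic scene, and small geometry helpers.

smooth_texture <- function(n = 128, cutoff = 0.35, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n, n)
  F <- fft(z)
  f <- (seq_len(n) - 1) / n
  f[f > 0.5] <- f[f > 0.5] - 1
  mask <- outer(f^2, f^2, "+") < cutoff^2
  img <- Re(fft(F * mask, inverse = TRUE)) / (n * n)
  (img - min(img)) / diff(range(img))
}

## moving image produced by applying the inverse of t to the reference,
## so that estimate_similarity(ref, mov) should recover t
make_moving <- function(ref, t) {
  warp_similarity(ref, invert_transform2d(t), fill = 0)
}

circular_shift <- function(img, dx, dy) {
  n <- nrow(img); m <- ncol(img)
  img[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(m) - 1 - dx) %% m) + 1]
}

angle_between_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

## RMS of distance-gated nearest-neighbor distances from a to b
gated_rms <- function(a, b, gate = 0.01) {
  nn <- ms3d:::cpp_nn1(a, b, gate)
  keep <- nn$idx > 0
  list(rms = sqrt(mean(nn$dist[keep]^2)), frac = mean(keep))
}

cloud_xyz <- function(cloud) cbind(cloud$x, cloud$y, cloud$z)

## one default scene plus its four rendered views, built once per session
.fixture_cache <- new.env(parent = emptyenv())
fixture_scene <- function() {
  if (is.null(.fixture_cache$scene)) {
    .fixture_cache$scene <- make_scene(seed = 5)
  }
  .fixture_cache$scene
}
fixture_views <- function() {
  if (is.null(.fixture_cache$views)) {
    scene <- fixture_scene()
    .fixture_cache$views <- lapply(0:3, function(k) {
      render_view(scene, k * 90)
    })
  }
  .fixture_cache$views
}
fixture_pipeline <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    .fixture_cache$pipeline <- run_pipeline(fixture_views())
  }
  .fixture_cache$pipeline
}

random_unit_normal <- function() {
  repeat {
    v <- rnorm(3)
    s <- sqrt(sum(v^2))
    if (s > 1e-3 && sqrt(v[2]^2 + v[3]^2) / s > 1e-3) return(v / s)
  }
}
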