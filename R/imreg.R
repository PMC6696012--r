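## Fourier-based registration of the reflectance imager's view onto the
## depth camera's view. Translation comes from phase correlation of the
## windowed images; rotation and scale come from phase correlation of the
## log-polar resampled Fourier magnitudes (Fourier-Mellin), which turns a
## rotation into a shift along the angle axis and a scaling into a shift
## along the log-radius axis.

EPS_CROSS_POWER <- 1e-12

## Integer-bin peak location plus 3x3-neighborhood parabolic refinement
## along each axis, with circular wrap.
peak_subpixel <- function(r) {
  idx <- which.max(r)
  h <- nrow(r); w <- ncol(r)
  r0 <- (idx - 1) %% h + 1
  c0 <- (idx - 1) %/% h + 1
  wrap <- function(i, n) (i - 1) %% n + 1
  para <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (abs(den) < 1e-15) 0 else {
      d <- 0.5 * (vm - vp) / den
      max(min(d, 0.5), -0.5)
    }
  }
  dy <- para(r[wrap(r0 - 1, h), c0], r[r0, c0], r[wrap(r0 + 1, h), c0])
  dx <- para(r[r0, wrap(c0 - 1, w)], r[r0, c0], r[r0, wrap(c0 + 1, w)])
  ## convert 1-based bin to signed circular shift
  sy <- (r0 - 1) + dy; if (sy > h / 2) sy <- sy - h
  sx <- (c0 - 1) + dx; if (sx > w / 2) sx <- sx - w
  list(sx = sx, sy = sy, peak = r[r0, c0])
}

#' Translation estimation by phase correlation
#'
#' Computes the normalized cross-power spectrum of the two images and takes
#' the inverse FFT, which is an impulse at the translation between them.
#' The integer peak is refined by 3x3 parabolic interpolation.
#'
#' @param img_a reference image (numeric matrix).
#' @param img_b moving image, same shape; for a pure circular shift
#'   \code{img_b[y, x] = img_a[y - dy, x - dx]}.
#' @param window apply a Hann window before the FFTs (default TRUE). Disable
#'   only for strictly circular content.
#' @param subpixel apply parabolic sub-pixel refinement (default TRUE).
#' @return list with \code{dx}, \code{dy} (pixels, shift of \code{img_b}
#'   relative to \code{img_a}) and \code{peak_response} in \code{[0, 1]}.
#' @export
phase_correlation <- function(img_a, img_b, window = TRUE, subpixel = TRUE) {
  check_image2d(img_a, 8L, "img_a")
  check_image2d(img_b, 8L, "img_b")
  if (!all(dim(img_a) == dim(img_b))) {
    stop("images must have identical shapes", call. = FALSE)
  }
  if (!all(is.finite(img_a)) || !all(is.finite(img_b))) {
    stop("images must be finite", call. = FALSE)
  }
  if (sd(img_a) == 0 || sd(img_b) == 0) {
    stop("degenerate input: constant image has a zero spectrum", call. = FALSE)
  }
  if (window) {
    wnd <- hann_window(nrow(img_a), ncol(img_a))
    img_a <- (img_a - mean(img_a)) * wnd
    img_b <- (img_b - mean(img_b)) * wnd
  }
  fa <- fft(img_a)
  fb <- fft(img_b)
  cp <- fb * Conj(fa)
  cp <- cp / (Mod(cp) + EPS_CROSS_POWER)
  r <- Re(fft(cp, inverse = TRUE)) / length(cp)
  pk <- peak_subpixel(r)
  if (!subpixel) {
    pk$sx <- round(pk$sx); pk$sy <- round(pk$sy)
  }
  list(dx = pk$sx, dy = pk$sy,
       peak_response = min(max(pk$peak, 0), 1))
}

## Reddy-Chatterji style high-pass emphasis on the centered magnitude
## spectrum; suppresses the DC-dominated low frequencies before log-polar
## resampling.
highpass_emphasis <- function(h, w) {
  fy <- (seq_len(h) - 1 - floor(h / 2)) / h
  fx <- (seq_len(w) - 1 - floor(w / 2)) / w
  X <- outer(cos(pi * fy), cos(pi * fx))
  (1 - X) * (2 - X)
}

#' Log-polar resampling of the Fourier magnitude
#'
#' Returns the centered, high-pass-filtered magnitude spectrum sampled on a
#' log-radius x angle grid. A rotation of the input image circularly shifts
#' the angle axis; a scaling shifts the log-radius axis by log(sigma).
#'
#' @param img numeric matrix.
#' @param n_rho,n_theta number of log-radius / angle bins (>= 32).
#' @param window apply a Hann window before the FFT.
#' @return object of class \code{logpolar_spectrum}: list with
#'   \code{values} (\code{n_rho x n_theta} matrix, rows = log rho, columns =
#'   theta over \code{[0, 180)} degrees), \code{rho_base} (radius ratio per
#'   bin), \code{n_rho}, \code{n_theta}, \code{theta_span_deg}.
#' @export
logpolar_magnitude <- function(img, n_rho = 128L, n_theta = 180L,
                               window = TRUE) {
  check_image2d(img, 8L)
  if (n_rho < 32L || n_theta < 32L) {
    stop("n_rho and n_theta must be >= 32", call. = FALSE)
  }
  h <- nrow(img); w <- ncol(img)
  if (window) img <- (img - mean(img)) * hann_window(h, w)
  mag <- fftshift2(Mod(fft(img))) * highpass_emphasis(h, w)
  cy <- floor(h / 2); cx <- floor(w / 2)  # DC bin, 0-based
  rho_min <- 2
  rho_max <- min(h, w) / 2 - 1
  rho_base <- (rho_max / rho_min)^(1 / (n_rho - 1))
  rho <- rho_min * rho_base^(seq_len(n_rho) - 1)
  theta <- (seq_len(n_theta) - 1) * pi / n_theta  # [0, 180) degrees
  sx <- outer(rho, cos(theta)) + cx
  sy <- outer(rho, sin(theta)) + cy
  vals <- matrix(interp_bilinear(mag, as.numeric(sx), as.numeric(sy),
                                 fill = 0),
                 n_rho, n_theta)
  structure(
    list(values = vals, rho_base = rho_base, n_rho = n_rho,
         n_theta = n_theta, theta_span_deg = 180),
    class = "logpolar_spectrum")
}

#' Rotation and scale between two images (Fourier-Mellin)
#'
#' Phase-correlates the log-polar magnitude spectra of the two images. The
#' angle-axis shift gives the rotation angle; the log-radius shift gives the
#' scale. The 180-degree ambiguity of the (point-symmetric) magnitude
#' spectrum is resolved by de-rotating with both candidate angles and
#' keeping the one whose subsequent translation correlation peaks higher.
#'
#' @param img_a reference image.
#' @param img_b moving image, same shape.
#' @param n_rho,n_theta log-polar grid size.
#' @return list with \code{theta0} (degrees, the rotation such that scaling
#'   and rotating \code{img_b} by \code{sigma}, \code{theta0} about its
#'   center aligns it with \code{img_a} up to translation) and \code{sigma}
#'   in \code{[1/4, 4]}.
#' @export
estimate_rotation_scale <- function(img_a, img_b, n_rho = 128L,
                                    n_theta = 180L) {
  if (!all(dim(img_a) == dim(img_b))) {
    stop("images must have identical shapes", call. = FALSE)
  }
  lpa <- logpolar_magnitude(img_a, n_rho, n_theta)
  lpb <- logpolar_magnitude(img_b, n_rho, n_theta)
  ## no extra window: the angle axis is exactly 180-periodic and log-radius
  ## shifts are small
  pc <- phase_correlation(lpa$values, lpb$values, window = FALSE)
  theta0 <- -pc$dx * lpa$theta_span_deg / lpa$n_theta
  sigma <- lpa$rho_base^pc$dy
  if (sigma < 0.25 || sigma > 4) {
    stop("estimated scale ", signif(sigma, 4),
         " outside [1/4, 4]: registration failure", call. = FALSE)
  }
  cand <- resolve_theta_ambiguity(img_a, img_b, theta0, sigma)
  list(theta0 = cand$theta0, sigma = sigma,
       peak_response = cand$peak_response,
       dx = cand$dx, dy = cand$dy)
}

## Try theta0 and theta0 + 180 and keep the angle whose de-rotated image
## gives the stronger translation-correlation peak.
resolve_theta_ambiguity <- function(img_a, img_b, theta0, sigma) {
  best <- NULL
  for (th in c(theta0, theta0 + 180)) {
    th <- ((th + 180) %% 360) - 180
    bw <- warp_similarity(img_b, transform2d(0, 0, th, sigma),
                          out_shape = dim(img_a), fill = 0)
    pc <- phase_correlation(img_a, bw)
    if (is.null(best) || pc$peak_response > best$peak_response) {
      best <- list(theta0 = th, dx = -pc$dx, dy = -pc$dy,
                   peak_response = pc$peak_response)
    }
  }
  best
}

#' Full similarity registration (translation, rotation, scale)
#'
#' Estimates rotation and scale by the Fourier-Mellin method, de-rotates and
#' de-scales the moving image, then estimates the residual translation by
#' phase correlation. The returned transform maps \code{img_b}'s grid onto
#' \code{img_a}'s grid, i.e. \code{warp_similarity(img_b, t)} aligns with
#' \code{img_a}.
#'
#' @param img_a reference image.
#' @param img_b moving image, same shape (pad or resample first otherwise).
#' @param n_rho,n_theta log-polar grid size.
#' @param min_peak_response peak-response floor below which a low-confidence
#'   warning is attached to the result.
#' @return a \code{reg_transform2d}.
#' @export
estimate_similarity <- function(img_a, img_b, n_rho = 128L, n_theta = 180L,
                                min_peak_response = 0.03) {
  rs <- estimate_rotation_scale(img_a, img_b, n_rho, n_theta)
  t <- transform2d(rs$dx, rs$dy, rs$theta0, rs$sigma,
                   peak_response = rs$peak_response)
  if (rs$peak_response < min_peak_response) {
    warning("low-confidence registration: peak response ",
            signif(rs$peak_response, 3), call. = FALSE)
    t$low_confidence <- TRUE
  }
  t
}
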