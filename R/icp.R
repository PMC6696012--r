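## Point-to-point ICP with a distance-gated nearest-neighbor
## correspondence step and the closed-form SVD rigid fit, plus the
## sequential accumulate-and-register multiview fusion.

#' Closed-form rigid fit between corresponding point sets
#'
#' Least-squares rotation + translation (Kabsch/Umeyama, no scale) mapping
#' \code{src} onto \code{dst} via SVD of the cross-covariance.
#'
#' @param src,dst n x 3 matrices of corresponding points (n >= 3).
#' @return 4 x 4 rigid transform matrix.
#' @export
rigid_fit <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3)
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- t(sweep(src, 2, cs)) %*% sweep(dst, 2, cd)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cd - R %*% cs
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

apply_rigid <- function(xyz, T) {
  sweep(xyz %*% t(T[1:3, 1:3]), 2, -T[1:3, 4])
}

#' Transform a cloud by a 4 x 4 rigid matrix
#'
#' @param cloud \code{spectral_point_cloud}.
#' @param T 4 x 4 rigid transform.
#' @return the transformed cloud.
#' @export
transform_cloud <- function(cloud, T) {
  set_xyz(cloud, apply_rigid(as_xyz(cloud), T))
}

#' Iterative closest point registration
#'
#' Point-to-point ICP: alternate distance-gated nearest-neighbor
#' correspondences with the closed-form rigid fit until the correspondence
#' RMS changes by less than \code{tol} or \code{max_iter} is reached.
#'
#' @param source,target \code{spectral_point_cloud}s (or n x 3 matrices);
#'   the returned transform maps \code{source} onto \code{target}.
#' @param max_corr_dist correspondence gate, meters (default 0.01).
#' @param max_iter iteration cap (default 50).
#' @param tol RMS-change convergence threshold, meters (default 1e-6).
#' @return list with \code{transform} (4 x 4), \code{rms} (meters) and
#'   \code{n_corr} (correspondences at convergence).
#' @export
icp <- function(source, target, max_corr_dist = 0.01, max_iter = 50L,
                tol = 1e-6) {
  src <- if (is.matrix(source)) source else as_xyz(source)
  tgt <- if (is.matrix(target)) target else as_xyz(target)
  if (nrow(src) == 0 || nrow(tgt) == 0) {
    stop("ICP requires non-empty clouds", call. = FALSE)
  }
  T <- diag(4)
  cur <- src
  rms_prev <- Inf
  rms <- Inf; n_corr <- 0L
  for (it in seq_len(max_iter)) {
    nn <- cpp_nn1(cur, tgt, max_corr_dist)
    keep <- nn$idx > 0L
    n_corr <- sum(keep)
    if (n_corr == 0L) {
      stop("no overlap: zero ICP correspondences within the gate",
           call. = FALSE)
    }
    if (n_corr < 3L) break
    rms <- sqrt(mean(nn$dist[keep]^2))
    dT <- rigid_fit(cur[keep, , drop = FALSE],
                    tgt[nn$idx[keep], , drop = FALSE])
    T <- dT %*% T
    cur <- apply_rigid(src, T)
    if (abs(rms_prev - rms) < tol) break
    rms_prev <- rms
  }
  nn <- cpp_nn1(cur, tgt, max_corr_dist)
  keep <- nn$idx > 0L
  rms <- sqrt(mean(nn$dist[keep]^2))
  list(transform = T, rms = rms, n_corr = sum(keep))
}

#' Fuse multiview clouds into the 3DROI model
#'
#' Sequential precise registration: the cloud at the first view is
#' ICP-registered with the adjacent second view, the accumulated result
#' with the third, and so on; the concatenation is then voxel-downsampled.
#' All inputs must already be in the common turntable frame (rough
#' registration).
#'
#' @param clouds ordered list of \code{spectral_point_cloud}s (>= 2 views).
#' @param max_corr_dist,max_iter,tol ICP parameters.
#' @param voxel downsampling voxel edge, meters (default 0.002).
#' @return list with \code{cloud} (the fused model), \code{icp_rms}
#'   (per-pair RMS, meters) and \code{view_counts}.
#' @export
fuse_views <- function(clouds, max_corr_dist = 0.01, max_iter = 50L,
                       tol = 1e-6, voxel = 0.002) {
  stopifnot(is.list(clouds), length(clouds) >= 2)
  acc <- clouds[[1]]
  rms <- numeric(0)
  for (k in 2:length(clouds)) {
    fit <- icp(acc, clouds[[k]], max_corr_dist = max_corr_dist,
               max_iter = max_iter, tol = tol)
    acc <- transform_cloud(acc, fit$transform)
    common <- intersect(names(acc), names(clouds[[k]]))
    acc <- rbind(acc[common], clouds[[k]][common])
    class(acc) <- c("spectral_point_cloud", "data.frame")
    rms <- c(rms, fit$rms)
  }
  fused <- voxel_downsample(acc, voxel = voxel)
  list(cloud = fused, icp_rms = rms,
       view_counts = vapply(clouds, nrow, 0L))
}
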