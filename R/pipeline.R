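## End-to-end orchestration: initialize -> calibrate axis -> calibrate
## spectral registration -> per-view unproject/attach/rough-register ->
## ICP fusion -> canopy indices and statistics -> SPAD map.

#' Default pipeline configuration
#'
#' All tunable parameters of the reconstruction pipeline with their
#' defaults. \code{v_n} is the number of equally spaced views (90-degree
#' interval at the default 4); \code{spin_sign} is +1 for a table spinning
#' counter-clockwise seen from above (+Y), -1 otherwise; \code{roi} is the
#' plant bounding box in the common frame (meters); \code{pot_top_height}
#' is the canopy height cut.
#'
#' @return named list of configuration entries.
#' @export
pipeline_config <- function() {
  list(
    intrinsics = list(cx = 112, cy = 100, fx = 300, fy = 300),
    v_n = 4L,
    spin_sign = 1,
    z_range = c(0.5, 4.5),
    roi = list(xmin = -0.15, xmax = 0.15, ymin = -0.02, ymax = 0.45,
               zmin = -0.15, zmax = 0.15),
    outlier = list(k_neighbors = 20L, std_ratio = 2.0),
    icp = list(max_corr_dist = 0.01, max_iter = 50L, tol = 1e-6),
    voxel = 0.002,
    pot_top_height = 0.065,
    registration_band = "Nir",
    spad_index = "CIG",
    min_sticker_inliers = 20L
  )
}

#' Read a pipeline configuration from YAML
#'
#' Entries missing from the file keep their defaults
#' (\code{\link{pipeline_config}}).
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- modifyList(pipeline_config(), yaml::read_yaml(path))
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$v_n < 2) stop("config: v_n must be >= 2", call. = FALSE)
  if (360 %% cfg$v_n != 0) {
    warning("config: 360 is not divisible by v_n = ", cfg$v_n, call. = FALSE)
  }
  if (!cfg$spin_sign %in% c(-1, 1)) {
    stop("config: spin_sign must be +1 or -1", call. = FALSE)
  }
  invisible(cfg)
}

view_gray <- function(view) {
  (view$rgb[, , 1] + view$rgb[, , 2] + view$rgb[, , 3]) / 3
}

cube_gray <- function(cube, band) {
  g <- cube$planes[[band]]
  g[is.na(g)] <- 0
  g
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full reconstruction pipeline
#'
#' Executes all stages on a list of per-view inputs: turntable axis
#' self-calibration from the first view and the view 180 degrees opposite,
#' spectral-to-depth registration on the first view (one transform reused
#' for every band and view), per-view unprojection, reflectance
#' attachment and rough registration into the common frame, ROI crop and
#' outlier removal, sequential ICP fusion with voxel downsampling, canopy
#' extraction, per-point vegetation indices with summary statistics, and a
#' per-point SPAD map from the published calibration.
#'
#' @param views list of length \code{v_n}; each element a list with
#'   \code{rgb} (h x w x 3 array in [0, 1]), \code{depth} (matrix,
#'   millimeters) and \code{cube} (\code{spectral_cube}), or a directory
#'   path readable by \code{\link{read_view}}. Views must be ordered by
#'   acquisition, 360/v_n degrees apart.
#' @param config configuration list (\code{\link{pipeline_config}}).
#' @param calib optional precomputed \code{rotary_calibration}; estimated
#'   from the views when NULL.
#' @param reg_transform optional precomputed \code{reg_transform2d};
#'   estimated from the first view when NULL.
#' @param output_dir optional directory; when given, writes
#'   \code{model.ply}, \code{stats.csv}, \code{spad.ply} and
#'   \code{report.json}.
#' @return list with \code{model} (fused annotated canopy cloud),
#'   \code{full_model} (fused cloud before the canopy cut), \code{stats}
#'   (canopy statistics table), \code{spad_cloud}, \code{calib},
#'   \code{reg_transform} and \code{report}.
#' @export
run_pipeline <- function(views, config = pipeline_config(), calib = NULL,
                         reg_transform = NULL, output_dir = NULL) {
  validate_config(config)
  views <- lapply(views, function(v) if (is.character(v)) read_view(v) else v)
  if (length(views) != config$v_n) {
    stop("expected v_n = ", config$v_n, " views, got ", length(views),
         call. = FALSE)
  }
  K <- camera_intrinsics(config$intrinsics$cx, config$intrinsics$cy,
                         config$intrinsics$fx, config$intrinsics$fy)
  report <- list(config = config, stages = list())

  if (is.null(calib)) {
    calib <- stage("calibrate", {
      opp <- round(config$v_n / 2) + 1L
      if (opp > length(views)) {
        stop("axis calibration needs a view 180 degrees from the first")
      }
      cols <- sticker_colors()
      cl0 <- unproject(views[[1]]$depth, K, rgb = views[[1]]$rgb,
                       z_range = config$z_range)
      cl180 <- unproject(views[[opp]]$depth, K, rgb = views[[opp]]$rgb,
                         z_range = config$z_range)
      y1 <- detect_sticker_center(cl0, cols$yellow,
                                  config$min_sticker_inliers)
      r1 <- detect_sticker_center(cl0, cols$red, config$min_sticker_inliers)
      y2 <- detect_sticker_center(cl180, cols$yellow,
                                  config$min_sticker_inliers)
      r2 <- detect_sticker_center(cl180, cols$red, config$min_sticker_inliers)
      cal <- estimate_axis(y1$center, r1$center, y2$center, r2$center)
      cal$n_inliers <- c(y1 = y1$n_inliers, r1 = r1$n_inliers,
                         y2 = y2$n_inliers, r2 = r2$n_inliers)
      cal
    })
  }
  report$stages$calibrate <- list(center = calib$center,
                                  normal = calib$normal,
                                  residual = calib$residual)

  if (is.null(reg_transform)) {
    reg_transform <- stage("register", {
      estimate_similarity(view_gray(views[[1]]),
                          cube_gray(views[[1]]$cube,
                                    config$registration_band))
    })
  }
  report$stages$register <- list(dx = reg_transform$dx,
                                 dy = reg_transform$dy,
                                 theta0_deg = reg_transform$theta0,
                                 sigma = reg_transform$sigma,
                                 peak_response = reg_transform$peak_response)

  per_view <- stage("reconstruct", {
    lapply(seq_along(views), function(k) {
      v <- views[[k]]
      cl <- unproject(v$depth, K, rgb = v$rgb, view_id = k - 1L,
                      z_range = config$z_range)
      stack <- register_cube(v$cube, reg_transform, dim(v$depth))
      cl <- attach_reflectance(cl, stack)
      gamma <- config$spin_sign * (k - 1) * 360 / config$v_n
      cl <- to_common_frame(cl, calib, gamma_deg = gamma)
      cl <- crop_roi(cl, config$roi)
      if (nrow(cl) > config$outlier$k_neighbors) {
        cl <- remove_outliers(cl, config$outlier$k_neighbors,
                              config$outlier$std_ratio)
      }
      cl
    })
  })
  report$stages$views <- list(point_counts = vapply(per_view, nrow, 0L))

  fused <- stage("fuse", {
    fuse_views(per_view, max_corr_dist = config$icp$max_corr_dist,
               max_iter = config$icp$max_iter, tol = config$icp$tol,
               voxel = config$voxel)
  })
  report$stages$fuse <- list(icp_rms = fused$icp_rms,
                             fused_points = nrow(fused$cloud))

  canopy <- stage("canopy", {
    annotate_cloud(extract_canopy(fused$cloud, config$pot_top_height))
  })
  stats <- stage("stats", canopy_stats_table(canopy))
  report$stages$canopy <- list(points = nrow(canopy))

  spad_cloud <- stage("spad", {
    model <- spad_paper_model(config$spad_index)
    x <- canopy[[paste0("idx_", config$spad_index)]]
    spad <- rep(NA_real_, length(x))
    okx <- !is.na(x) & (model$prototype != "M4" | x > 0)
    spad[okx] <- spad_predict(model, x[okx])
    cl <- canopy
    cl$spad <- spad
    cl
  })

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_ply(canopy, file.path(output_dir, "model.ply"))
    utils::write.csv(stats, file.path(output_dir, "stats.csv"),
                     row.names = FALSE)
    write_ply(spad_cloud, file.path(output_dir, "spad.ply"))
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(list(model = canopy, full_model = fused$cloud, stats = stats,
                 spad_cloud = spad_cloud, calib = calib,
                 reg_transform = reg_transform, report = report))
}
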