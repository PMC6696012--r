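## Vegetation indices computed per point from the five-band reflectance,
## and the canopy summary statistics used to characterise the models.

DENOM_EPS <- 1e-9

#' Names of the supported vegetation indices
#'
#' @return character vector: NDVI, GNDVI, NDVIR, CIG, RCIG, NG, NR, RVI,
#'   GRVI.
#' @export
index_names <- function() {
  c("NDVI", "GNDVI", "NDVIR", "CIG", "RCIG", "NG", "NR", "RVI", "GRVI")
}

safe_div <- function(num, den) {
  out <- num / den
  out[abs(den) < DENOM_EPS] <- NA_real_
  out
}

#' Compute a vegetation index from band reflectance
#'
#' Formulas (rho values dimensionless in \code{[0, 1]}):
#' \itemize{
#'   \item NDVI = (Nir - Red) / (Nir + Red)
#'   \item GNDVI = (Nir - Green) / (Nir + Green)
#'   \item NDVIR = (Nir - Rededge) / (Nir + Rededge)
#'   \item CIG = Nir / Green - 1
#'   \item RCIG = Nir / Rededge - 1
#'   \item NG = Green / (Nir + Green + Red)
#'   \item NR = Red / (Nir + Green + Red)
#'   \item RVI = Nir / Red
#'   \item GRVI = Nir / Green
#' }
#' The result is NA wherever a needed band is NA or the denominator's
#' magnitude is below 1e-9.
#'
#' @param r list or data.frame with vectors \code{rho_blue, rho_green,
#'   rho_red, rho_rededge, rho_nir} (any subset the index needs).
#' @param name index name (see \code{\link{index_names}}).
#' @return numeric vector of index values.
#' @export
compute_index <- function(r, name) {
  g <- r$rho_green; rd <- r$rho_red; re <- r$rho_rededge; nir <- r$rho_nir
  switch(name,
    NDVI = safe_div(nir - rd, nir + rd),
    GNDVI = safe_div(nir - g, nir + g),
    NDVIR = safe_div(nir - re, nir + re),
    CIG = safe_div(nir, g) - 1,
    RCIG = safe_div(nir, re) - 1,
    NG = safe_div(g, nir + g + rd),
    NR = safe_div(rd, nir + g + rd),
    RVI = safe_div(nir, rd),
    GRVI = safe_div(nir, g),
    stop("unknown vegetation index: ", name, call. = FALSE)
  )
}

#' Annotate a cloud with per-point vegetation indices
#'
#' Adds one column per requested index, named \code{idx_<name>}; NA
#' reflectance propagates.
#'
#' @param cloud \code{spectral_point_cloud} carrying \code{rho_*} columns.
#' @param names indices to compute (default all nine).
#' @return the annotated cloud.
#' @export
annotate_cloud <- function(cloud, names = index_names()) {
  for (nm in names) {
    cloud[[paste0("idx_", nm)]] <- compute_index(cloud, nm)
  }
  cloud
}

#' Canopy summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), coefficient of
#' variation (STD / mean x 100 percent) and the non-NA point count.
#'
#' @param values numeric vector (per-point reflectance or index); NA
#'   ignored.
#' @return list with \code{mean}, \code{std}, \code{cv_percent},
#'   \code{n_points}.
#' @export
canopy_stats <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0) stop("empty stats: no non-NA values", call. = FALSE)
  m <- mean(v)
  s <- if (n > 1) sd(v) else 0
  cv <- if (abs(m) < DENOM_EPS) {
    warning("mean is zero; CV reported as NaN", call. = FALSE)
    NaN
  } else s / m * 100
  list(mean = m, std = s, cv_percent = cv, n_points = n)
}

#' Canopy statistics table for bands and indices
#'
#' One row of \code{\link{canopy_stats}} per reflectance band and per-point
#' index column present on the cloud.
#'
#' @param cloud annotated \code{spectral_point_cloud}.
#' @return data.frame with columns \code{variable, mean, std, cv_percent,
#'   n_points}.
#' @export
canopy_stats_table <- function(cloud) {
  cols <- grep("^(rho_|idx_)", names(cloud), value = TRUE)
  rows <- lapply(cols, function(cc) {
    st <- tryCatch(suppressWarnings(canopy_stats(cloud[[cc]])),
                   error = function(e) list(mean = NA_real_, std = NA_real_,
                                            cv_percent = NA_real_,
                                            n_points = 0L))
    data.frame(variable = cc, mean = st$mean, std = st$std,
               cv_percent = st$cv_percent, n_points = st$n_points)
  })
  do.call(rbind, rows)
}
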