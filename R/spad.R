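## SPAD chlorophyll calibration: fitting index-vs-SPAD models with the four
## prototype functions and serving the published 3DROI regression
## equations.
##
## Prototypes:
##   M1 linear      SPAD = a x + b           coefficients (a, b)
##   M2 quadratic   SPAD = a x^2 + b x + c   coefficients (a, b, c)
##   M3 exponential SPAD = c 10^(k x)        coefficients (c, k), c > 0
##   M4 power       SPAD = c x^k             coefficients (c, k), c > 0, x > 0

spad_prototypes <- c("M1", "M2", "M3", "M4")

new_spad_model <- function(prototype, coefficients, index_name = NA_character_,
                           r_squared = NA_real_, rmse = NA_real_) {
  prototype <- match.arg(prototype, spad_prototypes)
  np <- c(M1 = 2L, M2 = 3L, M3 = 2L, M4 = 2L)[[prototype]]
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != np) {
    stop(prototype, " requires ", np, " coefficients", call. = FALSE)
  }
  if (prototype %in% c("M3", "M4") && coefficients[1] <= 0) {
    stop(prototype, " leading coefficient must be > 0", call. = FALSE)
  }
  structure(list(prototype = prototype, coefficients = coefficients,
                 index_name = index_name, r_squared = r_squared,
                 rmse = rmse),
            class = "spad_model")
}

#' @export
print.spad_model <- function(x, ...) {
  eqn <- switch(x$prototype,
    M1 = sprintf("SPAD = %.6g x + %.6g", x$coefficients[1], x$coefficients[2]),
    M2 = sprintf("SPAD = %.6g x^2 + %.6g x + %.6g", x$coefficients[1],
                 x$coefficients[2], x$coefficients[3]),
    M3 = sprintf("SPAD = %.6g * 10^(%.6g x)", x$coefficients[1],
                 x$coefficients[2]),
    M4 = sprintf("SPAD = %.6g * x^%.6g", x$coefficients[1],
                 x$coefficients[2]))
  cat(sprintf("SPAD model %s (%s): %s", x$prototype,
              ifelse(is.na(x$index_name), "?", x$index_name), eqn))
  if (is.finite(x$r_squared)) {
    cat(sprintf("  [R^2 = %.4f, RMSE = %.4f]", x$r_squared, x$rmse))
  }
  cat("\n")
  invisible(x)
}

#' Evaluate a SPAD model
#'
#' @param model \code{spad_model}.
#' @param x vegetation-index values; the power prototype (M4) requires
#'   \code{x > 0}.
#' @return predicted SPAD values.
#' @export
spad_predict <- function(model, x) {
  stopifnot(inherits(model, "spad_model"))
  cf <- model$coefficients
  switch(model$prototype,
    M1 = cf[1] * x + cf[2],
    M2 = cf[1] * x^2 + cf[2] * x + cf[3],
    M3 = cf[1] * 10^(cf[2] * x),
    M4 = {
      if (any(x <= 0, na.rm = TRUE)) {
        stop("power prototype (M4) requires x > 0", call. = FALSE)
      }
      cf[1] * x^cf[2]
    })
}

#' Fit a SPAD calibration model
#'
#' Least-squares fit of one prototype function. M1/M2 use ordinary least
#' squares; M3/M4 use nonlinear least squares (Levenberg-Marquardt)
#' initialized from the log-linearized OLS solution. Diagnostics:
#' \code{R^2 = 1 - SS_res / SS_tot} and \code{RMSE = sqrt(SS_res / n)}
#' (denominator n, not n - p).
#'
#' @param x index values; M4 requires all \code{x > 0}.
#' @param y SPAD values (M3/M4 require \code{y > 0} for the log-linear
#'   start).
#' @param prototype "M1", "M2", "M3" or "M4".
#' @param index_name optional index label stored on the model.
#' @return a \code{spad_model} with \code{r_squared} and \code{rmse}
#'   filled in.
#' @export
spad_fit <- function(x, y, prototype, index_name = NA_character_) {
  prototype <- match.arg(prototype, spad_prototypes)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  np <- c(M1 = 2L, M2 = 3L, M3 = 2L, M4 = 2L)[[prototype]]
  if (length(x) < np + 1) {
    stop("need at least ", np + 1, " points to fit ", prototype,
         call. = FALSE)
  }
  if (sd(y) == 0) stop("constant response: R^2 undefined", call. = FALSE)
  if (prototype == "M4" && any(x <= 0)) {
    stop("power prototype (M4) requires x > 0", call. = FALSE)
  }
  cf <- switch(prototype,
    M1 = {
      b <- coef(lm(y ~ x))
      c(b[["x"]], b[["(Intercept)"]])
    },
    M2 = {
      b <- coef(lm(y ~ I(x^2) + x))
      c(b[["I(x^2)"]], b[["x"]], b[["(Intercept)"]])
    },
    M3 = fit_nls_log10(x, y, log_x = FALSE),
    M4 = fit_nls_log10(x, y, log_x = TRUE))
  model <- new_spad_model(prototype, cf, index_name = index_name)
  ev <- spad_evaluate(model, x, y)
  model$r_squared <- ev$r_squared
  model$rmse <- ev$rmse
  model
}

## M3: y = c 10^(k x); M4: y = c x^k = c 10^(k log10 x).
fit_nls_log10 <- function(x, y, log_x) {
  if (any(y <= 0)) {
    stop("exponential/power prototypes require positive SPAD values",
         call. = FALSE)
  }
  u <- if (log_x) log10(x) else x
  b <- coef(lm(log10(y) ~ u))
  start <- list(cc = 10^b[["(Intercept)"]], k = b[["u"]])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ cc * 10^(k * u), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    c(start$cc, start$k)  # log-linear solution as a fallback
  } else {
    cf <- coef(fit)
    c(cf[["cc"]], cf[["k"]])
  }
}

#' Model diagnostics on (possibly held-out) data
#'
#' @param model \code{spad_model}.
#' @param x,y index and SPAD values (n >= 2).
#' @return list with \code{r_squared} (1 - SS_res / SS_tot) and
#'   \code{rmse} (sqrt(SS_res / n), SPAD units).
#' @export
spad_evaluate <- function(model, x, y) {
  stopifnot(length(x) == length(y), length(y) >= 2)
  pred <- spad_predict(model, x)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("constant response: R^2 undefined", call. = FALSE)
  list(r_squared = 1 - ss_res / ss_tot,
       rmse = sqrt(ss_res / length(y)))
}

#' Squared Pearson correlation between observations and predictions
#'
#' Alternative goodness-of-fit measure to the default
#' \code{1 - SS_res / SS_tot}; the two agree for OLS-fitted linear models
#' but can differ for the nonlinear prototypes.
#'
#' @param model \code{spad_model}.
#' @param x,y index and SPAD values.
#' @return squared Pearson correlation.
#' @export
spad_r2_pearson <- function(model, x, y) {
  stats::cor(y, spad_predict(model, x))^2
}

## Published 3DROI calibration equations, coefficients exactly as printed
## (with their printed R^2 / RMSE as metadata).
PAPER_SPAD_MODELS <- list(
  NDVI = list(prototype = "M2", coefficients = c(154.8, -77.053, 43.256),
              r_squared = 0.8670, rmse = 1.2916),
  GNDVI = list(prototype = "M3", coefficients = c(14.998, 2.4631),
               r_squared = 0.9414, rmse = 0.8725),
  NDVIR = list(prototype = "M4", coefficients = c(120.28, 0.5542),
               r_squared = 0.9253, rmse = 0.9940),
  CIG = list(prototype = "M3", coefficients = c(24.001, 0.333),
             r_squared = 0.9443, rmse = 0.8508),
  RCIG = list(prototype = "M2", coefficients = c(-18.37, 58.963, 23.433),
              r_squared = 0.9023, rmse = 1.1066),
  NG = list(prototype = "M2", coefficients = c(-2311.2, 762.19, -9.1868),
            r_squared = 0.9188, rmse = 1.008),
  NR = list(prototype = "M3", coefficients = c(122.99, -5.537),
            r_squared = 0.8071, rmse = 1.5918),
  RVI = list(prototype = "M2", coefficients = c(1.3041, -2.805, 35.654),
             r_squared = 0.9019, rmse = 1.1091),
  GRVI = list(prototype = "M2", coefficients = c(5.9953, -19.913, 51.704),
              r_squared = 0.9408, rmse = 0.8616)
)

#' Published SPAD calibration model for a vegetation index
#'
#' Registry of the nine fused-model (3DROI) SPAD regression equations with
#' their published coefficients, served verbatim. The stored
#' \code{r_squared}/\code{rmse} are the published fit diagnostics of the
#' original calibration data.
#'
#' @param index_name one of \code{\link{index_names}}.
#' @return an immutable \code{spad_model}.
#' @export
spad_paper_model <- function(index_name) {
  entry <- PAPER_SPAD_MODELS[[index_name]]
  if (is.null(entry)) {
    stop("no published model for index: ", index_name, call. = FALSE)
  }
  new_spad_model(entry$prototype, entry$coefficients,
                 index_name = index_name,
                 r_squared = entry$r_squared, rmse = entry$rmse)
}

#' Serialize / load a SPAD model as JSON
#'
#' Records prototype, coefficients, index name and fit diagnostics with
#' full double precision.
#'
#' @param model \code{spad_model}.
#' @param path JSON file path.
#' @return \code{read_spad_model} returns a \code{spad_model}.
#' @export
write_spad_model <- function(model, path) {
  jsonlite::write_json(
    list(prototype = model$prototype, coefficients = model$coefficients,
         index_name = model$index_name, r_squared = model$r_squared,
         rmse = model$rmse),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spad_model
#' @export
read_spad_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_spad_model(x$prototype, x$coefficients,
                 index_name = ifelse(is.null(x$index_name), NA, x$index_name),
                 r_squared = x$r_squared, rmse = x$rmse)
}
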