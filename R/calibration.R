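## Sensor calibration computations: spectral-axis regression, spatial
## resolution and resolvability limits, validation regressions, and the
## acquisition bandwidth budget.

#' Fit the spectral axis of a pushbroom camera
#'
#' Least-squares polynomial mapping spectral pixel index to wavelength (nm)
#' from identified calibration-lamp emission lines. The fit is rejected when
#' its RMSE exceeds the spectrograph's nominal spectral resolution
#' (`max_rmse_nm`, default 2.7 nm) or when the fitted axis is not strictly
#' increasing across the sensed pixel range.
#'
#' @param pixel Spectral pixel positions of identified lines (distinct).
#' @param wavelength_nm Reference wavelengths (nm).
#' @param degree Polynomial degree (default 1; 2-3 supported).
#' @param max_rmse_nm Acceptance bound on the fit RMSE (nm).
#' @return An object of class `spectral_calibration`: a list with
#'   `coefficients` (intercept first), `degree`, `adj_r_squared`, `rmse_nm`,
#'   `n`, and the underlying `lm` fit. Supports [tidy()], [glance()] and
#'   `predict()`.
#' @export
fit_spectral_axis <- function(pixel, wavelength_nm, degree = 1L,
                              max_rmse_nm = 2.7) {
  stopifnot(length(pixel) == length(wavelength_nm))
  assert_finite(pixel, "pixel"); assert_finite(wavelength_nm, "wavelength_nm")
  if (anyDuplicated(pixel)) {
    ct_abort("duplicate pixel positions", "ct_error_duplicate_pixel")
  }
  if (length(pixel) < degree + 2L) {
    ct_abort("need at least degree + 2 calibration points", "ct_error_too_few")
  }
  if (degree >= length(unique(pixel))) {
    ct_abort("singular fit: degree too high for the supplied points",
             "ct_error_singular")
  }
  fit <- lm(wavelength_nm ~ poly(pixel, degree, raw = TRUE))
  if (anyNA(coef(fit))) {
    ct_abort("singular fit: rank-deficient design", "ct_error_singular")
  }
  res <- stats::residuals(fit)
  n <- length(pixel)
  rmse <- sqrt(mean(res^2))
  ## exact calibrations are legitimate: silence the perfect-fit note
  r2 <- suppressWarnings(summary(fit))$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - degree - 1)
  if (rmse > max_rmse_nm) {
    ct_abort(sprintf("spectral fit RMSE %.3g nm exceeds the nominal spectral resolution %.3g nm",
                     rmse, max_rmse_nm), "ct_error_rmse")
  }
  grid <- seq(min(pixel), max(pixel), length.out = 512L)
  pred <- stats::predict(fit, list(pixel = grid))
  if (any(diff(pred) <= 0)) {
    ct_abort("fitted spectral axis is not strictly increasing", "ct_error_monotone")
  }
  structure(list(coefficients = unname(coef(fit)), degree = degree,
                 adj_r_squared = adj, rmse_nm = rmse, n = n, fit = fit),
            class = "spectral_calibration")
}

#' @export
predict.spectral_calibration <- function(object, pixel, ...) {
  as.numeric(stats::predict(object$fit, list(pixel = pixel)))
}

#' @method tidy spectral_calibration
#' @export
tidy.spectral_calibration <- function(x, ...) {
  tibble(term = paste0("pixel^", 0:x$degree), estimate = x$coefficients)
}

#' @method glance spectral_calibration
#' @export
glance.spectral_calibration <- function(x, ...) {
  tibble(adj_r_squared = x$adj_r_squared, rmse_nm = x$rmse_nm, n = x$n,
         degree = x$degree)
}

#' @export
print.spectral_calibration <- function(x, ...) {
  cat(sprintf("Spectral axis calibration (degree %d, n = %d)\n", x$degree, x$n))
  cat(sprintf("  adjusted R^2 = %.6f, RMSE = %.4g nm\n", x$adj_r_squared, x$rmse_nm))
  invisible(x)
}

#' Spatial resolution from a length target
#'
#' Resolution is the ratio of the physical target length to the number of
#' image pixels covering it, reported at 1 decimal (mm/pixel) as is
#' conventional for such targets. The full-precision value is kept as
#' attribute `exact`.
#'
#' @param target_length_mm Physical target length (mm), > 0.
#' @param n_pixels Pixels covering the target, >= 1.
#' @return mm per pixel, rounded to 1 decimal.
#' @export
#' @examples
#' spatial_resolution(279.4, 41) # 6.8 mm/pixel
spatial_resolution <- function(target_length_mm, n_pixels) {
  stopifnot(target_length_mm > 0)
  if (any(n_pixels < 1)) {
    ct_abort("`n_pixels` must be at least 1", "ct_error_pixels")
  }
  exact <- target_length_mm / n_pixels
  structure(round(exact, 1L), exact = exact)
}

#' Can a line-pair pattern be resolved at a given spatial resolution?
#'
#' A line pair needs at least two pixels (one per stripe), so a pattern of
#' `r` line pairs per mm is resolvable iff the spatial resolution satisfies
#' `SR <= 1 / (2 r)` (inclusive at the boundary).
#'
#' @param sr_mm_per_px Spatial resolution (mm/pixel), > 0.
#' @param pattern_lp_per_mm Pattern density (line pairs per mm), > 0.
#' @return A tibble with `limit_mm_per_px` and logical `resolvable`.
#' @export
#' @examples
#' resolvable(6.8, 1 / 15) # limit 7.5 -> resolvable
#' resolvable(6.8, 1 / 10) # limit 5.0 -> not resolvable
resolvable <- function(sr_mm_per_px, pattern_lp_per_mm) {
  stopifnot(all(sr_mm_per_px > 0), all(pattern_lp_per_mm > 0))
  limit <- 1 / (2 * pattern_lp_per_mm)
  tibble(limit_mm_per_px = limit, resolvable = sr_mm_per_px <= limit)
}

#' Validation regression of device measurements against a reference
#'
#' Ordinary least squares of `measured` on `reference`, with adjusted R^2
#' (`1 - (1 - R^2)(n - 1)/(n - 2)`) and two RMSE summaries: the residual
#' RMS about the fitted line (primary) and the RMS deviation from the
#' identity line (`measured - reference`).
#'
#' @param measured Device measurements.
#' @param reference Reference (ground-truth) measurements, same length,
#'   n >= 3, non-constant.
#' @return A one-row tibble: `slope`, `intercept`, `adj_r_squared`, `rmse`,
#'   `rmse_identity`, `n`.
#' @export
validation_regression <- function(measured, reference) {
  stopifnot(length(measured) == length(reference))
  assert_finite(measured, "measured"); assert_finite(reference, "reference")
  n <- length(measured)
  if (n < 3L) ct_abort("need n >= 3", "ct_error_too_few")
  if (var(reference) == 0) {
    ct_abort("zero variance in reference", "ct_error_zero_variance")
  }
  fit <- lm(measured ~ reference)
  r2 <- suppressWarnings(summary(fit))$r.squared
  tibble(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    rmse_identity = sqrt(mean((measured - reference)^2)),
    n = n
  )
}

#' Acquisition data-volume budget for a set of sensor streams
#'
#' Per-stream data rate is frame size x frame rate; the designed and
#' maximum totals are sums across streams. Totals are reported at 1 decimal
#' (MB/s), matching how such budgets are tabulated; per-stream rates keep
#' full precision.
#'
#' @param streams A tibble/data frame with columns `name`, `frame_mb`,
#'   `fps_designed`, `fps_max` (at least one stream; sizes and rates > 0).
#' @return A list of class `data_budget`: `streams` (tibble with
#'   `mbps_designed`, `mbps_max` added) and `total` (one-row tibble with
#'   rounded `designed_mb_s`, `max_mb_s`).
#' @export
#' @examples
#' data_budget(tibble::tibble(
#'   name = c("depth", "color", "thermal", "hyperspectral"),
#'   frame_mb = c(0.42, 8, 1.18, 0.29),
#'   fps_designed = c(6, 6, 6, 100), fps_max = c(30, 30, 30, 200)
#' ))
data_budget <- function(streams) {
  req <- c("name", "frame_mb", "fps_designed", "fps_max")
  stopifnot(all(req %in% names(streams)), nrow(streams) >= 1L,
            all(streams$frame_mb > 0), all(streams$fps_designed > 0),
            all(streams$fps_max > 0))
  s <- dplyr::mutate(as_tibble(streams),
                     mbps_designed = .data$frame_mb * .data$fps_designed,
                     mbps_max = .data$frame_mb * .data$fps_max)
  structure(list(
    streams = s,
    total = tibble(designed_mb_s = round(sum(s$mbps_designed), 1L),
                   max_mb_s = round(sum(s$mbps_max), 1L))
  ), class = "data_budget")
}

#' @method tidy data_budget
#' @export
tidy.data_budget <- function(x, ...) x$streams

#' @method glance data_budget
#' @export
glance.data_budget <- function(x, ...) x$total

#' @export
print.data_budget <- function(x, ...) {
  print(x$streams)
  cat(sprintf("Total: %.1f MB/s designed, %.1f MB/s maximum\n",
              x$total$designed_mb_s, x$total$max_mb_s))
  invisible(x)
}
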