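#' Satellite chlorophyll-a calibration
#'
#' Linear rescaling of the satellite processor output against same-day in-situ
#' chlorophyll-a. The default coefficients are the operational vicarious
#' calibration fitted from 15 match-ups between 3x3-pixel window means at the
#' automatic station and the station's fluorometer readings:
#' \code{chl_calib = 0.346 * chl_satellite + 3.76}.
#'
#' @param slope dimensionless gain (default 0.346).
#' @param intercept offset in ug/l (default 3.76).
#' @param fit_r2,fit_sd,n optional fit diagnostics (R-squared, residual SD in
#'   ug/l, number of match-ups).
#' @return an object of class \code{eo_calibration}.
#' @export
eo_calibration <- function(slope = 0.346, intercept = 3.76,
                           fit_r2 = NA_real_, fit_sd = NA_real_,
                           n = NA_integer_) {
  structure(list(slope = slope, intercept = intercept,
                 fit_r2 = fit_r2, fit_sd = fit_sd, n = n),
            class = "eo_calibration")
}

#' @export
print.eo_calibration <- function(x, ...) {
  cat(sprintf("eo_calibration: chl = %.4g * raw + %.4g", x$slope, x$intercept))
  if (!is.na(x$fit_r2)) {
    cat(sprintf("  (R2 = %.3f, SD = %.3g ug/l, n = %d)", x$fit_r2, x$fit_sd,
                x$n))
  }
  cat("\n")
  invisible(x)
}

#' Apply the satellite calibration
#'
#' @param raw raw satellite chlorophyll-a (ug/l), finite and non-negative.
#' @param calib an \code{eo_calibration} (defaults to the operational one).
#' @return calibrated chlorophyll-a in ug/l.
#' @examples
#' calibrate_eo(0)   # the intercept, 3.76 ug/l
#' calibrate_eo(10)  # 7.22 ug/l
#' @export
calibrate_eo <- function(raw, calib = eo_calibration()) {
  stopifnot(inherits(calib, "eo_calibration"), all(is.finite(raw) | is.na(raw)))
  calib$slope * raw + calib$intercept
}

#' Fluorometer correction for cyanobacteria interference
#'
#' In late summer the phytoplankton community is dominated by cyanobacteria,
#' whose chlorophyll-a sits largely in the weakly fluorescing photosystem I,
#' so the chlorophyll fluorometer under-reads. The correction is a multiple
#' regression of laboratory chlorophyll-a on the sensor reading and the
#' phycocyanin-derived cyanobacteria biomass (wet weight). Operational
#' coefficients: \code{chl = chl_sensor + 3.3 * cb_sensor - 0.8}
#' (R2 = 0.93, n = 19, residual SD 1.1 ug/l).
#'
#' @param chl_coefficient gain on the sensor chlorophyll reading (default 1,
#'   implicit in the printed equation).
#' @param cb_coefficient gain on cyanobacteria biomass, ug/l chlorophyll per
#'   mg/l wet weight (default 3.3).
#' @param offset additive offset in ug/l (default -0.8).
#' @param fit_r2,fit_sd,n optional fit diagnostics.
#' @return an object of class \code{fluorometer_calibration}.
#' @export
fluorometer_calibration <- function(chl_coefficient = 1.0,
                                    cb_coefficient = 3.3,
                                    offset = -0.8,
                                    fit_r2 = NA_real_, fit_sd = NA_real_,
                                    n = NA_integer_) {
  structure(list(chl_coefficient = chl_coefficient,
                 cb_coefficient = cb_coefficient, offset = offset,
                 fit_r2 = fit_r2, fit_sd = fit_sd, n = n),
            class = "fluorometer_calibration")
}

#' @export
print.fluorometer_calibration <- function(x, ...) {
  cat(sprintf("fluorometer_calibration: chl = %.4g*chl_sensor + %.4g*cb %+.4g",
              x$chl_coefficient, x$cb_coefficient, x$offset))
  if (!is.na(x$fit_r2)) {
    cat(sprintf("  (R2 = %.3f, SD = %.3g ug/l, n = %d)", x$fit_r2, x$fit_sd,
                x$n))
  }
  cat("\n")
  invisible(x)
}

#' Apply the fluorometer correction
#'
#' Negative corrected values are possible (the offset is -0.8 ug/l); they are
#' returned as-is so that the calibration arithmetic stays exact, and are only
#' floored at the positivity floor when entering the log-space fusion.
#'
#' @param chl_sensor sensor chlorophyll-a reading (ug/l-equivalent
#'   fluorescence).
#' @param cb_sensor cyanobacteria biomass (mg/l wet weight), non-negative.
#' @param calib a \code{fluorometer_calibration}.
#' @return corrected chlorophyll-a in ug/l.
#' @examples
#' correct_fluorometer(5.0, 0.5)  # 5.85 ug/l
#' @export
correct_fluorometer <- function(chl_sensor, cb_sensor,
                                calib = fluorometer_calibration()) {
  stopifnot(inherits(calib, "fluorometer_calibration"),
            all(is.finite(chl_sensor)), all(is.finite(cb_sensor)),
            all(cb_sensor >= 0))
  calib$chl_coefficient * chl_sensor + calib$cb_coefficient * cb_sensor +
    calib$offset
}

#' Fit the satellite calibration by ordinary least squares
#'
#' Regresses in-situ chlorophyll-a on the satellite window mean:
#' \code{in_situ ~ eo_window_mean}.
#'
#' @param pairs data frame with columns \code{eo_window_mean} and
#'   \code{in_situ} (ug/l); at least 3 rows.
#' @return an \code{eo_calibration} with fitted slope, intercept and
#'   diagnostics (R-squared, residual SD, n).
#' @export
fit_eo_calibration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("eo_window_mean", "in_situ") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[c("eo_window_mean", "in_situ")]), ]
  if (nrow(pairs) < 3) stop("need at least 3 match-up pairs")
  if (stats::var(pairs$eo_window_mean) == 0) {
    stop("degenerate design: all satellite values identical")
  }
  fit <- stats::lm(in_situ ~ eo_window_mean, data = pairs)
  s <- summary(fit)
  eo_calibration(slope = unname(stats::coef(fit)["eo_window_mean"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 fit_r2 = s$r.squared, fit_sd = s$sigma,
                 n = nrow(pairs))
}

#' Fit the fluorometer correction by multiple regression
#'
#' Regresses laboratory chlorophyll-a on the sensor reading and cyanobacteria
#' biomass: \code{chl_lab ~ chl_sensor + cb_sensor}.
#'
#' @param pairs data frame with columns \code{chl_sensor}, \code{cb_sensor}
#'   and \code{chl_lab}; at least 4 rows and non-collinear regressors.
#' @return a \code{fluorometer_calibration} with fitted coefficients and
#'   diagnostics.
#' @export
fit_fluorometer_correction <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("chl_sensor", "cb_sensor", "chl_lab") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs), ]
  if (nrow(pairs) < 4) stop("need at least 4 calibration samples")
  if (stats::var(pairs$cb_sensor) == 0 || stats::var(pairs$chl_sensor) == 0 ||
      abs(stats::cor(pairs$chl_sensor, pairs$cb_sensor)) > 0.999) {
    stop("collinear regressors: cyanobacteria coefficient is not identifiable")
  }
  fit <- stats::lm(chl_lab ~ chl_sensor + cb_sensor, data = pairs)
  s <- summary(fit)
  fluorometer_calibration(
    chl_coefficient = unname(stats::coef(fit)["chl_sensor"]),
    cb_coefficient = unname(stats::coef(fit)["cb_sensor"]),
    offset = unname(stats::coef(fit)["(Intercept)"]),
    fit_r2 = s$r.squared, fit_sd = s$sigma, n = nrow(pairs)
  )
}

#' Window mean of a raster at a station
#'
#' Mean of the valid pixels in an odd-sided square window centered on the
#' station pixel; the operational match-up extraction uses a 3x3 window.
#' Pixels flagged as no-data (NA) are skipped; if every pixel in the window is
#' no-data the result is NA, never zero.
#'
#' @param raster numeric matrix (\code{nx x ny} pixel lattice, NA = no-data).
#' @param station_pixel integer pair \code{c(ix, iy)} of the station pixel.
#' @param window window side in pixels, odd (default 3).
#' @return mean of valid window pixels, or NA if none.
#' @export
extract_window_mean <- function(raster, station_pixel, window = 3) {
  stopifnot(is.matrix(raster), length(station_pixel) == 2,
            window >= 1, window %% 2 == 1)
  r <- (window - 1) / 2
  ix <- max(1, station_pixel[1] - r):min(nrow(raster), station_pixel[1] + r)
  iy <- max(1, station_pixel[2] - r):min(ncol(raster), station_pixel[2] + r)
  vals <- raster[ix, iy]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}
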