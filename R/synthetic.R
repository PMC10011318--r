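#' Synthetic lake grid at desk scale
#'
#' Default spatial domain for synthetic experiments: a rectangular lake of
#' 12 km x 9 km gridded at 600 m with the 500-m shoreline buffer, giving an
#' 18 x 13 = 234-cell domain. The coarse cell size keeps runtimes small while
#' the extent preserves the geometry of an 8-km correlation length (the
#' domain is larger than the range, as in the real lake); the operational
#' 60-m resolution is available by argument.
#'
#' @param extent lake rectangle in metres, \code{c(x, y)}.
#' @param cell_size cell side in metres.
#' @param buffer_distance shoreline buffer in metres.
#' @return a \code{lake_grid}.
#' @export
synthetic_lake_grid <- function(extent = c(12000, 9000), cell_size = 600,
                                buffer_distance = 500) {
  make_grid(square_outline(extent), cell_size, buffer_distance)
}

#' Bloom specification for the synthetic truth
#'
#' The early-summer phytoplankton peak is injected as a deterministic
#' Gaussian bump in log space: amplitude
#' \code{exp(-0.5 ((day - peak_day) / (duration/4))^2) * amplitude}, spatially
#' uniform. The default peak sits in mid-June (day 47 of a season starting
#' May 1) and lasts two and a half weeks — short enough that sparse grab
#' sampling can miss it entirely.
#'
#' @param peak_day day index of the bloom maximum (day 1 = May 1).
#' @param amplitude log-space amplitude; the default \code{log(3)} triples the
#'   median concentration at the peak.
#' @param duration bloom duration in days; the bump SD is \code{duration/4},
#'   so ~95\% of the excess lies within the stated duration.
#' @return an object of class \code{bloom_spec}.
#' @export
bloom_spec <- function(peak_day = 47, amplitude = log(3), duration = 18) {
  stopifnot(duration > 0, amplitude >= 0)
  structure(list(peak_day = peak_day, amplitude = amplitude,
                 duration = duration), class = "bloom_spec")
}

#' Simulate the synthetic true chlorophyll-a field
#'
#' The log-field evolves as the stationary mean-reverting AR(1) process of the
#' fusion model: initial state \code{N(log(mu_b), sigma_s^2 C(l))}, daily
#' transition \code{x_k = alpha (x_{k-1} - log mu_b) + log mu_b + eta_k} with
#' innovation covariance \code{(1 - alpha^2) sigma_s^2 C(l)}, so every day's
#' marginal spatial covariance is the spherical model. The deterministic
#' bloom bump is added in log space on top of the stochastic field.
#'
#' @param grid a \code{lake_grid}.
#' @param config a \code{fusion_config} (supplies mu_b, sigma_s, l, alpha).
#' @param bloom a \code{bloom_spec}, or NULL for no bloom.
#' @param n_days season length in days (default 153 = May 1 to Sep 30).
#' @param seed integer seed (defaults to \code{config$seed}).
#' @return an object of class \code{truth_field}: list with \code{values} and
#'   \code{log_values} (\code{n_days x n_cells} matrices), \code{n_days},
#'   \code{bloom}.
#' @export
simulate_truth <- function(grid, config, bloom = bloom_spec(),
                           n_days = 153, seed = config$seed) {
  stopifnot(inherits(grid, "lake_grid"), inherits(config, "fusion_config"),
            n_days >= 1)
  chol_C <- state_cholesky(build_state_correlation(grid, config$l))
  mu <- log(config$mu_b)
  set.seed(seed)
  x <- matrix(NA_real_, n_days, grid$n_cells)
  x[1, ] <- mu + draw_correlated(1, chol_C, config$sigma_s)
  innov_sd <- config$sigma_s * sqrt(1 - config$alpha^2)
  for (k in seq_len(n_days - 1)) {
    x[k + 1, ] <- mu + config$alpha * (x[k, ] - mu) +
      draw_correlated(1, chol_C, innov_sd)
  }
  if (!is.null(bloom)) {
    stopifnot(inherits(bloom, "bloom_spec"))
    bump <- bloom$amplitude *
      exp(-0.5 * ((seq_len(n_days) - bloom$peak_day) / (bloom$duration / 4))^2)
    x <- x + bump  # recycled column-wise: one bump value per day
  }
  structure(list(values = exp(x), log_values = x, n_days = n_days,
                 bloom = bloom), class = "truth_field")
}

#' @export
print.truth_field <- function(x, ...) {
  cat(sprintf("truth_field: %d days x %d cells, median %.2f ug/l\n",
              x$n_days, ncol(x$values), stats::median(x$values)))
  invisible(x)
}

#' Monitoring design of the synthetic season
#'
#' Encodes the three observation streams of the emulated 2009 season:
#' \itemize{
#'   \item routine grab samples at the official monitoring station, once or
#'     twice a month May–September (10\% relative error);
#'   \item daily automatic-station fluorometry 0.9 km away (16\% relative
#'     error; 09:00 readings, so one value per day);
#'   \item about 8 cloud-free satellite snapshots over June–September covering
#'     every water cell (34\% relative error).
#' }
#' Day 1 is May 1; June 1 = day 32 and September 30 = day 153.
#'
#' @param grid a \code{lake_grid}.
#' @param routine_cell,automatic_cell water-cell indices; by default the
#'   routine station sits at the domain center and the automatic station at
#'   the nearest cell 900 m east of it.
#' @param routine_days,automatic_days,eo_days day-index vectors.
#' @param rel_sd named relative error SDs per source.
#' @param eo_cloud_fraction fraction of the listed satellite days dropped at
#'   random as clouded (default 0: \code{eo_days} already lists the
#'   cloud-free overpasses).
#' @return an object of class \code{sampling_design}.
#' @export
sampling_design <- function(grid,
                            routine_cell = NULL,
                            automatic_cell = NULL,
                            routine_days = c(1, 15, 32, 46, 62, 76, 93, 107,
                                             124, 138),
                            automatic_days = 1:153,
                            eo_days = c(40, 55, 70, 85, 100, 112, 127, 142),
                            rel_sd = c(routine = 0.10, automatic = 0.16,
                                       eo = 0.34),
                            eo_cloud_fraction = 0) {
  stopifnot(inherits(grid, "lake_grid"))
  center <- colMeans(grid$cell_centers)
  if (is.null(routine_cell)) routine_cell <- nearest_cell(grid, center)
  if (is.null(automatic_cell)) {
    automatic_cell <- nearest_cell(grid, center + c(900, 0))
  }
  stopifnot(routine_cell >= 1, routine_cell <= grid$n_cells,
            automatic_cell >= 1, automatic_cell <= grid$n_cells,
            all(rel_sd >= 0), all(rel_sd < 1),
            eo_cloud_fraction >= 0, eo_cloud_fraction <= 1)
  structure(list(routine_cell = routine_cell,
                 automatic_cell = automatic_cell,
                 routine_days = routine_days,
                 automatic_days = automatic_days,
                 eo_days = eo_days,
                 rel_sd = rel_sd,
                 eo_cloud_fraction = eo_cloud_fraction),
            class = "sampling_design")
}

#' WFD assessment period in day indices
#'
#' June 1 to September 30 of a season whose day 1 is May 1 — the window over
#' which Water Framework Directive status means are computed.
#'
#' @return integer vector \code{c(32, 153)}.
#' @export
wfd_period <- function() c(32L, 153L)

#' Sample the three observation streams from a truth field
#'
#' Each observation is the true concentration at its (day, cell) times a
#' lognormal noise factor \code{exp(N(0, s))} with
#' \code{s = sqrt(log(1 + cv^2))} for the source's relative error cv — the
#' noise is unbiased in log space and exactly reproduces the stated relative
#' SDs. Satellite days yield one observation per water cell; clouded days
#' (per \code{eo_cloud_fraction}) are dropped whole.
#'
#' @param truth a \code{truth_field}.
#' @param design a \code{sampling_design}.
#' @param seed integer seed.
#' @return data frame with columns \code{day}, \code{cell}, \code{value}
#'   (ug/l), \code{source}, \code{rel_sd}.
#' @export
sample_observations <- function(truth, design, seed = 1L) {
  stopifnot(inherits(truth, "truth_field"), inherits(design, "sampling_design"))
  all_days <- c(design$routine_days, design$automatic_days, design$eo_days)
  if (length(all_days) && (min(all_days) < 1 || max(all_days) > truth$n_days)) {
    stop("design days outside the truth field's day range")
  }
  set.seed(seed)
  eo_days <- design$eo_days
  if (design$eo_cloud_fraction > 0 && length(eo_days)) {
    eo_days <- eo_days[stats::runif(length(eo_days)) >=
                         design$eo_cloud_fraction]
  }
  n_cells <- ncol(truth$values)
  rows <- list(
    if (length(design$routine_days)) {
      data.frame(day = design$routine_days, cell = design$routine_cell,
                 source = "routine")
    },
    if (length(design$automatic_days)) {
      data.frame(day = design$automatic_days, cell = design$automatic_cell,
                 source = "automatic")
    },
    if (length(eo_days)) {
      data.frame(day = rep(eo_days, each = n_cells),
                 cell = rep(seq_len(n_cells), times = length(eo_days)),
                 source = "eo")
    }
  )
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(day = integer(0), cell = integer(0), value = numeric(0),
                      source = character(0), rel_sd = numeric(0)))
  }
  obs <- do.call(rbind, rows)
  obs$rel_sd <- unname(design$rel_sd[obs$source])
  true_vals <- truth$values[cbind(obs$day, obs$cell)]
  log_sd <- cv_to_log_sd(obs$rel_sd)
  obs$value <- true_vals * exp(stats::rnorm(nrow(obs), 0, log_sd))
  rownames(obs) <- NULL
  obs[c("day", "cell", "value", "source", "rel_sd")]
}

#' Synthesize raw (uncalibrated) sensor and satellite streams
#'
#' Produces the raw inputs the calibration stage consumes by inverting the two
#' calibration equations on noisy truth, so that applying
#' \code{\link{correct_fluorometer}} and \code{\link{calibrate_eo}} with the
#' default calibrations recovers the calibrated streams (exactly, in the
#' zero-noise limit). A synthetic cyanobacteria biomass series accompanies the
#' sensor stream: zero until mid-July, then a linear ramp to \code{cb_max} at
#' the end of August, emulating the late-summer cyanobacteria community.
#'
#' @param truth a \code{truth_field}.
#' @param design a \code{sampling_design}.
#' @param seed integer seed.
#' @param cb_max late-August cyanobacteria maximum (mg/l wet weight).
#' @param eo_calib,fluoro_calib calibrations to invert (defaults are the
#'   operational ones).
#' @return list with
#'   \item{sensor}{data frame: day, chl_sensor (raw fluorometer ug/l-equiv),
#'     cb_sensor (mg/l), chl_corrected (what the correction should return),
#'     chl_true}
#'   \item{eo}{list with \code{days} and \code{rasters}: one \code{nx x ny}
#'     raw-satellite matrix per cloud-free day (NA outside the domain)}
#'   \item{eo_clipped}{count of raw satellite pixels clipped at zero by the
#'     calibration inversion}
#' @export
synthesize_raw_streams <- function(truth, design, seed = 1L, cb_max = 1.5,
                                   eo_calib = eo_calibration(),
                                   fluoro_calib = fluorometer_calibration()) {
  stopifnot(inherits(truth, "truth_field"), inherits(design, "sampling_design"))
  set.seed(seed)
  days <- design$automatic_days
  n_days <- truth$n_days
  # cyanobacteria ramp: 0 before day 77 (mid-July), linear to cb_max at
  # day 123 (Aug 31), flat after
  cb_series <- pmin(pmax((seq_len(n_days) - 77) / (123 - 77), 0), 1) * cb_max
  chl_true <- truth$values[cbind(days, design$automatic_cell)]
  s_auto <- cv_to_log_sd(design$rel_sd["automatic"])
  chl_corrected <- chl_true * exp(stats::rnorm(length(days), 0, s_auto))
  cb <- cb_series[days]
  chl_sensor <- (chl_corrected - fluoro_calib$cb_coefficient * cb -
                   fluoro_calib$offset) / fluoro_calib$chl_coefficient
  sensor <- data.frame(day = days, chl_sensor = chl_sensor, cb_sensor = cb,
                       chl_corrected = chl_corrected, chl_true = chl_true)

  s_eo <- cv_to_log_sd(design$rel_sd["eo"])
  n_clipped <- 0L
  grid_dim <- NULL
  rasters <- lapply(design$eo_days, function(d) {
    calib_vals <- truth$values[d, ] * exp(stats::rnorm(ncol(truth$values),
                                                       0, s_eo))
    raw <- (calib_vals - eo_calib$intercept) / eo_calib$slope
    clipped <- raw < 0
    n_clipped <<- n_clipped + sum(clipped)
    raw[clipped] <- 0
    raw
  })
  list(sensor = sensor,
       eo = list(days = design$eo_days, raw_values = rasters),
       eo_clipped = n_clipped)
}

#' Synthetic calibration match-up pairs
#'
#' Generators for regression fixtures at the sample sizes and residual SDs of
#' the operational calibrations: 19 laboratory samples with residual SD
#' 1.1 ug/l for the fluorometer correction, 15 satellite match-ups with
#' residual SD 2.56 ug/l for the satellite calibration. Used to check that the
#' fitting routines recover the printed coefficients within their OLS
#' standard errors.
#'
#' @param n number of pairs.
#' @param resid_sd residual SD of the generated relationship (ug/l).
#' @param seed integer seed.
#' @param calib generating calibration (defaults operational).
#' @return a data frame ready for \code{\link{fit_fluorometer_correction}} or
#'   \code{\link{fit_eo_calibration}}.
#' @export
synthesize_fluoro_pairs <- function(n = 19, resid_sd = 1.1, seed = 1L,
                                    calib = fluorometer_calibration()) {
  set.seed(seed)
  chl_sensor <- stats::runif(n, 1, 12)
  cb_sensor <- stats::runif(n, 0, 1.5)
  chl_lab <- correct_fluorometer(chl_sensor, cb_sensor, calib) +
    stats::rnorm(n, 0, resid_sd)
  data.frame(chl_sensor = chl_sensor, cb_sensor = cb_sensor,
             chl_lab = chl_lab)
}

#' @rdname synthesize_fluoro_pairs
#' @export
synthesize_eo_pairs <- function(n = 15, resid_sd = 2.56, seed = 1L,
                                calib = eo_calibration()) {
  set.seed(seed)
  raw <- stats::runif(n, 0, 40)
  in_situ <- calibrate_eo(raw, calib) + stats::rnorm(n, 0, resid_sd)
  data.frame(eo_window_mean = raw, in_situ = in_situ)
}
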