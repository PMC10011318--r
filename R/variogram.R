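#' Spherical semivariance model
#'
#' \code{nugget + sill * (1.5 h/range - 0.5 (h/range)^3)} for \code{h < range},
#' \code{nugget + sill} beyond. The companion correlation model used by the
#' fusion state covariance is \code{1 - (semivariance - nugget)/sill}.
#'
#' @param h distances (m).
#' @param nugget,sill,range model parameters; \code{range > 0},
#'   \code{sill, nugget >= 0}.
#' @return semivariance at each distance.
#' @export
spherical_semivariance <- function(h, nugget, sill, range) {
  x <- pmin(h / range, 1)
  nugget + sill * (1.5 * x - 0.5 * x^3)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Classical method-of-moments estimator: half the mean squared difference of
#' all pairs of valid values whose separation falls in each distance bin.
#' Bins that receive no pairs are reported with NA semivariance.
#'
#' @param values numeric vector, one value per location (NA allowed; the
#'   fusion applies this to one day's log-chlorophyll field).
#' @param coords two-column matrix of planar coordinates (m).
#' @param lag_width bin width in metres.
#' @param max_lag largest separation considered; default two thirds of the
#'   maximum pairwise distance (the usual rule to avoid sparse long-range
#'   bins).
#' @return data frame with columns \code{lag} (bin center, m), \code{gamma}
#'   (semivariance) and \code{n_pairs}.
#' @export
empirical_variogram <- function(values, coords, lag_width,
                                max_lag = NULL) {
  coords <- as.matrix(coords)
  stopifnot(length(values) == nrow(coords), lag_width > 0)
  ok <- which(!is.na(values))
  if (length(ok) < 2) stop("need at least 2 valid locations")
  v <- values[ok]
  d <- as.vector(stats::dist(coords[ok, , drop = FALSE]))
  sq <- as.vector(stats::dist(v))^2  # (v_i - v_j)^2 over the same pair order
  if (is.null(max_lag)) max_lag <- max(d) * 2 / 3
  keep <- d <= max_lag & d > 0
  d <- d[keep]; sq <- sq[keep]
  bin <- pmax(1L, ceiling(d / lag_width))
  nbin <- max(1L, ceiling(max_lag / lag_width))
  n_pairs <- tabulate(bin, nbins = nbin)
  ssum <- vapply(seq_len(nbin), function(b) sum(sq[bin == b]), numeric(1))
  gamma <- ifelse(n_pairs > 0, ssum / (2 * n_pairs), NA_real_)
  data.frame(lag = (seq_len(nbin) - 0.5) * lag_width,
             gamma = gamma, n_pairs = n_pairs)
}

#' Pooled empirical variogram over several snapshot days
#'
#' Satellite snapshots are pooled by averaging the per-day empirical
#' semivariances bin-wise, weighted by pair counts; counts are summed.
#'
#' @param fields numeric matrix, days in rows and locations in columns (NA =
#'   missing pixel).
#' @param coords two-column coordinate matrix matching the columns.
#' @param lag_width,max_lag as in \code{\link{empirical_variogram}}.
#' @return data frame as from \code{\link{empirical_variogram}}.
#' @export
pooled_variogram <- function(fields, coords, lag_width, max_lag = NULL) {
  fields <- as.matrix(fields)
  per_day <- lapply(seq_len(nrow(fields)), function(k) {
    empirical_variogram(fields[k, ], coords, lag_width, max_lag)
  })
  lags <- per_day[[1]]$lag
  stopifnot(all(vapply(per_day, function(x) identical(x$lag, lags),
                       logical(1))))
  n_pairs <- Reduce(`+`, lapply(per_day, `[[`, "n_pairs"))
  wsum <- Reduce(`+`, lapply(per_day, function(x) {
    ifelse(x$n_pairs > 0, x$gamma * x$n_pairs, 0)
  }))
  data.frame(lag = lags,
             gamma = ifelse(n_pairs > 0, wsum / n_pairs, NA_real_),
             n_pairs = n_pairs)
}

#' Fit a spherical variogram model
#'
#' Weighted least squares (weights = pair counts) fit of the spherical model
#' to an empirical variogram, the procedure used to select the spatial
#' correlation length of the fusion model. The range is constrained positive
#' and the nugget and sill non-negative via the Levenberg-Marquardt bounds.
#'
#' @param lags bin centers (m).
#' @param gamma empirical semivariances (NA bins are dropped).
#' @param n_pairs pair counts used as weights.
#' @param fix_nugget if TRUE (default) the nugget is fixed at 0, matching a
#'   mean-square-continuous field; set FALSE to estimate it (recommended when
#'   the empirical variogram comes from noisy observations, whose measurement
#'   error appears as a nugget).
#' @return an object of class \code{variogram_fit}: list with \code{nugget},
#'   \code{sill}, \code{range} (m), the input points and the fitted curve.
#' @export
fit_spherical_variogram <- function(lags, gamma, n_pairs,
                                    fix_nugget = TRUE) {
  ok <- !is.na(gamma) & n_pairs > 0
  lags <- lags[ok]; gamma <- gamma[ok]; n_pairs <- n_pairs[ok]
  if (length(lags) < 3) stop("need at least 3 non-empty variogram bins")
  if (stats::var(gamma) == 0) {
    stop("all semivariances equal: range is unidentifiable")
  }
  w <- sqrt(n_pairs)
  residuals_fn <- function(p) {
    nugget <- if (fix_nugget) 0 else p[3]
    w * (spherical_semivariance(lags, nugget, p[1], p[2]) - gamma)
  }
  # the range is not identifiable beyond the data support: when the
  # empirical curve looks linear (no visible sill), an unconstrained fit
  # runs sill and range off to infinity together, so the range is bounded
  # by the largest lag and flagged when it hits that bound
  p0 <- c(sill = max(gamma), range = max(lags) / 2)
  lower <- c(0, 1e-6)
  upper <- c(Inf, max(lags))
  if (!fix_nugget) {
    p0 <- c(p0, nugget = 0)
    lower <- c(lower, 0)
    upper <- c(upper, Inf)
  }
  fit <- minpack.lm::nls.lm(p0, lower = lower, upper = upper,
                            fn = residuals_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0 || fit$info == 9) {
    stop("spherical variogram fit did not converge (last iterate: sill ",
         signif(fit$par[1], 4), ", range ", signif(fit$par[2], 4), " m)")
  }
  co <- fit$par
  nugget <- if (fix_nugget) 0 else unname(co[3])
  structure(list(
    nugget = nugget, sill = unname(co[1]), range = unname(co[2]),
    range_at_bound = unname(co[2]) >= max(lags) * (1 - 1e-8),
    lags = lags, gamma = gamma, n_pairs = n_pairs,
    fitted = spherical_semivariance(lags, nugget, unname(co[1]),
                                    unname(co[2]))
  ), class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf(
    "variogram_fit (spherical): nugget %.4g, sill %.4g, range %.0f m\n",
    x$nugget, x$sill, x$range))
  invisible(x)
}

#' Per-day log-value fields from satellite observations
#'
#' Arranges the satellite rows of an observation table as a days x cells
#' matrix of log-concentrations (NA where a cell has no retrieval), the input
#' expected by \code{\link{pooled_variogram}} when selecting the spatial
#' correlation length from satellite snapshots.
#'
#' @param observations observation data frame (\code{day}, \code{cell},
#'   \code{value}, \code{source}).
#' @param grid the \code{lake_grid}.
#' @param source source label to select (default \code{"eo"}).
#' @return numeric matrix with one row per snapshot day (row names are the
#'   day indices).
#' @export
eo_log_fields <- function(observations, grid, source = "eo") {
  stopifnot(inherits(grid, "lake_grid"))
  sub <- observations[observations$source == source, ]
  if (nrow(sub) == 0) stop("no observations with source '", source, "'")
  days <- sort(unique(sub$day))
  fields <- matrix(NA_real_, length(days), grid$n_cells,
                   dimnames = list(days, NULL))
  for (i in seq_along(days)) {
    rows <- sub[sub$day == days[i], ]
    fields[i, rows$cell] <- log(rows$value)
  }
  fields
}

#' Temporal decorrelation time of a daily series
#'
#' Computes the sample autocorrelation of the log-values of a daily series and
#' returns the first lag (days) at which it drops below the threshold. The
#' default threshold is the e-folding convention 1/e; the procedure is the one
#' used to choose the 3-day temporal correlation of the fusion model.
#'
#' @param series daily values (positive; logs are taken internally). At least
#'   10 non-missing days.
#' @param threshold autocorrelation threshold (default \code{exp(-1)}).
#' @param max_lag largest lag examined (default half the series length).
#' @return decorrelation time in days (smallest lag with ACF below threshold).
#' @export
temporal_autocorrelation <- function(series, threshold = exp(-1),
                                     max_lag = NULL) {
  x <- log(series[!is.na(series)])
  if (length(x) < 10) stop("need at least 10 non-missing days")
  if (stats::var(x) == 0) {
    stop("constant series: autocorrelation is undefined")
  }
  if (is.null(max_lag)) max_lag <- floor(length(x) / 2)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  below <- which(rho < threshold)
  if (!length(below)) {
    stop("autocorrelation never drops below the threshold within max_lag")
  }
  below[1]
}
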