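#' Station time series with 68% confidence interval
#'
#' Extracts the per-day posterior triple at one cell from a fusion product.
#' In stretches without informative observations the interval widens with the
#' time since the last observation, which is how the products expose the cost
#' of sparse sampling.
#'
#' @param product a fusion product data frame (from \code{\link{run_filter}}'s
#'   \code{$product} or \code{\link{run_smoother}}).
#' @param cell water-cell index of the station.
#' @return data frame: \code{day}, \code{mean}, \code{ci68_low},
#'   \code{ci68_high}, \code{sd_linear}.
#' @export
station_timeseries <- function(product, cell) {
  stopifnot(all(c("day", "cell", "mean", "ci68_low", "ci68_high") %in%
                  names(product)))
  if (!cell %in% product$cell) stop("cell not in the product's domain")
  out <- product[product$cell == cell,
                 c("day", "mean", "ci68_low", "ci68_high", "sd_linear")]
  out <- out[order(out$day), ]
  rownames(out) <- NULL
  out
}

#' Standard deviation from a 68% interval
#'
#' The reporting convention approximates the SD of a fusion estimate by half
#' the width of its 68\% confidence interval, which makes it directly
#' comparable to the SD of a normal distribution.
#'
#' @param ci68_low,ci68_high interval bounds (ug/l), \code{ci68_high >=
#'   ci68_low}.
#' @return SD in ug/l.
#' @examples
#' sd_from_interval(4, 10)  # 3
#' @export
sd_from_interval <- function(ci68_low, ci68_high) {
  stopifnot(all(ci68_high >= ci68_low))
  (ci68_high - ci68_low) / 2
}

#' Period summary of a fusion product
#'
#' Aggregates daily fusion results over an assessment window (by default the
#' WFD period, June 1 to September 30). The period mean is the average of the
#' daily posterior means; the period SD is the average of the daily linear SDs
#' (half-interval widths) — an average uncertainty, not the SD of the daily
#' means. Domain scope additionally averages over all water cells with equal
#' weights (cells are equal-area).
#'
#' @param product a fusion product data frame.
#' @param scope either \code{"domain"} or a water-cell index.
#' @param period integer day range \code{c(first, last)}, inclusive; default
#'   \code{\link{wfd_period}()}.
#' @param data_combination optional label recording which observation streams
#'   produced the product.
#' @return an object of class \code{period_summary}: list with
#'   \code{mean_chl} (ug/l), \code{sd} (ug/l), \code{relative_sd} (percent,
#'   \code{100 * sd / mean_chl}), \code{scope}, \code{period},
#'   \code{data_combination}.
#' @export
period_summary <- function(product, scope = "domain", period = wfd_period(),
                           data_combination = NA_character_) {
  stopifnot(length(period) == 2, period[1] <= period[2])
  rows <- product$day >= period[1] & product$day <= period[2]
  if (!identical(scope, "domain")) {
    if (!scope %in% product$cell) stop("scope cell not in the product")
    rows <- rows & product$cell == scope
  }
  sub <- product[rows, ]
  if (nrow(sub) == 0) stop("empty period: no product rows in the day range")
  mean_chl <- mean(sub$mean)
  sd <- mean(sub$sd_linear)
  structure(list(mean_chl = mean_chl, sd = sd,
                 relative_sd = 100 * sd / mean_chl,
                 scope = scope, period = period,
                 data_combination = data_combination),
            class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  scope <- if (identical(x$scope, "domain")) "domain" else {
    sprintf("cell %d", x$scope)
  }
  cat(sprintf(
    "period_summary [%s, days %d-%d%s]: mean %.2f ug/l, SD %.2f ug/l, relative SD %.1f%%\n",
    scope, x$period[1], x$period[2],
    if (is.na(x$data_combination)) "" else paste0(", ", x$data_combination),
    x$mean_chl, x$sd, x$relative_sd))
  invisible(x)
}

#' Relative-SD map for one day
#'
#' Per-cell relative uncertainty, \code{100 * sd_linear / mean} percent — the
#' quantity mapped alongside the concentration field to show where the
#' monitoring network leaves the estimate poorly constrained.
#'
#' @param product a fusion product data frame.
#' @param day day index.
#' @return data frame: \code{cell}, \code{relative_sd} (percent).
#' @export
relative_sd_map <- function(product, day) {
  sub <- product[product$day == day, ]
  if (nrow(sub) == 0) stop("day not in the product range")
  data.frame(cell = sub$cell, relative_sd = 100 * sub$sd_linear / sub$mean)
}

#' Run a full synthetic fusion experiment
#'
#' One call wires the whole pipeline: simulate a truth field, sample the three
#' observation streams, and run filter plus smoother once per requested
#' stream combination, returning products, station and domain period
#' summaries, and a run manifest. This is the engine behind monitoring-design
#' comparisons: which combination of grab samples, daily sensors and satellite
#' snapshots buys how much certainty.
#'
#' @param grid a \code{lake_grid} (default \code{\link{synthetic_lake_grid}()}).
#' @param config a \code{fusion_config}.
#' @param design a \code{sampling_design} (default built from the grid).
#' @param combinations list of character vectors, each a non-empty subset of
#'   \code{c("routine", "automatic", "eo")}.
#' @param n_days season length in days.
#' @param seed top-level seed; child seeds for truth, sampling and each
#'   fusion run are derived from it deterministically so individual streams
#'   are reproducible even when the set of combinations changes.
#' @param period aggregation window for the period summaries.
#' @return an object of class \code{fusion_experiment}: list with
#'   \item{truth}{the \code{truth_field}}
#'   \item{observations}{the sampled observation table}
#'   \item{runs}{one entry per combination: smoother \code{product}, filter
#'     \code{filter_product}, \code{station_summary} (routine station),
#'     \code{automatic_summary}, \code{domain_summary}}
#'   \item{manifest}{seed, config, design and combination labels}
#' @export
run_experiment <- function(grid = synthetic_lake_grid(),
                           config = fusion_config(),
                           design = sampling_design(grid),
                           combinations = list(
                             "routine",
                             c("routine", "eo"),
                             c("routine", "automatic"),
                             c("routine", "automatic", "eo")
                           ),
                           n_days = 153, seed = 1L,
                           period = wfd_period()) {
  stopifnot(length(combinations) >= 1)
  labels <- vapply(combinations, function(s) paste(sort(s), collapse = "+"),
                   character(1))
  known <- c("routine", "automatic", "eo")
  for (s in combinations) {
    if (!length(s) || !all(s %in% known)) {
      stop("unknown stream label in combination: ",
           paste(setdiff(s, known), collapse = ", "))
    }
  }
  # deterministic child seeds: stream-level reproducibility
  truth_seed <- seed * 1000L + 1L
  obs_seed <- seed * 1000L + 2L
  truth <- simulate_truth(grid, config, n_days = n_days, seed = truth_seed)
  observations <- sample_observations(truth, design, seed = obs_seed)

  runs <- vector("list", length(combinations))
  names(runs) <- labels
  for (i in seq_along(combinations)) {
    obs_i <- observations[observations$source %in% combinations[[i]], ]
    cfg_i <- config
    cfg_i$seed <- seed * 1000L + 10L + i
    fit <- run_filter(obs_i, grid, cfg_i, n_days)
    smoothed <- run_smoother(fit)
    runs[[i]] <- list(
      combination = combinations[[i]],
      product = smoothed,
      filter_product = fit$product,
      n_obs = sum(fit$n_obs),
      station_summary = period_summary(smoothed, design$routine_cell, period,
                                       labels[i]),
      automatic_summary = period_summary(smoothed, design$automatic_cell,
                                         period, labels[i]),
      domain_summary = period_summary(smoothed, "domain", period, labels[i])
    )
    fit <- NULL
  }
  manifest <- list(seed = seed, truth_seed = truth_seed, obs_seed = obs_seed,
                   n_days = n_days, period = period,
                   combinations = labels,
                   config = unclass(config)[c("mu_b", "sigma_s", "l", "alpha",
                                              "ensemble_size")],
                   routine_cell = design$routine_cell,
                   automatic_cell = design$automatic_cell)
  structure(list(truth = truth, observations = observations, runs = runs,
                 manifest = manifest),
            class = "fusion_experiment")
}

#' @export
print.fusion_experiment <- function(x, ...) {
  cat(sprintf("fusion_experiment: %d combinations over %d days\n",
              length(x$runs), x$manifest$n_days))
  for (nm in names(x$runs)) {
    st <- x$runs[[nm]]$station_summary
    dm <- x$runs[[nm]]$domain_summary
    cat(sprintf(
      "  %-22s station: %.2f ug/l (rel SD %5.1f%%)  domain: %.2f ug/l (rel SD %5.1f%%)\n",
      nm, st$mean_chl, st$relative_sd, dm$mean_chl, dm$relative_sd))
  }
  invisible(x)
}

#' Period-summary table of an experiment
#'
#' Flattens the station and domain period summaries of all stream
#' combinations into one data frame, the tabular product used to compare
#' monitoring designs.
#'
#' @param experiment a \code{fusion_experiment}.
#' @return data frame with columns \code{combination}, \code{scope},
#'   \code{mean_chl}, \code{sd}, \code{relative_sd}.
#' @export
experiment_table <- function(experiment) {
  stopifnot(inherits(experiment, "fusion_experiment"))
  rows <- lapply(names(experiment$runs), function(nm) {
    r <- experiment$runs[[nm]]
    do.call(rbind, lapply(
      list(c("routine_station", "station_summary"),
           c("automatic_station", "automatic_summary"),
           c("domain", "domain_summary")),
      function(sc) {
        s <- r[[sc[2]]]
        data.frame(combination = nm, scope = sc[1], mean_chl = s$mean_chl,
                   sd = s$sd, relative_sd = s$relative_sd)
      }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
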