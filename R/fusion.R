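#' Spherical spatial correlation matrix of the state
#'
#' Entry (i, j) is \code{1 - (1.5 h/l - 0.5 (h/l)^3)} for center distance
#' \code{h < l} and 0 beyond: the compactly supported isotropic spherical
#' model. Symmetric with unit diagonal. The state covariance of the fusion
#' model is \code{sigma_s^2} times this matrix.
#'
#' @param grid a \code{lake_grid}.
#' @param l correlation length in metres.
#' @return \code{n_cells x n_cells} correlation matrix.
#' @export
build_state_correlation <- function(grid, l) {
  stopifnot(inherits(grid, "lake_grid"), l > 0)
  h <- as.matrix(stats::dist(grid$cell_centers))
  x <- pmin(h / l, 1)
  C <- 1 - (1.5 * x - 0.5 * x^3)
  C[h >= l] <- 0
  diag(C) <- 1
  C
}

# Upper-triangular Cholesky factor of the state correlation, with a
# jitter-and-retry ladder for near-singular geometries (duplicate centers,
# very dense grids relative to l).
state_cholesky <- function(C) {
  for (jit in c(0, 1e-10, 1e-8, 1e-6)) {
    Cj <- C
    if (jit > 0) diag(Cj) <- diag(Cj) + jit
    L <- tryCatch(chol(Cj), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("state correlation matrix is not positive definite even after ",
       "jitter; check for coincident cell centers")
}

# N draws from N(0, sd^2 * C) given the upper Cholesky factor of C,
# returned as an N x n matrix.
draw_correlated <- function(n_draws, L, sd) {
  n <- ncol(L)
  if (sd == 0) return(matrix(0, n_draws, n))
  matrix(stats::rnorm(n_draws * n), n_draws, n) %*% L * sd
}

#' Initialize the log-space ensemble from the stationary prior
#'
#' Members are drawn from a multivariate normal with mean \code{log(mu_b)} in
#' every cell and covariance \code{sigma_s^2 C(l)} — the no-data state in
#' which predicted uncertainty coincides with the historical variability of
#' the lake.
#'
#' @param grid a \code{lake_grid}.
#' @param config a \code{fusion_config}.
#' @param chol_C optional precomputed Cholesky factor of the correlation
#'   matrix (recomputed from the grid when missing).
#' @return an object of class \code{ensemble_state}: list with \code{members}
#'   (\code{ensemble_size x n_cells} matrix of log-concentrations) and
#'   \code{day = 1}.
#' @export
initialize_ensemble <- function(grid, config, chol_C = NULL) {
  stopifnot(inherits(grid, "lake_grid"), inherits(config, "fusion_config"))
  if (is.null(chol_C)) chol_C <- state_cholesky(build_state_correlation(grid, config$l))
  members <- log(config$mu_b) +
    draw_correlated(config$ensemble_size, chol_C, config$sigma_s)
  structure(list(members = members, day = 1L), class = "ensemble_state")
}

#' @export
print.ensemble_state <- function(x, ...) {
  cat(sprintf("ensemble_state: day %d, %d members x %d cells\n",
              x$day, nrow(x$members), ncol(x$members)))
  invisible(x)
}

#' Propagate the ensemble one day forward
#'
#' Applies the mean-reverting dynamics in log space,
#' \code{m -> alpha * (m - log(mu_b)) + log(mu_b)}, and adds an innovation
#' drawn from \code{N(0, (1 - alpha^2) sigma_s^2 C)}. The innovation scaling
#' makes the stationary marginal covariance equal to the spherical state
#' covariance, so with no data the predicted spread stays at the historical
#' variability.
#'
#' @param state an \code{ensemble_state}.
#' @param config a \code{fusion_config}.
#' @param chol_C optional precomputed Cholesky factor of the correlation
#'   matrix; required here (pass it from the calling loop) unless a
#'   \code{grid} is supplied.
#' @param grid optional \code{lake_grid} used to build the factor when
#'   \code{chol_C} is missing.
#' @return the forecast \code{ensemble_state} at \code{day + 1}.
#' @export
propagate <- function(state, config, chol_C = NULL, grid = NULL) {
  stopifnot(inherits(state, "ensemble_state"), inherits(config, "fusion_config"))
  if (is.null(chol_C)) {
    if (is.null(grid)) stop("supply chol_C or grid")
    chol_C <- state_cholesky(build_state_correlation(grid, config$l))
  }
  mu <- log(config$mu_b)
  innov_sd <- config$sigma_s * sqrt(1 - config$alpha^2)
  members <- mu + config$alpha * (state$members - mu) +
    draw_correlated(nrow(state$members), chol_C, innov_sd)
  structure(list(members = members, day = state$day + 1L),
            class = "ensemble_state")
}

#' Assimilate one day's observations (stochastic ensemble Kalman update)
#'
#' Perturbed-observation analysis with identity observation operator: the
#' Kalman gain is formed from the ensemble anomaly covariance at the observed
#' cells and a diagonal observation covariance of squared log-space SDs, and
#' each member is updated against its own perturbed copy of the observations.
#' An empty batch returns the state unchanged.
#'
#' @param state an \code{ensemble_state} (the forecast for the batch's day).
#' @param batch data frame with columns \code{cell}, \code{log_value},
#'   \code{log_sd} (one row per observation; several observations may share a
#'   cell — each keeps its own error).
#' @param config a \code{fusion_config} (unused beyond validation; present so
#'   callers can thread one object through the filter loop).
#' @return the analysis \code{ensemble_state}.
#' @export
assimilate <- function(state, batch, config = NULL) {
  stopifnot(inherits(state, "ensemble_state"))
  if (is.null(batch) || nrow(batch) == 0) return(state)
  stopifnot(all(c("cell", "log_value", "log_sd") %in% names(batch)),
            all(batch$log_sd > 0),
            all(batch$cell >= 1), all(batch$cell <= ncol(state$members)))
  A <- state$members
  N <- nrow(A)
  idx <- batch$cell
  Ac <- sweep(A, 2, colMeans(A))            # anomalies, N x n
  PHt <- crossprod(Ac, Ac[, idx, drop = FALSE]) / (N - 1)   # n x m
  S <- PHt[idx, , drop = FALSE]                              # m x m = HPH'
  diag(S) <- diag(S) + batch$log_sd^2
  K <- t(solve(S, t(PHt)))                                   # n x m
  # perturbed observations: member i sees y + e_i, e_i ~ N(0, R)
  E <- matrix(stats::rnorm(N * length(idx), sd = rep(batch$log_sd, each = N)),
              N, length(idx))
  innov <- sweep(E, 2, batch$log_value, FUN = "+") - A[, idx, drop = FALSE]
  structure(list(members = A + innov %*% t(K), day = state$day),
            class = "ensemble_state")
}

#' Per-cell posterior summary of an ensemble
#'
#' All moments are taken in log space, where the model is Gaussian: with
#' log-mean m and log-SD s per cell, the reported concentration is
#' \code{exp(m)} (the posterior median on the original scale), the 68\%
#' interval is \code{(exp(m - s), exp(m + s))} — asymmetric after
#' back-transformation — and the linear SD is defined as half the interval
#' width, \code{(exp(m + s) - exp(m - s)) / 2 = exp(m) * sinh(s)}.
#'
#' @param state an \code{ensemble_state} with at least 2 members.
#' @return data frame with columns \code{cell}, \code{mean} (ug/l),
#'   \code{log_sd}, \code{ci68_low}, \code{ci68_high}, \code{sd_linear}.
#' @export
summarize_ensemble <- function(state) {
  stopifnot(inherits(state, "ensemble_state"), nrow(state$members) >= 2)
  m <- colMeans(state$members)
  s <- apply(state$members, 2, stats::sd)
  data.frame(cell = seq_along(m), mean = exp(m), log_sd = s,
             ci68_low = exp(m - s), ci68_high = exp(m + s),
             sd_linear = (exp(m + s) - exp(m - s)) / 2)
}

# Split an observation table into per-day batches in log space.
# Values are floored at config$floor_ugL before the log transform; log-space
# SDs come from the per-source relative SDs unless a rel_sd column overrides.
observation_batches <- function(observations, config, n_days) {
  if (is.null(observations) || nrow(observations) == 0) {
    return(replicate(n_days, NULL, simplify = FALSE))
  }
  obs <- as.data.frame(observations)
  stopifnot(all(c("day", "cell", "value", "source") %in% names(obs)))
  if (any(obs$day < 1 | obs$day > n_days)) {
    stop("observation days outside 1..n_days")
  }
  rel <- if ("rel_sd" %in% names(obs)) obs$rel_sd else {
    unknown <- setdiff(unique(obs$source), names(config$sigma_o))
    if (length(unknown)) {
      stop("unknown observation source(s): ", paste(unknown, collapse = ", "))
    }
    unname(config$sigma_o[obs$source])
  }
  obs$log_value <- log(pmax(obs$value, config$floor_ugL))
  obs$log_sd <- cv_to_log_sd(rel)
  lapply(seq_len(n_days), function(k) obs[obs$day == k, , drop = FALSE])
}

#' Run the ensemble Kalman filter over a monitoring season
#'
#' Initializes the ensemble from the stationary no-data prior, then for every
#' day propagates the state and assimilates that day's observations (possibly
#' none). The whole run is seeded from \code{config$seed}, so identical
#' inputs give bit-identical output.
#'
#' @param observations data frame with columns \code{day} (integer 1..n_days),
#'   \code{cell} (water-cell index), \code{value} (ug/l) and \code{source}
#'   (matched against \code{names(config$sigma_o)}); an optional \code{rel_sd}
#'   column overrides the per-source relative SD. May be NULL or empty for a
#'   no-data run.
#' @param grid a \code{lake_grid}.
#' @param config a \code{fusion_config}.
#' @param n_days number of daily steps.
#' @param keep_ensembles keep the forecast and analysis member matrices
#'   (needed by \code{\link{run_smoother}}); set FALSE to save memory when
#'   only filter products are wanted.
#' @return an object of class \code{fusion_fit}: list with the filter
#'   \code{product} (data frame: day, cell, mean, log_sd, ci68_low, ci68_high,
#'   sd_linear, phase = "filter"), per-day observation counts, and, when kept,
#'   the \code{forecasts} and \code{analyses} ensembles.
#' @export
run_filter <- function(observations, grid, config, n_days,
                       keep_ensembles = TRUE) {
  stopifnot(inherits(grid, "lake_grid"), inherits(config, "fusion_config"),
            n_days >= 1)
  batches <- observation_batches(observations, config, n_days)
  chol_C <- state_cholesky(build_state_correlation(grid, config$l))

  set.seed(config$seed)
  forecasts <- if (keep_ensembles) vector("list", n_days) else NULL
  analyses <- if (keep_ensembles) vector("list", n_days) else NULL
  summaries <- vector("list", n_days)
  n_obs <- integer(n_days)

  state <- initialize_ensemble(grid, config, chol_C)  # forecast for day 1
  for (k in seq_len(n_days)) {
    if (k > 1) state <- propagate(state, config, chol_C)
    if (keep_ensembles) forecasts[[k]] <- state$members
    state <- assimilate(state, batches[[k]], config)
    if (keep_ensembles) analyses[[k]] <- state$members
    n_obs[k] <- if (is.null(batches[[k]])) 0L else nrow(batches[[k]])
    s <- summarize_ensemble(state)
    s$day <- k
    summaries[[k]] <- s
  }
  product <- do.call(rbind, summaries)
  product$phase <- "filter"
  structure(list(
    product = product[c("day", "cell", "mean", "log_sd", "ci68_low",
                        "ci68_high", "sd_linear", "phase")],
    grid = grid, config = config, n_days = n_days, n_obs = n_obs,
    forecasts = forecasts, analyses = analyses
  ), class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf("fusion_fit: %d days x %d cells, %d observations assimilated\n",
              x$n_days, x$grid$n_cells, sum(x$n_obs)))
  invisible(x)
}

#' Fixed-interval ensemble Kalman smoother
#'
#' Backward recursion over the stored filter ensembles. For day k the smoother
#' gain is the cross-covariance between the day-k analysis and the day-(k+1)
#' forecast times the inverse forecast covariance; each member is corrected by
#' the gain applied to its own smoothed-minus-forecast increment at k+1. The
#' final day's smoother equals the filter analysis, and smoothed variances
#' never exceed filter variances beyond sampling noise.
#'
#' Because the dynamics are linear with known drift and innovation covariance,
#' the cross-covariance is evaluated analytically from the ensemble analysis
#' covariance (\code{alpha Pa}) and the forecast covariance as
#' \code{alpha^2 Pa + Q}, rather than from raw sample cross-moments. The two
#' coincide in expectation; the analytic form avoids inverting a sample
#' covariance whose rank is limited by the ensemble size, which otherwise
#' collapses the smoothed spread when the ensemble is not much larger than the
#' number of cells.
#'
#' @param fit a \code{fusion_fit} from \code{\link{run_filter}} with
#'   \code{keep_ensembles = TRUE}.
#' @return data frame of the same shape as the filter product with
#'   \code{phase = "smoother"}.
#' @export
run_smoother <- function(fit) {
  stopifnot(inherits(fit, "fusion_fit"))
  if (is.null(fit$analyses) || is.null(fit$forecasts)) {
    stop("run_filter must be called with keep_ensembles = TRUE")
  }
  n_days <- fit$n_days
  cfg <- fit$config
  Q <- (1 - cfg$alpha^2) * cfg$sigma_s^2 *
    build_state_correlation(fit$grid, cfg$l)
  smoothed <- fit$analyses[[n_days]]
  out <- vector("list", n_days)
  out[[n_days]] <- smoothed
  for (k in seq_len(n_days - 1)) {
    j <- n_days - k            # days n_days-1 .. 1
    Xa <- fit$analyses[[j]]
    Xf <- fit$forecasts[[j + 1]]
    N <- nrow(Xa)
    Aa <- sweep(Xa, 2, colMeans(Xa))
    Pa <- crossprod(Aa) / (N - 1)
    Pf <- cfg$alpha^2 * Pa + Q             # forecast covariance, full rank
    J <- cfg$alpha * t(solve(Pf, Pa))      # n x n smoother gain
    smoothed <- Xa + (smoothed - Xf) %*% t(J)
    out[[j]] <- smoothed
  }
  summaries <- lapply(seq_len(n_days), function(k) {
    s <- summarize_ensemble(structure(list(members = out[[k]], day = k),
                                      class = "ensemble_state"))
    s$day <- k
    s
  })
  product <- do.call(rbind, summaries)
  product$phase <- "smoother"
  product[c("day", "cell", "mean", "log_sd", "ci68_low", "ci68_high",
            "sd_linear", "phase")]
}
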