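test_that("noise-free configuration gives a constant field at the background mean", {
  g <- grid_3x3()
  cfg <- fusion_config(sigma_s = 0, alpha = 0, ensemble_size = 10)
  tr <- simulate_truth(g, cfg, bloom = NULL, n_days = 5, seed = 1)
  expect_equal(unname(tr$values), matrix(6.2, 5, 9))
  expect_equal(tr$log_values, log(tr$values))
})

test_that("truth values are strictly positive and reproducible under a seed", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 10)
  tr1 <- simulate_truth(g, cfg, n_days = 40, seed = 11)
  tr2 <- simulate_truth(g, cfg, n_days = 40, seed = 11)
  tr3 <- simulate_truth(g, cfg, n_days = 40, seed = 12)
  expect_identical(tr1$values, tr2$values)
  expect_false(identical(tr1$values, tr3$values))
  expect_true(all(tr1$values > 0))
})

test_that("log-truth at one cell has the AR(1) stationary variance and lag-1 autocorrelation", {
  g <- grid_1cell()
  cfg <- fusion_config(ensemble_size = 10)
  n <- 20000
  tr <- simulate_truth(g, cfg, bloom = NULL, n_days = n, seed = 2)
  x <- tr$log_values[, 1]
  # stationary AR(1) closed forms: mean log(mu_b), var sigma_s^2, lag-1
  # cor alpha. With alpha = 0.97 the effective sample size is
  # n (1-alpha)/(1+alpha) ~ 305; bounds are ~3 Monte-Carlo SEs:
  # SE(mean) = sigma_s sqrt((1+a)/((1-a) n)) ~ 0.068,
  # SE(var) ~ sigma_s^2 sqrt(2/305) ~ 0.11, SE(r1) ~ sqrt((1-a^2)/n) ~ 0.002
  expect_lt(abs(mean(x) - log(6.2)), 0.21)
  expect_lt(abs(var(x) - cfg$sigma_s^2), 0.35)
  r1 <- cor(x[-1], x[-n])
  expect_lt(abs(r1 - cfg$alpha), 0.01)
})

test_that("the bloom adds a log-space bump of the stated amplitude at the peak day", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 10)
  b <- bloom_spec(peak_day = 20, amplitude = log(3), duration = 16)
  tr0 <- simulate_truth(g, cfg, bloom = NULL, n_days = 40, seed = 7)
  tr1 <- simulate_truth(g, cfg, bloom = b, n_days = 40, seed = 7)
  bump <- tr1$log_values - tr0$log_values
  expect_equal(unname(bump[20, ]), rep(log(3), 9))
  # ~95% of the excess within the stated duration
  expect_lt(max(bump[c(1:11, 29:40), ]), 0.15 * log(3))
})

test_that("observation counts follow the design", {
  g <- make_grid(square_outline(6000), 600, 500)  # 64 cells
  cfg <- fusion_config(ensemble_size = 10)
  tr <- simulate_truth(g, cfg, n_days = 153, seed = 3)
  d <- sampling_design(g)  # 8 EO days, cloud fraction 0
  obs <- sample_observations(tr, d, seed = 4)
  expect_equal(sum(obs$source == "eo"), 8 * 64)
  expect_equal(sum(obs$source == "routine"), length(d$routine_days))
  expect_equal(sum(obs$source == "automatic"), length(d$automatic_days))
  expect_true(all(obs$value > 0))
  # stations must be distinct cells ~900 m apart
  expect_false(d$routine_cell == d$automatic_cell)
  dd <- sqrt(sum((g$cell_centers[d$routine_cell, ] -
                    g$cell_centers[d$automatic_cell, ])^2))
  expect_lt(abs(dd - 900), 600)
})

test_that("zero relative error reproduces the truth exactly", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 10)
  tr <- simulate_truth(g, cfg, n_days = 20, seed = 5)
  d <- sampling_design(g, routine_days = c(2, 10), automatic_days = 1:20,
                       eo_days = c(6, 15),
                       rel_sd = c(routine = 0, automatic = 0, eo = 0))
  obs <- sample_observations(tr, d, seed = 6)
  expect_equal(obs$value, tr$values[cbind(obs$day, obs$cell)])
})

test_that("observation noise is lognormal with log-SD sqrt(log(1+cv^2)) and unbiased in log space", {
  g <- grid_1cell()
  cfg <- fusion_config(ensemble_size = 10)
  tr <- simulate_truth(g, cfg, n_days = 4000, seed = 8)
  d <- sampling_design(g, routine_cell = 1, automatic_cell = 1,
                       routine_days = integer(0), automatic_days = integer(0),
                       eo_days = 1:4000)
  obs <- sample_observations(tr, d, seed = 9)
  lr <- log(obs$value) - tr$log_values[cbind(obs$day, obs$cell)]
  s_expected <- sqrt(log(1 + 0.34^2))
  expect_equal(sd(lr), s_expected, tolerance = 0.02)   # ~3 SE at n = 4000
  expect_lt(abs(mean(lr)), 3 * s_expected / sqrt(4000))
})

test_that("cloud fraction drops whole satellite days", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 10)
  tr <- simulate_truth(g, cfg, n_days = 50, seed = 10)
  d <- sampling_design(g, routine_days = integer(0),
                       automatic_days = integer(0),
                       eo_days = seq(5, 50, by = 5), eo_cloud_fraction = 1)
  obs <- sample_observations(tr, d, seed = 11)
  expect_equal(nrow(obs), 0)
})

test_that("raw streams invert the calibrations exactly in the zero-noise limit", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 10)
  tr <- simulate_truth(g, cfg, n_days = 153, seed = 12)
  d <- sampling_design(g, rel_sd = c(routine = 0, automatic = 0, eo = 0))
  raw <- synthesize_raw_streams(tr, d, seed = 13)
  # fluorometer round trip
  rec <- correct_fluorometer(raw$sensor$chl_sensor, raw$sensor$cb_sensor)
  expect_equal(rec, raw$sensor$chl_true, tolerance = 1e-12)
  # satellite round trip (unclipped pixels)
  for (i in seq_along(raw$eo$days)) {
    cal <- calibrate_eo(raw$eo$raw_values[[i]])
    truth_day <- tr$values[raw$eo$days[i], ]
    unclipped <- raw$eo$raw_values[[i]] > 0
    expect_equal(cal[unclipped], truth_day[unclipped], tolerance = 1e-12)
  }
  # cyanobacteria ramp: zero before mid-July (day 77), positive in late August
  expect_true(all(raw$sensor$cb_sensor[raw$sensor$day < 77] == 0))
  expect_true(all(raw$sensor$cb_sensor[raw$sensor$day >= 123] > 0))
})

test_that("design days outside the truth range are rejected", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 10)
  tr <- simulate_truth(g, cfg, n_days = 10, seed = 14)
  d <- sampling_design(g, routine_days = c(5, 20), automatic_days = 1:10,
                       eo_days = integer(0))
  expect_error(sample_observations(tr, d, seed = 1), "day range")
})
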