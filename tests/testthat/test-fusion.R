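test_that("the state correlation is the spherical model with unit diagonal and compact support", {
  g2 <- make_grid(square_outline(c(1200, 600)), 600, 0)  # two cells 600 m apart
  C <- build_state_correlation(g2, l = 1200)   # h = l/2
  expect_equal(unname(diag(C)), c(1, 1))
  expect_equal(C[1, 2], 0.3125)                # 1 - (3/4 - 1/16)
  expect_equal(C[1, 2], C[2, 1])
  C0 <- build_state_correlation(g2, l = 600)   # h >= l
  expect_equal(C0[1, 2], 0)
  C3 <- build_state_correlation(grid_3x3(), l = 8000)
  expect_true(all(eigen(C3, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("ensemble initialization draws from the stationary prior", {
  g <- grid_3x3()
  cfg0 <- fusion_config(sigma_s = 0, ensemble_size = 20)
  set.seed(1)
  st0 <- initialize_ensemble(g, cfg0)
  expect_true(all(st0$members == log(6.2)))

  cfg <- fusion_config(ensemble_size = 500)
  set.seed(2)
  st <- initialize_ensemble(g, cfg)
  # per-cell mean within ~3 CLT standard errors sigma_s/sqrt(500)
  expect_true(all(abs(colMeans(st$members) - log(6.2)) <
                    3.5 * cfg$sigma_s / sqrt(500)))
  # sample covariance on two cells approaches sigma_s^2 * C
  g2 <- make_grid(square_outline(c(1200, 600)), 600, 0)
  cfg_big <- fusion_config(ensemble_size = 20000)
  set.seed(3)
  st2 <- initialize_ensemble(g2, cfg_big)
  S <- cov(st2$members)
  C <- build_state_correlation(g2, cfg_big$l)
  expect_equal(S / cfg_big$sigma_s^2, C, tolerance = 0.05)
})

test_that("propagation is the mean-reverting AR(1) map with stationary spread", {
  g <- grid_3x3()
  # alpha = 1, sigma_s = 0: identity
  cfg1 <- fusion_config(alpha = 1, sigma_s = 0, ensemble_size = 5)
  st <- structure(list(members = matrix(rnorm(45), 5, 9), day = 1L),
                  class = "ensemble_state")
  set.seed(4)
  expect_equal(propagate(st, cfg1, grid = g)$members, st$members)
  # alpha = 0: full reversion plus full-variance noise
  cfg0 <- fusion_config(alpha = 0, ensemble_size = 4000)
  st0 <- structure(list(members = matrix(5, 4000, 9), day = 1L),
                   class = "ensemble_state")
  set.seed(5)
  pr <- propagate(st0, cfg0, grid = g)
  expect_true(all(abs(colMeans(pr$members) - log(6.2)) <
                    3.5 * cfg0$sigma_s / sqrt(4000)))
  expect_equal(unname(apply(pr$members, 2, sd)), rep(cfg0$sigma_s, 9),
               tolerance = 0.05)
  # repeated propagation keeps the per-cell log-variance at sigma_s^2
  cfg <- fusion_config(ensemble_size = 2000)
  set.seed(6)
  state <- initialize_ensemble(g, cfg)
  L <- chol(build_state_correlation(g, cfg$l))
  for (k in 1:60) state <- propagate(state, cfg, L)
  expect_equal(unname(apply(state$members, 2, sd)), rep(cfg$sigma_s, 9),
               tolerance = 0.08)
  expect_equal(state$day, 61L)
})

test_that("an empty batch leaves the state unchanged", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 30)
  set.seed(7)
  st <- initialize_ensemble(g, cfg)
  expect_identical(assimilate(st, NULL), st)
  empty <- data.frame(cell = integer(0), log_value = numeric(0),
                      log_sd = numeric(0))
  expect_identical(assimilate(st, empty), st)
})

test_that("a single-cell update matches the conjugate normal posterior", {
  g <- grid_1cell()
  cfg <- fusion_config(ensemble_size = 1e5)
  set.seed(8)
  st <- initialize_ensemble(g, cfg)
  y <- log(12)
  s_o <- 0.3
  batch <- data.frame(cell = 1L, log_value = y, log_sd = s_o)
  post <- assimilate(st, batch)
  # closed-form conjugate update with the ensemble's own prior moments
  m0 <- mean(st$members)
  v0 <- var(as.vector(st$members))
  m_exact <- (y / s_o^2 + m0 / v0) / (1 / s_o^2 + 1 / v0)
  v_exact <- 1 / (1 / s_o^2 + 1 / v0)
  expect_equal(mean(post$members), m_exact, tolerance = 0.005)
  expect_equal(var(as.vector(post$members)), v_exact, tolerance = 0.01)
})

test_that("a near-exact observation pins the posterior to the observed value", {
  g <- grid_1cell()
  cfg <- fusion_config(ensemble_size = 2000)
  set.seed(9)
  st <- initialize_ensemble(g, cfg)
  batch <- data.frame(cell = 1L, log_value = log(15), log_sd = 1e-6)
  post <- assimilate(st, batch)
  expect_equal(unname(mean(post$members)), log(15), tolerance = 1e-4)
  expect_lt(sd(post$members), 1e-4)
})

test_that("the filter tracks daily exact observations on a single cell", {
  g <- grid_1cell()
  cfg <- fusion_config(ensemble_size = 200, seed = 10)
  vals <- exp(log(6.2) + sin(1:15 / 3))
  obs <- data.frame(day = 1:15, cell = 1L, value = vals, source = "routine",
                    rel_sd = 1e-4)
  fit <- run_filter(obs, g, cfg, 15)
  expect_equal(fit$product$mean, vals, tolerance = 1e-3)
})

test_that("filter and smoother moments match the exact Kalman filter and RTS smoother", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 5000, seed = 11)
  n_days <- 10
  set.seed(12)
  obs <- data.frame(
    day = c(2, 2, 5, 8, rep(4, 9)),
    cell = c(1, 5, 9, 3, 1:9),
    value = exp(log(6.2) + rnorm(13, 0, 0.8)),
    source = c("routine", "routine", "automatic", "routine", rep("eo", 9))
  )
  fit <- run_filter(obs, g, cfg, n_days)
  sm <- run_smoother(fit)
  oracle <- exact_kfs(with_log_columns(obs, cfg), 9,
                      build_state_correlation(g, cfg$l),
                      log(cfg$mu_b), cfg$sigma_s, cfg$alpha, n_days)
  # ensemble sampling error at N = 5000 is ~1.5% of a log-SD <= sigma_s;
  # tolerances are ~3-4 Monte-Carlo standard errors
  fm <- product_matrix(fit$product, "mean", n_days, 9)
  fs <- product_matrix(fit$product, "log_sd", n_days, 9)
  sd_exact_f <- t(sapply(1:n_days, function(k) sqrt(diag(oracle$Pa[[k]]))))
  expect_lt(max(abs(log(fm) - oracle$ma)), 0.06)
  expect_lt(max(abs(fs / sd_exact_f - 1)), 0.06)

  smm <- product_matrix(sm, "mean", n_days, 9)
  sms <- product_matrix(sm, "log_sd", n_days, 9)
  sd_exact_s <- t(sapply(1:n_days, function(k) sqrt(diag(oracle$Ps[[k]]))))
  expect_lt(max(abs(log(smm) - oracle$ms)), 0.06)
  expect_lt(max(abs(sms / sd_exact_s - 1)), 0.08)
})

test_that("the smoother equals the filter on the final day and on no-data runs", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 100, seed = 13)
  obs <- data.frame(day = c(3, 7), cell = c(2, 8), value = c(9, 4),
                    source = "routine")
  fit <- run_filter(obs, g, cfg, 12)
  sm <- run_smoother(fit)
  last_f <- fit$product[fit$product$day == 12, ]
  last_s <- sm[sm$day == 12, ]
  expect_equal(last_s$mean, last_f$mean)
  expect_equal(last_s$log_sd, last_f$log_sd)
  # with no observations the backward pass has nothing to propagate:
  # smoother and filter coincide exactly
  fit0 <- run_filter(NULL, g, cfg, 12)
  sm0 <- run_smoother(fit0)
  expect_equal(sm0$mean, fit0$product$mean)
  expect_equal(sm0$log_sd, fit0$product$log_sd)
})

test_that("assimilation reduces variance at observed cells and smoothing never inflates it", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 1000, seed = 14)
  obs <- data.frame(day = c(rep(4, 9), 8), cell = c(1:9, 5),
                    value = exp(log(6.2) + c(rnorm(9, 0, 0.5), 0.3)),
                    source = c(rep("eo", 9), "routine"))
  fit <- run_filter(obs, g, cfg, 10)
  for (k in c(4, 8)) {
    fvar <- apply(fit$forecasts[[k]], 2, var)
    avar <- apply(fit$analyses[[k]], 2, var)
    cells <- obs$cell[obs$day == k]
    expect_true(all(avar[cells] <= fvar[cells]))
  }
  sm <- run_smoother(fit)
  # smoother log-SD <= filter log-SD within ~3 MC standard errors
  slack <- 3 * cfg$sigma_s / sqrt(2 * (cfg$ensemble_size - 1))
  expect_true(all(sm$log_sd <= fit$product$log_sd + slack))
})

test_that("all reported concentrations and interval bounds are strictly positive", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 100, seed = 15)
  obs <- data.frame(day = c(2, 5), cell = c(1, 9), value = c(0.05, 40),
                    source = "routine")  # one value below the floor
  fit <- run_filter(obs, g, cfg, 6)
  sm <- run_smoother(fit)
  for (p in list(fit$product, sm)) {
    expect_true(all(p$mean > 0))
    expect_true(all(p$ci68_low > 0))
    expect_true(all(p$ci68_high > p$ci68_low))
    expect_true(all(p$ci68_low < p$mean & p$mean < p$ci68_high))
    # asymmetry of the back-transformed interval
    expect_true(all(p$ci68_high - p$mean >= p$mean - p$ci68_low - 1e-12))
  }
})

test_that("ensemble summaries back-transform log moments as documented", {
  # all members identical
  st <- structure(list(members = matrix(log(10), 50, 2), day = 1L),
                  class = "ensemble_state")
  s <- summarize_ensemble(st)
  expect_equal(s$mean, c(10, 10))
  expect_equal(s$ci68_low, c(10, 10))
  expect_equal(s$sd_linear, c(0, 0))
  # exact mean m and SD s via standardized members: m = 0, s = log 2
  z <- as.vector(scale(rnorm(400)))
  st2 <- structure(list(members = matrix(0 + log(2) * z, 400, 1), day = 1L),
                   class = "ensemble_state")
  s2 <- summarize_ensemble(st2)
  expect_equal(s2$mean, 1)
  expect_equal(s2$ci68_low, 0.5)
  expect_equal(s2$ci68_high, 2)
  expect_equal(s2$sd_linear, 0.75)
  # the configured no-data bound: m = log(6.2), s = log(20/6.2)
  st3 <- structure(list(members = matrix(log(6.2) + log(20 / 6.2) * z, 400, 1),
                        day = 1L), class = "ensemble_state")
  expect_equal(summarize_ensemble(st3)$ci68_high, 20)
})

test_that("identical seed and config give bit-identical filter products", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 50, seed = 16)
  obs <- data.frame(day = c(2, 6), cell = c(3, 7), value = c(8, 5),
                    source = "routine")
  f1 <- run_filter(obs, g, cfg, 8)
  f2 <- run_filter(obs, g, cfg, 8)
  expect_identical(f1$product, f2$product)
})

test_that("observations referencing unknown sources or days are rejected", {
  g <- grid_3x3()
  cfg <- fusion_config(ensemble_size = 20)
  bad_source <- data.frame(day = 1, cell = 1, value = 5, source = "drone")
  expect_error(run_filter(bad_source, g, cfg, 5), "unknown observation source")
  bad_day <- data.frame(day = 9, cell = 1, value = 5, source = "routine")
  expect_error(run_filter(bad_day, g, cfg, 5), "outside")
})
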