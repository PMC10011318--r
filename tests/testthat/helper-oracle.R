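# Independent exact linear-Gaussian Kalman filter and RTS smoother in log
# space, written directly from the closed-form recursions (dense matrices, no
# ensembles). Used as the oracle the ensemble implementations must converge
# to on small grids.
exact_kfs <- function(obs, n_cells, C, mu, sigma_s, alpha, n_days) {
  Q <- (1 - alpha^2) * sigma_s^2 * C
  P <- sigma_s^2 * C
  m <- rep(mu, n_cells)
  mf <- ma <- matrix(NA_real_, n_days, n_cells)
  Pf <- Pa <- vector("list", n_days)
  for (k in seq_len(n_days)) {
    if (k > 1) {
      m <- mu + alpha * (m - mu)
      P <- alpha^2 * P + Q
    }
    mf[k, ] <- m
    Pf[[k]] <- P
    b <- obs[obs$day == k, , drop = FALSE]
    if (nrow(b)) {
      H <- matrix(0, nrow(b), n_cells)
      H[cbind(seq_len(nrow(b)), b$cell)] <- 1
      S <- H %*% P %*% t(H) + diag(b$log_sd^2, nrow(b))
      K <- P %*% t(H) %*% solve(S)
      m <- m + as.vector(K %*% (b$log_value - H %*% m))
      P <- P - K %*% H %*% P
      P <- (P + t(P)) / 2
    }
    ma[k, ] <- m
    Pa[[k]] <- P
  }
  ms <- ma
  Ps <- Pa
  if (n_days > 1) {
    for (k in (n_days - 1):1) {
      J <- alpha * Pa[[k]] %*% solve(Pf[[k + 1]])
      ms[k, ] <- ma[k, ] + as.vector(J %*% (ms[k + 1, ] - mf[k + 1, ]))
      Ps[[k]] <- Pa[[k]] + J %*% (Ps[[k + 1]] - Pf[[k + 1]]) %*% t(J)
    }
  }
  list(mf = mf, ma = ma, ms = ms, Pf = Pf, Pa = Pa, Ps = Ps)
}

# log-space observation columns the way the filter derives them
with_log_columns <- function(obs, config) {
  obs$log_value <- log(pmax(obs$value, config$floor_ugL))
  obs$log_sd <- cv_to_log_sd(unname(config$sigma_o[obs$source]))
  obs
}

# small square grids used across tests
grid_3x3 <- function() make_grid(square_outline(1800), 600, 0)
grid_1cell <- function() make_grid(square_outline(600), 600, 0)

# reshape a product data frame into a days x cells matrix of one column
product_matrix <- function(product, column, n_days, n_cells) {
  m <- matrix(NA_real_, n_days, n_cells)
  m[cbind(product$day, product$cell)] <- product[[column]]
  m
}
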