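# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: grid integration instead of MCMC,
# double loops instead of vectorized sums, raw-sample pooling instead of
# moment algebra.

# Deterministic grid integration of the two-source mixing posterior
# (residual SD fixed), returning the posterior mean of p.
grid_posterior_mean_k2 <- function(consumers, sources, resid_sd,
                                   alpha = c(1, 1), n_grid = 2001) {
  p1 <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  log_post <- vapply(p1, function(pp) {
    p <- c(pp, 1 - pp)
    mu_c <- sum(p * sources$mean_c13)
    mu_n <- sum(p * sources$mean_n15)
    v_c <- sum(p^2 * sources$sd_c13^2) + resid_sd[1]^2
    v_n <- sum(p^2 * sources$sd_n15^2) + resid_sd[2]^2
    sum(dnorm(consumers$d13C, mu_c, sqrt(v_c), log = TRUE)) +
      sum(dnorm(consumers$d15N, mu_n, sqrt(v_n), log = TRUE)) +
      (alpha[1] - 1) * log(pp) + (alpha[2] - 1) * log(1 - pp)
  }, 0)
  w <- exp(log_post - max(log_post))
  w <- w / sum(w)
  m1 <- sum(w * p1)
  c(m1, 1 - m1)
}

# Same, for three sources on a barycentric grid.
grid_posterior_mean_k3 <- function(consumers, sources, resid_sd,
                                   alpha = c(1, 1, 1), n_grid = 201) {
  s <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  grid <- expand.grid(p1 = s, p2 = s)
  grid <- grid[grid$p1 + grid$p2 < 1 - 1e-6, ]
  lp <- mapply(function(p1, p2) {
    p <- c(p1, p2, 1 - p1 - p2)
    mu_c <- sum(p * sources$mean_c13)
    mu_n <- sum(p * sources$mean_n15)
    v_c <- sum(p^2 * sources$sd_c13^2) + resid_sd[1]^2
    v_n <- sum(p^2 * sources$sd_n15^2) + resid_sd[2]^2
    sum(dnorm(consumers$d13C, mu_c, sqrt(v_c), log = TRUE)) +
      sum(dnorm(consumers$d15N, mu_n, sqrt(v_n), log = TRUE)) +
      sum((alpha - 1) * log(p))
  }, grid$p1, grid$p2)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  p1 <- sum(w * grid$p1)
  p2 <- sum(w * grid$p2)
  c(p1, p2, 1 - p1 - p2)
}

# Brute-force double-loop sum-of-squares decomposition.
ss_oracle <- function(values, individual) {
  grand <- mean(values)
  tnw <- 0
  for (v in values) tnw <- tnw + (v - grand)^2
  wic <- 0
  for (id in unique(individual)) {
    vv <- values[individual == id]
    m <- mean(vv)
    for (v in vv) wic <- wic + (v - m)^2
  }
  list(WIC = wic, TNW = tnw, BIC = tnw - wic)
}

# OLS via explicit normal equations.
normal_equations_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Two-isotope sources for quick toys.
toy_sources_k2 <- function() {
  source_table(c("low", "high"), mean_c13 = c(-25, -15),
               sd_c13 = c(1, 1), mean_n15 = c(3, 9), sd_n15 = c(1, 1),
               n = c(10, 10))
}
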