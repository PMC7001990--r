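test_that("forward model identities", {
  src <- toy_sources_k2()
  vertex <- forward_model(c(1, 0), src)
  expect_equal(unname(vertex$mean), c(-25, 3))
  mid <- forward_model(c(0.5, 0.5), src)
  expect_equal(unname(mid$mean[["d13C"]]), -20)
  expect_equal(unname(mid$sd[["d13C"]]), sqrt(0.25 + 0.25),
               tolerance = 1e-12)
  expect_error(forward_model(c(0.7, 0.7), src), "simplex")
})

test_that("draws live on the simplex and the fit is seed-deterministic", {
  src <- toy_sources_k2()
  cons <- data.frame(d13C = c(-21, -20, -19.5), d15N = c(5.5, 6, 6.2))
  sp <- mixing_spec(cons, src, chains = 2, iter = 600, burn = 100,
                    seed = 42)
  post <- fit_mixing_model(sp)
  expect_true(all(abs(rowSums(post$p_draws) - 1) < 1e-9))
  expect_true(all(post$p_draws >= 0))
  post2 <- fit_mixing_model(sp)
  expect_identical(post$p_draws, post2$p_draws)
})

test_that("near-vertex consumers recover the dominant source", {
  src <- source_table(c("a", "b"), c(-25, -15), c(0.3, 0.3),
                      c(3, 9), c(0.3, 0.3), c(10, 10))
  set.seed(8)
  cons <- data.frame(d13C = rnorm(25, -25, 0.2), d15N = rnorm(25, 3, 0.2))
  sp <- mixing_spec(cons, src, resid_sd = 0.2, chains = 2, iter = 3000,
                    burn = 500, seed = 5)
  post <- fit_mixing_model(sp)
  pm <- colMeans(post$p_draws)
  expect_gt(pm[["a"]], 0.95)
  oracle <- grid_posterior_mean_k2(cons, src, resid_sd = c(0.2, 0.2))
  expect_equal(unname(pm), oracle, tolerance = 0.03)
})

test_that("symmetric midpoint setup yields p close to 1/2", {
  src <- toy_sources_k2()
  cons <- data.frame(d13C = rep(-20, 20), d15N = rep(6, 20))
  sp <- mixing_spec(cons, src, resid_sd = 1, chains = 2, iter = 3000,
                    burn = 500, seed = 9)
  post <- fit_mixing_model(sp)
  expect_equal(unname(colMeans(post$p_draws)), c(0.5, 0.5),
               tolerance = 0.03)
})

test_that("grid-integration oracle agreement on K = 2 and K = 3 toys", {
  src2 <- toy_sources_k2()
  set.seed(21)
  cons2 <- data.frame(d13C = rnorm(15, -22, 1), d15N = rnorm(15, 5, 1))
  sp2 <- mixing_spec(cons2, src2, resid_sd = 1, chains = 2, iter = 4000,
                     burn = 1000, seed = 13)
  pm2 <- colMeans(fit_mixing_model(sp2)$p_draws)
  or2 <- grid_posterior_mean_k2(cons2, src2, resid_sd = c(1, 1))
  expect_equal(unname(pm2), or2, tolerance = 0.03)

  src3 <- source_table(c("a", "b", "c"), c(-28, -22, -16), c(1, 1, 1),
                       c(3, 6, 9), c(1, 1, 1), c(10, 10, 10))
  cons3 <- data.frame(d13C = rnorm(15, -22, 1), d15N = rnorm(15, 6.5, 1))
  sp3 <- mixing_spec(cons3, src3, resid_sd = 1, chains = 2, iter = 6000,
                     burn = 1500, seed = 17)
  pm3 <- colMeans(fit_mixing_model(sp3)$p_draws)
  or3 <- grid_posterior_mean_k3(cons3, src3, resid_sd = c(1, 1))
  expect_equal(unname(pm3), or3, tolerance = 0.03)
})

test_that("flat likelihood recovers the Dirichlet prior mean", {
  src <- source_table(c("a", "b", "c"), c(-25, -20, -15), c(1, 1, 1),
                      c(3, 6, 9), c(1, 1, 1), c(5, 5, 5))
  cons <- data.frame(d13C = -20, d15N = 6)
  sp <- mixing_spec(cons, src, resid_sd = 500, chains = 2, iter = 6000,
                    burn = 1500, seed = 3)
  post <- fit_mixing_model(sp)
  expect_equal(unname(colMeans(post$p_draws)), rep(1 / 3, 3),
               tolerance = 0.04)
})

test_that("source order permutation permutes the posterior summaries", {
  src <- source_table(c("a", "b", "c"), c(-27, -21, -16), c(1, 1.2, 0.8),
                      c(3, 6, 8), c(1, 1, 1), c(8, 8, 8))
  set.seed(31)
  cons <- data.frame(d13C = rnorm(20, -21, 1), d15N = rnorm(20, 6, 1))
  fit_means <- function(ss) {
    sp <- mixing_spec(cons, ss, resid_sd = 1, chains = 2, iter = 10000,
                      burn = 1500, seed = 11)
    s <- summarize_posterior(fit_mixing_model(sp), percent = FALSE)
    setNames(s$mean, s$source)
  }
  m1 <- fit_means(src)
  perm <- src[c(3, 1, 2), ]
  class(perm) <- c("source_table", "data.frame")
  m2 <- fit_means(perm)
  # bound ~4x the combined Monte Carlo SE of the two fits; a genuine
  # label-handling defect shifts the means by an order of magnitude more
  expect_lt(max(abs(m1[sort(names(m1))] - m2[sort(names(m2))])), 0.045)
})

test_that("degenerate and invalid specs are handled", {
  one <- source_table("only", -20, 1, 5, 1, 5)
  post <- fit_mixing_model(mixing_spec(data.frame(d13C = -20, d15N = 5),
                                       one))
  expect_equal(unname(colMeans(post$p_draws)), 1)
  src <- toy_sources_k2()
  expect_error(mixing_spec(data.frame(d13C = numeric(),
                                      d15N = numeric()), src),
               "no consumer")
  expect_error(mixing_spec(data.frame(d13C = 1, d15N = 1), src,
                           alpha = c(0, 1)), "> 0")
  sp <- mixing_spec(data.frame(d13C = -20, d15N = 6), src, chains = 1,
                    iter = 300, burn = 100, seed = 1)
  post <- suppressWarnings(fit_mixing_model(sp))
  expect_error(summarize_posterior(post, probs = 0.5)[1, ], NA)
})

test_that("posterior summary moments and percent scale", {
  src <- toy_sources_k2()
  cons <- data.frame(d13C = rep(-20, 10), d15N = rep(6, 10))
  sp <- mixing_spec(cons, src, resid_sd = 1, chains = 2, iter = 1000,
                    burn = 200, seed = 2)
  post <- fit_mixing_model(sp)
  s_pct <- summarize_posterior(post)
  s_prop <- summarize_posterior(post, percent = FALSE)
  expect_equal(s_pct$mean, 100 * s_prop$mean)
  expect_equal(sum(s_prop$mean), 1, tolerance = 1e-9)
  # all-identical draws degenerate summary
  fake <- post
  fake$p_draws <- matrix(c(0.2, 0.8), nrow = 200, ncol = 2, byrow = TRUE,
                         dimnames = list(NULL, c("low", "high")))
  s <- summarize_posterior(fake, percent = FALSE)
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$q50, c(0.2, 0.8))
  fake$p_draws <- fake$p_draws[1:50, ]
  expect_error(summarize_posterior(fake), "too few")
})
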