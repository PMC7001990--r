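#' Deterministic forward model for a two-isotope mixture
#'
#' For a diet proportion vector p over K TDF-corrected sources, the
#' expected consumer tissue value per isotope is the proportion-weighted
#' mean, and the mixture variance is the proportion-squared-weighted sum
#' of the corrected source variances:
#' mean = sum_k p_k mu_k, var = sum_k p_k^2 sigma_k^2.
#'
#' @param p Proportion vector on the K-simplex (checked to 1e-6).
#' @param sources A [source_table()] already in consumer-tissue space
#'   (see [tdf_correct_sources()]).
#' @return List with `mean` and `sd`, each named `c(d13C, d15N)`.
#' @export
forward_model <- function(p, sources) {
  stopifnot(inherits(sources, "source_table"))
  if (length(p) != nrow(sources)) {
    stop("length(p) must equal the number of sources")
  }
  if (any(p < -1e-6) || abs(sum(p) - 1) > 1e-6) {
    stop("p is off the simplex (negative entry or sum != 1)")
  }
  m <- c(d13C = sum(p * sources$mean_c13), d15N = sum(p * sources$mean_n15))
  v <- c(d13C = sum(p^2 * sources$sd_c13^2),
         d15N = sum(p^2 * sources$sd_n15^2))
  list(mean = m, sd = sqrt(v))
}

#' Specification for the Bayesian mixing model
#'
#' Bundles the data and sampler settings of the stable-isotope mixing
#' model.  Consumers enter as one observation per individual (their mean
#' whisker value); sources may be given in diet space together with a
#' [trophic_discrimination()] (applied internally, with optional
#' per-source Delta13C overrides) or already corrected.
#'
#' @param consumers Data frame with columns `d13C` and `d15N`, one row
#'   per consumer.
#' @param sources A [source_table()].
#' @param tdf `NULL` if `sources` is already in consumer-tissue space,
#'   otherwise a [trophic_discrimination()] to apply.
#' @param c13_overrides Passed to [tdf_correct_sources()] (e.g.
#'   `c("human food" = 2.5)` for a keratin-specific value).
#' @param alpha Dirichlet prior concentration: scalar or length-K vector
#'   (default 1: uniform over the simplex).
#' @param resid_sd_scale Scale of the half-Normal prior on the residual
#'   SD per isotope (per mil; default 2).
#' @param resid_sd Optional fixed residual SD (scalar or
#'   `c(d13C, d15N)`); `NULL` (default) estimates it.
#' @param chains,iter,burn,thin MCMC settings (defaults 4 chains of
#'   10000 iterations, 1000 burn-in, no thinning).
#' @param seed Integer seed; the same spec yields identical draws.
#' @return A `mixing_spec` object.
#' @export
mixing_spec <- function(consumers, sources, tdf = NULL, c13_overrides = NULL,
                        alpha = 1, resid_sd_scale = 2, resid_sd = NULL,
                        chains = 4, iter = 10000, burn = 1000, thin = 1,
                        seed = 1) {
  stopifnot(inherits(sources, "source_table"))
  if (!all(c("d13C", "d15N") %in% names(consumers))) {
    stop("consumers must have d13C and d15N columns")
  }
  consumers <- as.data.frame(consumers)[, c("d13C", "d15N")]
  if (!nrow(consumers)) stop("no consumer observations")
  if (anyNA(consumers)) stop("NA in consumer observations")
  if (!is.null(tdf)) {
    sources <- tdf_correct_sources(sources, tdf, c13_overrides)
  }
  K <- nrow(sources)
  alpha <- rep_len(alpha, K)
  if (any(alpha <= 0)) stop("prior concentrations must be > 0")
  if (!is.null(resid_sd)) {
    resid_sd <- rep_len(resid_sd, 2L)
    if (any(resid_sd < 0)) stop("fixed residual SD must be >= 0")
  }
  if (resid_sd_scale <= 0) stop("resid_sd_scale must be > 0")
  if (chains < 1 || iter < 10 || burn < 0 || burn >= iter || thin < 1) {
    stop("invalid MCMC settings")
  }
  # zero-SD sources act as near-delta distributions
  sources$sd_c13 <- pmax(sources$sd_c13, 1e-6)
  sources$sd_n15 <- pmax(sources$sd_n15, 1e-6)
  out <- list(consumers = consumers, sources = sources, alpha = alpha,
              resid_sd_scale = resid_sd_scale, resid_sd = resid_sd,
              chains = as.integer(chains), iter = as.integer(iter),
              burn = as.integer(burn), thin = as.integer(thin),
              seed = as.integer(seed))
  class(out) <- "mixing_spec"
  out
}

# Softmax with a fixed reference coordinate (last one pinned at 0).
.softmax_ref <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

# Log posterior density on the unconstrained scale.
# theta = (z_1..z_{K-1}, [log sig_C, log sig_N]).
# Includes the simplex Jacobian sum(log p) and, when residual SDs are
# estimated, the log-scale Jacobian + half-Normal prior.
.mix_log_post <- function(theta, spec) {
  K <- nrow(spec$sources)
  z <- theta[seq_len(K - 1L)]
  p <- .softmax_ref(z)
  if (any(p < 1e-300)) return(-Inf)
  if (is.null(spec$resid_sd)) {
    sig <- exp(theta[K:(K + 1L)])
  } else {
    sig <- spec$resid_sd
  }
  mu_c <- sum(p * spec$sources$mean_c13)
  mu_n <- sum(p * spec$sources$mean_n15)
  v_c <- sum(p^2 * spec$sources$sd_c13^2) + sig[1L]^2
  v_n <- sum(p^2 * spec$sources$sd_n15^2) + sig[2L]^2
  ll <- sum(stats::dnorm(spec$consumers$d13C, mu_c, sqrt(v_c), log = TRUE)) +
    sum(stats::dnorm(spec$consumers$d15N, mu_n, sqrt(v_n), log = TRUE))
  lp <- sum((spec$alpha - 1) * log(p)) + sum(log(p))  # Dirichlet + Jacobian
  if (is.null(spec$resid_sd)) {
    lp <- lp - sum(sig^2) / (2 * spec$resid_sd_scale^2) + sum(log(sig))
  }
  ll + lp
}

# One adaptive random-walk Metropolis chain.  Early burn-in tunes a
# diagonal proposal scale toward a 0.234 acceptance rate; once enough
# history exists the proposal switches to a scaled empirical-covariance
# (Haario-style adaptive Metropolis) kernel, refreshed periodically.
# All adaptation stops at the end of burn-in.
.mix_chain <- function(spec, n_par, init) {
  iter <- spec$iter
  draws <- matrix(NA_real_, iter, n_par)
  theta <- init
  lp <- .mix_log_post(theta, spec)
  step <- rep(0.5, n_par)
  lambda <- 2.38 / sqrt(n_par)
  chol_cov <- NULL
  t_cov <- max(100L, spec$burn %/% 4L)
  accept <- 0L
  for (t in seq_len(iter)) {
    prop <- if (is.null(chol_cov)) {
      theta + stats::rnorm(n_par, 0, step)
    } else {
      theta + lambda * drop(stats::rnorm(n_par) %*% chol_cov)
    }
    lp_prop <- .mix_log_post(prop, spec)
    alpha <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
    if (stats::runif(1) < alpha) {
      theta <- prop
      lp <- lp_prop
      accept <- accept + 1L
    }
    draws[t, ] <- theta
    if (t <= spec$burn) {
      gamma <- min(1, 5 / sqrt(t))
      if (is.null(chol_cov)) {
        step <- pmin(pmax(step * exp(gamma * (alpha - 0.234) * 0.5),
                          1e-3), 10)
      } else {
        lambda <- min(max(lambda * exp(gamma * (alpha - 0.234) * 0.5),
                          1e-3), 10)
      }
      if (t >= t_cov && t %% 50L == 0L) {
        hist <- draws[max(1L, t %/% 2L):t, , drop = FALSE]
        cc <- stats::cov(hist) + diag(1e-8, n_par)
        ch <- tryCatch(chol(cc), error = function(e) NULL)
        if (!is.null(ch)) chol_cov <- ch
      }
    }
  }
  list(draws = draws, accept_rate = accept / iter)
}

# Split-R-hat over a draws array (iterations x chains).
.split_rhat <- function(x) {
  half <- floor(nrow(x) / 2)
  if (half < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  m <- ncol(halves)
  n <- nrow(halves)
  mu <- colMeans(halves)
  s2 <- apply(halves, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial positive sequence on the
# chain-pooled autocorrelations.
.ess <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4L) return(NA_real_)
  acf_k <- function(v) {
    a <- stats::acf(v, lag.max = min(n - 2L, 200L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  }
  rho <- rowMeans(vapply(seq_len(m), function(j) acf_k(x[, j]),
                         numeric(min(n - 2L, 200L) + 1L)))
  tau <- 1
  k <- 2L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2L
  }
  max(1, m * n / tau)
}

#' Fit the Bayesian stable-isotope mixing model
#'
#' Posterior inference for the diet proportion vector p of one consumer
#' group.  Likelihood: each consumer's (d13C, d15N) is independently
#' Normal with mean `sum_k p_k mu_k` and variance
#' `sum_k p_k^2 sigma_k^2 + sigma_resid^2` per isotope, sources being
#' TDF-corrected.  Prior: p ~ Dirichlet(alpha); residual SDs ~
#' half-Normal.  Sampling is adaptive random-walk Metropolis on a
#' softmax transform of the simplex (last coordinate as reference) plus
#' log residual SDs.  With K = 1 source the posterior is the degenerate
#' point p = 1.
#'
#' @param spec A [mixing_spec()].
#' @return A `mixing_posterior`: retained draws of p (and residual SDs),
#'   split-R-hat and effective sample size per parameter, acceptance
#'   rates, and a `converged` flag (all R-hat <= 1.1); non-convergence
#'   triggers a warning, never a silent return.
#' @export
fit_mixing_model <- function(spec) {
  stopifnot(inherits(spec, "mixing_spec"))
  K <- nrow(spec$sources)
  src_names <- spec$sources$source
  if (K == 1L) {
    draws <- matrix(1, 100L, 1L, dimnames = list(NULL, src_names))
    out <- list(p_draws = draws, resid_draws = NULL, sources = spec$sources,
                rhat = c(stats::setNames(NA_real_, src_names)),
                ess = c(stats::setNames(Inf, src_names)),
                accept_rate = NA_real_, converged = TRUE, spec = spec)
    class(out) <- "mixing_posterior"
    return(out)
  }
  est_sig <- is.null(spec$resid_sd)
  n_par <- (K - 1L) + if (est_sig) 2L else 0L
  set.seed(spec$seed)
  chains <- lapply(seq_len(spec$chains), function(ch) {
    init <- c(stats::rnorm(K - 1L, 0, 0.5),
              if (est_sig) stats::rnorm(2L, 0, 0.3))
    .mix_chain(spec, n_par, init)
  })
  keep <- seq(spec$burn + 1L, spec$iter, by = spec$thin)
  # transform retained draws to the constrained scale
  per_chain <- lapply(chains, function(ch) {
    zs <- ch$draws[keep, , drop = FALSE]
    p <- t(apply(zs[, seq_len(K - 1L), drop = FALSE], 1, .softmax_ref))
    colnames(p) <- src_names
    sig <- if (est_sig) {
      s <- exp(zs[, K:(K + 1L), drop = FALSE])
      colnames(s) <- c("resid_sd_c13", "resid_sd_n15")
      s
    } else NULL
    list(p = p, sig = sig)
  })
  n_keep <- length(keep)
  par_mats <- lapply(seq_len(K), function(k) {
    vapply(per_chain, function(pc) pc$p[, k], numeric(n_keep))
  })
  names(par_mats) <- src_names
  if (est_sig) {
    for (j in 1:2) {
      par_mats[[c("resid_sd_c13", "resid_sd_n15")[j]]] <-
        vapply(per_chain, function(pc) pc$sig[, j], numeric(n_keep))
    }
  }
  rhat <- vapply(par_mats, .split_rhat, 0)
  ess <- vapply(par_mats, .ess, 0)
  converged <- all(is.na(rhat) | rhat <= 1.1)
  if (!converged) {
    warning("mixing model did not converge: max split-R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))
  }
  p_draws <- do.call(rbind, lapply(per_chain, `[[`, "p"))
  resid_draws <- if (est_sig) {
    do.call(rbind, lapply(per_chain, `[[`, "sig"))
  } else NULL
  out <- list(p_draws = p_draws, resid_draws = resid_draws,
              sources = spec$sources, rhat = rhat, ess = ess,
              accept_rate = mean(vapply(chains, `[[`, 0, "accept_rate")),
              converged = converged,
              chain_id = rep(seq_len(spec$chains), each = n_keep),
              spec = spec)
  class(out) <- "mixing_posterior"
  out
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat("Bayesian mixing model posterior:", ncol(x$p_draws), "sources,",
      nrow(x$p_draws), "retained draws\n")
  cat("  converged:", x$converged,
      "| max R-hat:", round(max(x$rhat, na.rm = TRUE), 3),
      "| min ESS:", round(min(x$ess, na.rm = TRUE)), "\n")
  print(summarize_posterior(x), digits = 3)
  invisible(x)
}

#' Summarize a mixing-model posterior
#'
#' Per-source posterior mean, SD, and quantiles of the diet proportions
#' over retained draws, reported as percentages by default.
#'
#' @param posterior A `mixing_posterior` from [fit_mixing_model()].
#' @param probs Quantile probabilities (default 2.5/25/50/75/97.5%).
#' @param percent Report on the percentage scale (default) or as raw
#'   proportions.
#' @return Data frame with one row per source.
#' @export
summarize_posterior <- function(posterior,
                                probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                                percent = TRUE) {
  stopifnot(inherits(posterior, "mixing_posterior"))
  draws <- posterior$p_draws
  if (nrow(draws) < 100L) {
    stop("too few retained draws (", nrow(draws), " < 100)")
  }
  scale <- if (percent) 100 else 1
  qs <- matrix(apply(draws, 2, stats::quantile, probs = probs),
               nrow = ncol(draws), ncol = length(probs),
               byrow = TRUE) * scale
  colnames(qs) <- paste0("q", formatC(100 * probs, format = "fg"))
  out <- data.frame(source = colnames(draws),
                    mean = colMeans(draws) * scale,
                    sd = apply(draws, 2, stats::sd) * scale,
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(qs, row.names = NULL))
}
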