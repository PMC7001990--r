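#' Variance-stabilizing covariate transforms
#'
#' The transforms used on land-use covariates before linear modelling:
#' square root, square, natural log, and arcsine-square-root (for
#' proportions).  Log of zero is an error unless an `offset` is
#' configured; no offset is ever applied silently.
#'
#' @param values Numeric vector.
#' @param kind One of `"sqrt"`, `"square"`, `"log"`, `"arcsine_sqrt"`.
#' @param offset Added inside a log transform (e.g. half the smallest
#'   nonzero value); `NULL` means none.
#' @param labels Optional labels (buffer names) used in error messages.
#' @return Transformed numeric vector.
#' @export
transform_covariate <- function(values,
                                kind = c("sqrt", "square", "log",
                                         "arcsine_sqrt"),
                                offset = NULL, labels = NULL) {
  kind <- match.arg(kind)
  lab <- function(idx) {
    if (is.null(labels)) paste("position", idx) else
      paste0("'", labels[idx], "' (", signif(values[idx], 4), ")")
  }
  bad_msg <- function(idx, why) {
    stop(kind, " transform ", why, " at ",
         paste(vapply(utils::head(idx, 5), lab, ""), collapse = ", "))
  }
  switch(kind,
    sqrt = {
      if (any(values < 0)) bad_msg(which(values < 0), "needs values >= 0")
      sqrt(values)
    },
    square = values^2,
    log = {
      x <- if (is.null(offset)) values else values + offset
      if (any(x <= 0)) {
        bad_msg(which(x <= 0),
                if (is.null(offset))
                  "of a non-positive value (configure an offset)"
                else "still non-positive after the offset")
      }
      log(x)
    },
    arcsine_sqrt = {
      if (any(values < 0 | values > 1)) {
        bad_msg(which(values < 0 | values > 1), "needs proportions in [0,1]")
      }
      asin(sqrt(values))
    }
  )
}

#' Fit a Gaussian linear (ANCOVA-style) model for AIC comparison
#'
#' Ordinary least squares via [stats::lm()] with treatment contrasts
#' (alphabetically first factor level as reference), returning the
#' Gaussian log-likelihood at the MLE and AIC = 2k - 2 logLik with
#' k = number of coefficients + 1 (the residual variance).  Rank
#' deficiency is an error naming the aliased terms rather than a silent
#' drop.
#'
#' @param formula Model formula (factors, covariates, interactions).
#' @param data Data frame.
#' @return A `landuse_fit` with elements `fit` (the `lm`), `formula`,
#'   `logLik`, `K`, `AIC`, `n`, and the response vector.
#' @export
fit_linear_model <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(X) <= ncol(X)) {
    stop("need more observations (", nrow(X), ") than coefficients (",
         ncol(X), ")")
  }
  fit <- stats::lm(formula, data = data,
                   contrasts = NULL)  # default treatment contrasts
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit)) + 1L
  out <- list(fit = fit, formula = formula, logLik = ll, K = k,
              AIC = 2 * k - 2 * ll, n = nrow(X),
              response = stats::model.response(mf))
  class(out) <- "landuse_fit"
  out
}

#' @export
print.landuse_fit <- function(x, ...) {
  cat("Linear model:", deparse(x$formula), "\n")
  cat("  n =", x$n, "| K =", x$K, "| logLik =", round(x$logLik, 3),
      "| AIC =", round(x$AIC, 2), "\n")
  invisible(x)
}

#' Akaike weights from AIC differences
#'
#' Given AIC values (or, equivalently, AIC differences), computes
#' Delta-AIC relative to the best model, the relative likelihood
#' exp(-Delta/2), and the Akaike weight (relative likelihoods normalized
#' to sum to 1).  Adding a constant to all AICs changes nothing, so the
#' function can be applied directly to a published Delta-AIC column.
#'
#' @param aic Numeric vector of AIC values or Delta-AIC differences.
#' @return Data frame with `delta_aic`, `rel_likelihood`, `weight`.
#' @export
akaike_weights <- function(aic) {
  if (!length(aic) || anyNA(aic)) stop("AIC vector must be non-empty, no NA")
  delta <- aic - min(aic)
  rel <- exp(-delta / 2)
  data.frame(delta_aic = delta, rel_likelihood = rel,
             weight = rel / sum(rel))
}

#' Rank fitted models by AIC
#'
#' Builds a model-comparison table (formula, K, log-likelihood, AIC,
#' Delta-AIC, relative likelihood, Akaike weight) from a list of
#' [fit_linear_model()] fits, ordered best first.  All fits must be on
#' the same response data.
#'
#' @param fits List of `landuse_fit` objects.
#' @return Data frame of class `model_comparison`.
#' @export
aic_rank <- function(fits) {
  if (inherits(fits, "landuse_fit")) fits <- list(fits)
  if (!length(fits)) stop("no fitted models")
  stopifnot(all(vapply(fits, inherits, TRUE, "landuse_fit")))
  y0 <- fits[[1L]]$response
  same <- vapply(fits, function(f) {
    length(f$response) == length(y0) && all(f$response == y0)
  }, TRUE)
  if (!all(same)) stop("models were fitted to differing response data")
  aw <- akaike_weights(vapply(fits, `[[`, 0, "AIC"))
  out <- data.frame(
    model = vapply(fits, function(f) deparse(f$formula), ""),
    K = vapply(fits, `[[`, 0L, "K"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    delta_aic = aw$delta_aic,
    rel_likelihood = aw$rel_likelihood,
    weight = aw$weight,
    stringsAsFactors = FALSE)
  out <- out[order(out$delta_aic), ]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Pairwise Pearson correlation screen
#'
#' Pearson r with the t-based two-sided p-value for chosen covariate
#' pairs; used to detect collinear land-use covariates before model
#' fitting.
#'
#' @param data Data frame of covariates.
#' @param pairs List of length-2 character vectors naming column pairs;
#'   `NULL` screens all pairs.
#' @return Data frame with `var1`, `var2`, `r`, `p`, `n`.
#' @export
correlation_screen <- function(data, pairs = NULL) {
  num_cols <- names(data)[vapply(data, is.numeric, TRUE)]
  if (is.null(pairs)) {
    pairs <- utils::combn(num_cols, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    if (length(pr) != 2L || !all(pr %in% names(data))) {
      stop("invalid pair: ", paste(pr, collapse = ", "))
    }
    x <- data[[pr[1L]]]
    y <- data[[pr[2L]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) stop("fewer than 3 complete pairs for ",
                           paste(pr, collapse = "-"))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      stop("constant column in pair ", paste(pr, collapse = "-"),
           ": correlation undefined")
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = pr[1L], var2 = pr[2L],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
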