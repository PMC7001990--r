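#' WIC/TNW variance-component decomposition
#'
#' Quantifies individual diet specialization from repeated isotope
#' measurements along each individual's vibrissa, via a one-way
#' sum-of-squares decomposition with individual as the factor:
#' TNW (total niche width) is the total sum of squares of all subsamples
#' around the grand mean, WIC (within-individual component) the pooled
#' sum of squares around each individual's own mean, and BIC the
#' between-individual remainder, so WIC + BIC = TNW exactly.  The index
#' WIC/TNW runs from 0 (every individual occupies a narrow slice of the
#' group niche: strong specialization) to 1 (no individual variation in
#' niche use).
#'
#' @param whiskers Whisker subsample table with columns `individual`,
#'   `d13C`, `d15N` and optionally `area` (used when `group` is
#'   `"area"`).
#' @param isotope Which isotope column(s) to decompose (default both).
#' @param group `"area"` to decompose per study area, `NULL` for one
#'   pooled group.
#' @return Data frame of class `specialization_result` with one row per
#'   group x isotope: `WIC`, `BIC`, `TNW`, `index`, `n_individuals`,
#'   `n_subsamples`.
#' @export
variance_components <- function(whiskers, isotope = c("d13C", "d15N"),
                                group = "area") {
  isotope <- match.arg(isotope, c("d13C", "d15N"), several.ok = TRUE)
  req <- c("individual", isotope)
  if (!is.null(group)) req <- c(req, group)
  missing_col <- setdiff(req, names(whiskers))
  if (length(missing_col)) {
    stop("whisker table lacks column(s): ",
         paste(missing_col, collapse = ", "))
  }
  grp <- if (is.null(group)) rep("all", nrow(whiskers)) else
    as.character(whiskers[[group]])
  rows <- list()
  for (g in unique(grp)) {
    sub <- whiskers[grp == g, , drop = FALSE]
    if (nrow(sub) < 2L) stop("group '", g, "' has fewer than 2 subsamples")
    singles <- names(which(table(sub$individual) == 1L))
    if (length(singles)) {
      warning("group '", g, "': individual(s) with a single subsample ",
              "contribute 0 to WIC: ", paste(singles, collapse = ", "))
    }
    for (iso in isotope) {
      x <- sub[[iso]]
      tnw <- sum((x - mean(x))^2)
      if (tnw <= 0) {
        stop("group '", g, "', ", iso,
             ": all values identical; WIC/TNW undefined")
      }
      wic <- sum(unlist(lapply(split(x, sub$individual),
                               function(v) (v - mean(v))^2)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, isotope = iso, WIC = wic, BIC = tnw - wic, TNW = tnw,
        index = wic / tnw,
        n_individuals = length(unique(sub$individual)),
        n_subsamples = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("specialization_result", "data.frame")
  out
}

#' WIC/TNW index from sums of squares
#'
#' The specialization index given a within-individual and a total sum of
#' squares.  For reporting, the percentage of variation occurring within
#' individuals is `round(100 * wic_tnw_ratio(w, t))`.
#'
#' @param within Within-individual sum of squares (WIC), >= 0.
#' @param total Total sum of squares (TNW), > 0 and >= `within`.
#' @return The ratio WIC/TNW in \[0, 1\] (vectorized).
#' @export
wic_tnw_ratio <- function(within, total) {
  if (any(total <= 0)) stop("total sum of squares must be > 0")
  if (any(within < 0)) stop("within sum of squares must be >= 0")
  if (any(within > total)) stop("within exceeds total sum of squares")
  within / total
}
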