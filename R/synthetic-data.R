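#' Configuration for the scat-record generator
#'
#' Describes the occurrence process behind a synthetic scat dataset:
#' each food item appears in each scat independently with a per-area,
#' per-season probability.  Optionally, a logit-scale slope ties the
#' probability of anthropogenic items to a per-transect altered-open-
#' space proportion, so land-use covariate effects can be planted.
#'
#' @param occurrence Data frame with columns `area`, `season`
#'   (`"wet"`/`"dry"`), `item`, `prob` (in \[0,1\]); every area x season
#'   cell must cover the same item list.
#' @param transects_per_area Number of transects per area (>= 1).
#' @param scats_per_transect Scats generated per transect per season
#'   (>= 1).
#' @param altered_slope Optional logit-scale slope of anthropogenic-item
#'   probability on the transect's altered-open-space proportion.
#' @param anthropogenic_items Items the slope applies to.
#' @param resample_empty Redraw scats that contain no item at all
#'   (default `FALSE`: empty scats are kept and counted in N).
#' @param seed Integer seed.
#' @return A `scat_sim_config` object.
#' @export
scat_sim_config <- function(occurrence, transects_per_area = 5,
                            scats_per_transect = 20, altered_slope = NULL,
                            anthropogenic_items = character(),
                            resample_empty = FALSE, seed = 1) {
  req <- c("area", "season", "item", "prob")
  missing_col <- setdiff(req, names(occurrence))
  if (length(missing_col)) {
    stop("occurrence table lacks column(s): ",
         paste(missing_col, collapse = ", "))
  }
  if (any(occurrence$prob < 0 | occurrence$prob > 1)) {
    stop("occurrence probabilities must lie in [0, 1]")
  }
  if (!all(occurrence$season %in% c("wet", "dry"))) {
    stop("season must be 'wet' or 'dry'")
  }
  items_by_cell <- lapply(
    split(occurrence$item, interaction(occurrence$area, occurrence$season)),
    sort)
  items_by_cell <- items_by_cell[lengths(items_by_cell) > 0]
  if (length(unique(items_by_cell)) != 1L) {
    stop("every area x season cell must list the same items")
  }
  if (transects_per_area < 1 || scats_per_transect < 1) {
    stop("transect and scat counts must be >= 1")
  }
  out <- list(occurrence = occurrence,
              transects_per_area = as.integer(transects_per_area),
              scats_per_transect = as.integer(scats_per_transect),
              altered_slope = altered_slope,
              anthropogenic_items = anthropogenic_items,
              resample_empty = isTRUE(resample_empty),
              seed = as.integer(seed))
  class(out) <- "scat_sim_config"
  out
}

#' Generate a scat record dataset with known truth
#'
#' Simulates one row per scat with independent per-item presence at the
#' configured probabilities, wet-season scats dated November-April and
#' dry-season scats May-October.  The configured probability table (the
#' ground truth) and the per-transect covariate draws are returned
#' alongside.
#'
#' @param config A [scat_sim_config()].
#' @return List with `scats` (record table: `scat_id`, `transect`,
#'   `area`, `year_month`, one 0/1 column per item), `truth` (the
#'   occurrence probabilities actually used, per transect when a
#'   covariate slope is configured), `transects` (per-transect
#'   altered-open-space proportions), and `n_empty`.
#' @export
gen_scat_dataset <- function(config) {
  stopifnot(inherits(config, "scat_sim_config"))
  set.seed(config$seed)
  occ <- config$occurrence
  items <- sort(unique(occ$item))
  areas <- unique(occ$area)
  wet_months <- c(11, 12, 1, 2, 3, 4)
  dry_months <- 5:10

  transects <- data.frame(
    transect = paste0(rep(areas, each = config$transects_per_area), "_T",
                      seq_len(config$transects_per_area)),
    area = rep(areas, each = config$transects_per_area),
    altered = stats::runif(length(areas) * config$transects_per_area,
                           0, 0.35),
    stringsAsFactors = FALSE)

  truth_rows <- list()
  scat_rows <- list()
  sid <- 0L
  for (ti in seq_len(nrow(transects))) {
    tr <- transects[ti, ]
    for (season in c("wet", "dry")) {
      cell <- occ[occ$area == tr$area & occ$season == season, ]
      p <- cell$prob[match(items, cell$item)]
      if (!is.null(config$altered_slope)) {
        adj <- items %in% config$anthropogenic_items
        p[adj] <- stats::plogis(stats::qlogis(pmin(pmax(p[adj], 1e-12),
                                                   1 - 1e-12)) +
                                  config$altered_slope * tr$altered)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transect = tr$transect, area = tr$area, season = season,
        item = items, prob = p, stringsAsFactors = FALSE)
      months <- if (season == "wet") wet_months else dry_months
      n <- config$scats_per_transect
      pres <- matrix(stats::rbinom(n * length(items), 1L,
                                   rep(p, each = n)), nrow = n)
      if (config$resample_empty && any(p > 0)) {
        empty <- rowSums(pres) == 0L
        guard <- 0L
        while (any(empty) && guard < 1000L) {
          pres[empty, ] <- matrix(
            stats::rbinom(sum(empty) * length(items), 1L,
                          rep(p, each = sum(empty))), nrow = sum(empty))
          empty <- rowSums(pres) == 0L
          guard <- guard + 1L
        }
      }
      colnames(pres) <- items
      df <- data.frame(
        scat_id = paste0("S", sid + seq_len(n)),
        transect = tr$transect, area = tr$area,
        year_month = sprintf("2017-%02d", sample(months, n, replace = TRUE)),
        stringsAsFactors = FALSE)
      sid <- sid + n
      scat_rows[[length(scat_rows) + 1L]] <- cbind(df, as.data.frame(pres))
    }
  }
  scats <- do.call(rbind, scat_rows)
  rownames(scats) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(scats = scats, truth = truth, transects = transects,
       n_empty = sum(rowSums(scats[items]) == 0))
}

#' Configuration for the whisker isotope generator
#'
#' Forward model of the mixing equations: each area has a true diet
#' proportion vector over the sources; the group-level tissue mean is
#' the proportion-weighted, TDF-corrected source mean; each individual
#' draws a latent mean around it (between-individual SD) and each
#' vibrissa subsample draws around the latent mean (within-individual
#' SD).  Subsample counts per individual are drawn around a mean of 16
#' with SD 7 (floored at 1), matching typical vibrissa sectioning.
#'
#' @param proportions Named list: per-area numeric proportion vector
#'   over the sources (each summing to 1 within 1e-9, named by source).
#' @param sources A [source_table()] in diet space.
#' @param tdf A [trophic_discrimination()].
#' @param c13_overrides Per-source Delta13C overrides (see
#'   [tdf_correct_sources()]).
#' @param between_sd,within_sd Named `c(c13=, n15=)` SDs in per mil
#'   (>= 0).
#' @param n_individuals Individuals per area (scalar or named by area).
#' @param subsample_mean,subsample_sd Distribution of subsamples per
#'   vibrissa.
#' @param seed Integer seed.
#' @return A `whisker_sim_config` object.
#' @export
whisker_sim_config <- function(proportions, sources,
                               tdf = trophic_discrimination(),
                               c13_overrides = NULL,
                               between_sd = c(c13 = 0.9, n15 = 0.6),
                               within_sd = c(c13 = 1.7, n15 = 2.4),
                               n_individuals = 10,
                               subsample_mean = 16, subsample_sd = 7,
                               seed = 1) {
  stopifnot(inherits(sources, "source_table"))
  if (!length(proportions) || is.null(names(proportions))) {
    stop("'proportions' must be a named list of per-area vectors")
  }
  for (a in names(proportions)) {
    p <- proportions[[a]]
    if (length(p) != nrow(sources)) {
      stop("area '", a, "': proportion vector length != number of sources")
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop("area '", a, "': proportions must sum to 1 (got ", sum(p), ")")
    }
    if (any(p < 0)) stop("area '", a, "': negative proportion")
  }
  if (any(c(between_sd, within_sd) < 0)) stop("SDs must be >= 0")
  n_individuals <- if (is.null(names(n_individuals))) {
    stats::setNames(rep_len(n_individuals, length(proportions)),
                    names(proportions))
  } else n_individuals
  if (any(n_individuals < 1)) stop("need >= 1 individual per area")
  if (subsample_mean < 1 || subsample_sd < 0) {
    stop("invalid subsample count distribution")
  }
  out <- list(proportions = proportions, sources = sources, tdf = tdf,
              c13_overrides = c13_overrides,
              between_sd = between_sd, within_sd = within_sd,
              n_individuals = n_individuals,
              subsample_mean = subsample_mean, subsample_sd = subsample_sd,
              seed = as.integer(seed))
  class(out) <- "whisker_sim_config"
  out
}

#' Generate whisker isotope profiles with known truth
#'
#' @param config A [whisker_sim_config()].
#' @return List with `whiskers` (subsample table: `individual`, `area`,
#'   `sex`, `subsample`, `d13C`, `d15N`) and `truth` (per-area forward
#'   means, per-individual latent means, and the true proportion
#'   vectors).
#' @export
gen_whisker_dataset <- function(config) {
  stopifnot(inherits(config, "whisker_sim_config"))
  set.seed(config$seed)
  corrected <- tdf_correct_sources(config$sources, config$tdf,
                                   config$c13_overrides)
  group_rows <- list()
  ind_rows <- list()
  sub_rows <- list()
  for (a in names(config$proportions)) {
    p <- config$proportions[[a]]
    fm <- forward_model(p, corrected)
    group_rows[[a]] <- data.frame(area = a, mean_c13 = fm$mean[["d13C"]],
                                  mean_n15 = fm$mean[["d15N"]],
                                  stringsAsFactors = FALSE)
    n_ind <- config$n_individuals[[a]]
    for (i in seq_len(n_ind)) {
      id <- sprintf("%s_%02d", a, i)
      lat_c <- stats::rnorm(1, fm$mean[["d13C"]], config$between_sd[["c13"]])
      lat_n <- stats::rnorm(1, fm$mean[["d15N"]], config$between_sd[["n15"]])
      m <- max(1L, round(stats::rnorm(1, config$subsample_mean,
                                      config$subsample_sd)))
      ind_rows[[id]] <- data.frame(
        individual = id, area = a, latent_c13 = lat_c, latent_n15 = lat_n,
        n_subsamples = m, stringsAsFactors = FALSE)
      sub_rows[[id]] <- data.frame(
        individual = id, area = a,
        sex = sample(c("F", "M"), 1),
        subsample = seq_len(m),
        d13C = stats::rnorm(m, lat_c, config$within_sd[["c13"]]),
        d15N = stats::rnorm(m, lat_n, config$within_sd[["n15"]]),
        stringsAsFactors = FALSE)
    }
  }
  whiskers <- do.call(rbind, sub_rows)
  rownames(whiskers) <- NULL
  individuals <- do.call(rbind, ind_rows)
  rownames(individuals) <- NULL
  list(whiskers = whiskers,
       truth = list(group_means = do.call(rbind, group_rows),
                    individuals = individuals,
                    proportions = config$proportions,
                    corrected_sources = corrected))
}

#' Configuration for the buffer covariate generator
#'
#' Emulates a land-use covariate table for circular "pseudo-home-range"
#' buffers: proportion urban, proportion altered open space, road
#' density (km/km2) and human density (10,000 people/km2), with a
#' configurable correlation structure imposed through a Gaussian copula.
#' The default correlation matrix reproduces the strong collinearity of
#' road density, human density and urban cover typical of such buffers.
#'
#' @param n_buffers Number of buffers (>= 2).
#' @param urban_range,altered_range Proportion ranges within \[0,1\].
#' @param roads_range,humans_range Density ranges (>= 0).
#' @param correlation 4x4 positive-semidefinite correlation matrix over
#'   (urban, altered, roads, humans).
#' @param seed Integer seed.
#' @return A `covariate_sim_config` object.
#' @export
covariate_sim_config <- function(n_buffers = 24,
                                 urban_range = c(0, 1),
                                 altered_range = c(0, 0.35),
                                 roads_range = c(1, 16),
                                 humans_range = c(0, 11),
                                 correlation = NULL, seed = 1) {
  chk_range <- function(r, name, unit_interval = FALSE) {
    if (length(r) != 2L || anyNA(r) || r[2L] < r[1L]) {
      stop("'", name, "' must be c(min, max) with max >= min")
    }
    if (unit_interval && (r[1L] < 0 || r[2L] > 1)) {
      stop("'", name, "' must lie within [0, 1]")
    }
    if (!unit_interval && r[1L] < 0) {
      stop("'", name, "' must be non-negative")
    }
  }
  chk_range(urban_range, "urban_range", TRUE)
  chk_range(altered_range, "altered_range", TRUE)
  chk_range(roads_range, "roads_range")
  chk_range(humans_range, "humans_range")
  if (n_buffers < 2) stop("need at least 2 buffers")
  if (is.null(correlation)) {
    correlation <- diag(4)
    dimnames(correlation) <- list(c("urban", "altered", "roads", "humans"),
                                  c("urban", "altered", "roads", "humans"))
    correlation["urban", "roads"] <- correlation["roads", "urban"] <- 0.81
    correlation["urban", "humans"] <- correlation["humans", "urban"] <- 0.78
    correlation["roads", "humans"] <- correlation["humans", "roads"] <- 0.88
  }
  if (!isTRUE(all.equal(dim(correlation), c(4L, 4L))) ||
      any(abs(correlation - t(correlation)) > 1e-12) ||
      any(abs(diag(correlation) - 1) > 1e-12)) {
    stop("'correlation' must be a symmetric 4x4 correlation matrix")
  }
  if (min(eigen(correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("'correlation' is not positive semidefinite")
  }
  out <- list(n_buffers = as.integer(n_buffers), urban_range = urban_range,
              altered_range = altered_range, roads_range = roads_range,
              humans_range = humans_range, correlation = correlation,
              seed = as.integer(seed))
  class(out) <- "covariate_sim_config"
  out
}

#' Generate a buffer covariate table
#'
#' Draws correlated standard normals (Gaussian copula), maps them to
#' uniforms and scales each into its configured range, so marginals
#' respect the ranges while the rank correlation follows the configured
#' matrix.  Buffers in the upper half of urban cover are labelled
#' `"urban"`, the rest `"suburban"`.
#'
#' @param config A [covariate_sim_config()].
#' @return Data frame: `buffer`, `area`, `urban`, `altered`, `roads`,
#'   `humans`.
#' @export
gen_covariate_table <- function(config) {
  stopifnot(inherits(config, "covariate_sim_config"))
  set.seed(config$seed)
  z <- MASS::mvrnorm(config$n_buffers, mu = rep(0, 4),
                     Sigma = config$correlation)
  u <- stats::pnorm(z)
  scale_to <- function(uu, r) r[1L] + uu * (r[2L] - r[1L])
  out <- data.frame(
    buffer = sprintf("B%02d", seq_len(config$n_buffers)),
    urban = scale_to(u[, 1L], config$urban_range),
    altered = scale_to(u[, 2L], config$altered_range),
    roads = scale_to(u[, 3L], config$roads_range),
    humans = scale_to(u[, 4L], config$humans_range),
    stringsAsFactors = FALSE)
  out$area <- ifelse(out$urban >= stats::median(out$urban),
                     "urban", "suburban")
  out[, c("buffer", "area", "urban", "altered", "roads", "humans")]
}
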