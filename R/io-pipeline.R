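# Required and numeric columns per table schema.  Scat tables carry an
# open-ended set of 0/1 item columns after the metadata block.
.schemas <- list(
  scat = list(required = c("scat_id", "transect", "area", "year_month"),
              numeric = character(), open = TRUE),
  whisker = list(required = c("individual", "area", "sex", "subsample",
                              "d13C", "d15N"),
                 numeric = c("subsample", "d13C", "d15N"), open = FALSE),
  source = list(required = c("source", "d13C", "d15N"),
                numeric = c("d13C", "d15N"), open = FALSE),
  covariate = list(required = c("buffer", "area", "urban", "altered",
                                "roads", "humans"),
                   numeric = c("urban", "altered", "roads", "humans"),
                   open = FALSE),
  taxonomy = list(required = c("item", "category", "anthropogenic"),
                  numeric = character(), open = FALSE)
)

#' Load and validate a delimited input table
#'
#' Reads a comma-delimited, headered text file against one of the
#' package's table schemas (`"scat"`, `"whisker"`, `"source"`,
#' `"covariate"`, `"taxonomy"`).  Missing required columns are fatal and
#' named; unparseable numeric cells are fatal with their row number;
#' unknown extra columns only warn (except for scat tables, whose extra
#' columns are the food items and must be 0/1-codeable).
#'
#' @param path Path to a CSV file.
#' @param schema Schema name.
#' @return Validated data frame.
#' @export
load_table <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- .schemas[[schema]]
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing_col <- setdiff(sch$required, names(tab))
  if (length(missing_col)) {
    stop("table '", basename(path), "' (schema ", schema,
         ") lacks required column(s): ", paste(missing_col, collapse = ", "))
  }
  numeric_cols <- sch$numeric
  if (sch$open) {
    numeric_cols <- c(numeric_cols, setdiff(names(tab), sch$required))
  } else {
    extra <- setdiff(names(tab), sch$required)
    if (length(extra)) {
      warning("ignoring unknown column(s) in '", basename(path), "': ",
              paste(extra, collapse = ", "))
    }
  }
  for (cc in numeric_cols) {
    v <- tab[[cc]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        stop("non-numeric value in column '", cc, "' of '", basename(path),
             "' at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
      }
      tab[[cc]] <- parsed
    }
    if (anyNA(tab[[cc]])) {
      stop("missing value in numeric column '", cc, "' of '",
           basename(path), "' at row(s): ",
           paste(utils::head(which(is.na(tab[[cc]])), 5), collapse = ", "))
    }
  }
  if (schema == "taxonomy") {
    tab$anthropogenic <- as.logical(tab$anthropogenic)
    tab <- food_taxonomy(tab$item, tab$category, tab$anthropogenic)
  }
  message("loaded ", nrow(tab), " rows from ", basename(path),
          " (schema: ", schema, ")")
  tab
}

#' Write a delimited output table
#'
#' Comma-delimited, UTF-8, header row, no row names; the format all
#' pipeline outputs use so that they are re-loadable by [load_table()].
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every setting of a full analysis run.  Inputs may be given as
#' file paths (loaded through [load_table()]) or as already-loaded data
#' frames.
#'
#' @param scats,whiskers,source_samples Input tables or file paths;
#'   `source_samples` may be `NULL` to use [reference_sources()].
#' @param taxonomy Optional [food_taxonomy()] or path.
#' @param season A [season_rule()].
#' @param categories Category list for the niche-breadth statistic.
#' @param tdf A [trophic_discrimination()].
#' @param c13_overrides Per-source Delta13C overrides for mixing (default
#'   `c("human food" = 2.5)`, the keratin value for a human-food source).
#' @param combine Length-2 character vector of sources pooled a priori
#'   before mixing (`NULL` for none).
#' @param threshold_k_sd SD multiplier of the anthropogenic threshold.
#' @param mcmc List of MCMC settings (`chains`, `iter`, `burn`, `thin`).
#' @param seed Master seed.
#' @param outdir Output directory (`NULL` to skip writing files).
#' @return A `run_config` object.
#' @export
run_config <- function(scats, whiskers, source_samples = NULL,
                       taxonomy = NULL, season = season_rule(),
                       categories = diet_categories(),
                       tdf = trophic_discrimination(),
                       c13_overrides = c("human food" = 2.5),
                       combine = c("rabbits", "pocket gophers"),
                       threshold_k_sd = 1,
                       mcmc = list(chains = 4, iter = 10000, burn = 1000,
                                   thin = 1),
                       seed = 1, outdir = NULL) {
  out <- list(scats = scats, whiskers = whiskers,
              source_samples = source_samples, taxonomy = taxonomy,
              season = season, categories = categories, tdf = tdf,
              c13_overrides = c13_overrides, combine = combine,
              threshold_k_sd = threshold_k_sd, mcmc = mcmc,
              seed = as.integer(seed), outdir = outdir)
  class(out) <- "run_config"
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full diet-analysis pipeline
#'
#' Executes, in order: scat aggregation and occurrence indices (FO, PO,
#' niche breadth per group), the pairwise Morisita overlap matrix,
#' source preparation (summary, optional a priori pooling, TDF
#' correction), the anthropogenic d13C threshold and consumer
#' classification, the Bayesian mixing model per study area, the
#' WIC/TNW specialization decomposition, and writes every table plus a
#' machine-readable run manifest when an output directory is configured.
#' Reruns with the same config and seed give identical numbers.
#'
#' @param config A [run_config()].
#' @return List of stage results, invisibly when writing to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  as_tab <- function(x, schema) {
    if (is.character(x) && length(x) == 1L) load_table(x, schema) else x
  }
  scats <- .stage("load_scats", as_tab(config$scats, "scat"))
  whiskers <- .stage("load_whiskers", as_tab(config$whiskers, "whisker"))
  taxonomy <- if (is.character(config$taxonomy)) {
    .stage("load_taxonomy", load_table(config$taxonomy, "taxonomy"))
  } else config$taxonomy

  tables <- .stage("aggregate_scats",
                   aggregate_scats(scats, taxonomy, config$season))
  message("scat groups: ", paste(names(tables), collapse = ", "))
  diet <- .stage("diet_indices", {
    do.call(rbind, lapply(tables, function(tt) {
      data.frame(group = tt$group, item = names(tt$counts),
                 n = as.integer(tt$counts), N = tt$n_scats,
                 FO = frequency_of_occurrence(tt),
                 PO = percent_occurrence(tt),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
  breadth <- .stage("niche_breadth", {
    data.frame(group = names(tables),
               B = vapply(tables, levins_niche_breadth, 0,
                          categories = config$categories),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  overlap <- .stage("morisita_overlap", {
    gs <- names(tables)
    m <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
    diag(m) <- 1
    if (length(gs) > 1L) {
      for (i in seq_along(gs)) for (j in seq_along(gs)) {
        if (i < j) {
          m[i, j] <- m[j, i] <- morisita_overlap(
            tables[[i]], tables[[j]], categories = config$categories)
        }
      }
    }
    m
  })

  sources <- .stage("prepare_sources", {
    if (is.null(config$source_samples)) {
      reference_sources()
    } else {
      summarize_sources(as_tab(config$source_samples, "source"))
    }
  })
  if (!is.null(config$combine) &&
      all(config$combine %in% sources$source)) {
    sources <- .stage("combine_sources",
                      combine_sources(sources, config$combine))
  }
  threshold <- .stage("anthropogenic_threshold",
                      anthropogenic_threshold(sources, config$tdf,
                                              config$threshold_k_sd))
  classes <- .stage("classify_consumers",
                    classify_consumers(whiskers, threshold))

  wm <- whisker_means(whiskers)
  mixing <- .stage("mixing_model", {
    lapply(split(wm, wm$area), function(grp) {
      overrides <- config$c13_overrides
      overrides <- overrides[names(overrides) %in% sources$source]
      if (!length(overrides)) overrides <- NULL
      spec <- mixing_spec(grp, sources, tdf = config$tdf,
                          c13_overrides = overrides,
                          chains = config$mcmc$chains,
                          iter = config$mcmc$iter,
                          burn = config$mcmc$burn,
                          thin = config$mcmc$thin,
                          seed = config$seed)
      fit_mixing_model(spec)
    })
  })
  mixing_summary <- do.call(rbind, lapply(names(mixing), function(a) {
    cbind(area = a, summarize_posterior(mixing[[a]]))
  }))
  diagnostics <- do.call(rbind, lapply(names(mixing), function(a) {
    data.frame(area = a, parameter = names(mixing[[a]]$rhat),
               rhat = as.numeric(mixing[[a]]$rhat),
               ess = as.numeric(mixing[[a]]$ess),
               converged = mixing[[a]]$converged,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  specialization <- .stage("specialization",
                           variance_components(whiskers, group = "area"))

  results <- list(diet = diet, breadth = breadth, overlap = overlap,
                  sources = sources, threshold = as.numeric(threshold),
                  classification = classes, mixing = mixing,
                  mixing_summary = mixing_summary,
                  mixing_diagnostics = diagnostics,
                  specialization = specialization)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$outdir, f)
    write_table(diet, o("diet_indices.csv"))
    write_table(breadth, o("niche_breadth.csv"))
    write_table(cbind(group = rownames(overlap), as.data.frame(overlap)),
                o("overlap_matrix.csv"))
    write_table(as.data.frame(sources), o("sources.csv"))
    write_table(classes$individuals, o("consumer_classification.csv"))
    write_table(classes$area_fractions, o("area_fractions.csv"))
    write_table(mixing_summary, o("mixing_summary.csv"))
    write_table(diagnostics, o("mixing_diagnostics.csv"))
    write_table(as.data.frame(specialization), o("specialization.csv"))
    manifest <- list(
      package = "urbandiet",
      package_version = as.character(utils::packageVersion("urbandiet")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      threshold = as.numeric(threshold),
      threshold_k_sd = config$threshold_k_sd,
      tdf = unclass(config$tdf),
      c13_overrides = as.list(config$c13_overrides),
      combine = config$combine,
      categories = config$categories,
      mcmc = config$mcmc)
    jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    message("pipeline outputs written to ", config$outdir)
    return(invisible(results))
  }
  results
}
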