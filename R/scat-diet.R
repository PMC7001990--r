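#' The nine standard diet analysis categories
#'
#' Food-item categories used by default for the Levins niche breadth
#' statistic: the categories of food items that occur commonly (> 10% of
#' scats) in urban and suburban coyote diets.
#'
#' @return Character vector of the 9 category names.
#' @export
diet_categories <- function() {
  c("birds", "reptiles", "invertebrates", "trash",
    "ornamental fruit and seeds", "domestic cats",
    "rabbits", "ground squirrels", "pocket gophers")
}

#' Food-item taxonomy
#'
#' Maps raw food-item names (the 0/1 columns of a scat record table) onto
#' analysis categories and flags anthropogenic items.  Every item maps to
#' exactly one category; items outside the 9 standard analysis categories
#' may use any other label (e.g. `"other"`).
#'
#' @param item Character vector of item names.
#' @param category Character vector, same length, of category labels.
#' @param anthropogenic Logical vector, same length; is the item a
#'   human-associated subsidy (trash, pet food, ornamental fruit,
#'   domestic animals)?
#' @return A `food_taxonomy` data frame.
#' @export
food_taxonomy <- function(item, category = item,
                          anthropogenic = rep(FALSE, length(item))) {
  if (length(category) != length(item) ||
      length(anthropogenic) != length(item)) {
    stop("'item', 'category' and 'anthropogenic' must have equal length")
  }
  if (anyDuplicated(item)) {
    stop("duplicated item names in taxonomy: ",
         paste(unique(item[duplicated(item)]), collapse = ", "))
  }
  out <- data.frame(item = as.character(item),
                    category = as.character(category),
                    anthropogenic = as.logical(anthropogenic),
                    stringsAsFactors = FALSE)
  class(out) <- c("food_taxonomy", "data.frame")
  out
}

#' Wet/dry season rule
#'
#' Southern-California Mediterranean climates have two seasons; scats are
#' classified by calendar month of collection.  The default rule assigns
#' November-April to the wet season and May-October to the dry season.
#'
#' @param wet_months Integer vector of calendar months (1-12) belonging to
#'   the wet season; the complement is the dry season.
#' @return A `season_rule` object.
#' @export
season_rule <- function(wet_months = c(11, 12, 1, 2, 3, 4)) {
  wet_months <- as.integer(wet_months)
  if (anyNA(wet_months) || any(wet_months < 1L | wet_months > 12L)) {
    stop("wet_months must be calendar months in 1..12")
  }
  if (anyDuplicated(wet_months)) stop("duplicated months in wet_months")
  out <- list(wet = sort(wet_months), dry = sort(setdiff(1:12, wet_months)))
  class(out) <- "season_rule"
  out
}

#' Assign seasons to months
#'
#' @param month Integer vector of calendar months (1-12).
#' @param rule A [season_rule()].
#' @return Character vector `"wet"`/`"dry"`.
#' @export
assign_season <- function(month, rule = season_rule()) {
  month <- as.integer(month)
  bad <- which(is.na(month) | month < 1L | month > 12L)
  if (length(bad)) {
    stop("month outside 1-12 at position(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ifelse(month %in% rule$wet, "wet", "dry")
}

#' Per-group diet occurrence table
#'
#' The central occurrence container: per-item counts of scats containing
#' each item (`n_i`) together with the total number of scats `N` in the
#' group.  `sum(counts)` may exceed `N` because scats commonly contain
#' several items.
#'
#' @param counts Named non-negative integer vector, one entry per item.
#' @param n_scats Total number of scats `N` in the group (positive).
#' @param group Group label (e.g. `"urban.wet"`).
#' @return A `diet_table` object.
#' @export
diet_table <- function(counts, n_scats, group = "all") {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("'counts' must be a fully named vector")
  }
  counts <- round(counts)
  if (any(counts < 0)) stop("negative occurrence count")
  n_scats <- as.integer(n_scats)
  if (is.na(n_scats) || n_scats < 1L) stop("'n_scats' (N) must be >= 1")
  if (any(counts > n_scats)) {
    stop("occurrence count exceeds total scat count N for item(s): ",
         paste(names(counts)[counts > n_scats], collapse = ", "))
  }
  out <- list(counts = counts, n_scats = n_scats, group = as.character(group))
  class(out) <- "diet_table"
  out
}

#' @export
print.diet_table <- function(x, ...) {
  cat("Diet occurrence table:", x$group, "\n")
  cat("  N =", x$n_scats, "scats;", length(x$counts), "items; sum(n_i) =",
      sum(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

# Extract the month from a "YYYY-MM" (or bare month) field.
.parse_month <- function(year_month) {
  ym <- as.character(year_month)
  m <- ifelse(grepl("-", ym), sub("^.*-", "", ym), ym)
  suppressWarnings(as.integer(m))
}

#' Tabulate scat records into per-group diet tables
#'
#' Aggregates a scat record table (one row per scat, one 0/1 column per
#' food item) into [diet_table()] objects per group.  Presence is per
#' scat: an item found more than once in one scat still counts once.
#' When a taxonomy is supplied, items are first mapped to categories and
#' a scat counts toward a category if any of its items does.
#'
#' @param scats Data frame with columns `scat_id`, `transect`, `area`,
#'   `year_month` (either `"YYYY-MM"` or a bare month number) followed by
#'   one 0/1 column per food item.
#' @param taxonomy Optional [food_taxonomy()]; every item column must be
#'   present in it.  `NULL` keeps items ungrouped.
#' @param season A [season_rule()] used when `"season"` is part of `by`.
#' @param by Character vector of grouping keys among
#'   `c("area", "season", "transect")`; empty for one pooled table.
#' @return Named list of [diet_table()] objects, one per group.
#' @export
aggregate_scats <- function(scats, taxonomy = NULL, season = season_rule(),
                            by = c("area", "season")) {
  meta_cols <- c("scat_id", "transect", "area", "year_month")
  missing_meta <- setdiff(meta_cols, names(scats))
  if (length(missing_meta)) {
    stop("scat table lacks required column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  item_cols <- setdiff(names(scats), meta_cols)
  if (!length(item_cols)) stop("scat table has no food-item columns")
  bad_by <- setdiff(by, c("area", "season", "transect"))
  if (length(bad_by)) stop("unknown grouping key(s): ",
                           paste(bad_by, collapse = ", "))

  present <- as.matrix(scats[item_cols]) > 0
  if (!is.null(taxonomy)) {
    unmapped <- setdiff(item_cols, taxonomy$item)
    if (length(unmapped)) {
      stop("food item(s) absent from taxonomy: ",
           paste(unmapped, collapse = ", "))
    }
    cat_of <- taxonomy$category[match(item_cols, taxonomy$item)]
    cats <- unique(cat_of)
    present <- vapply(cats, function(cc) {
      rowSums(present[, cat_of == cc, drop = FALSE]) > 0
    }, logical(nrow(scats)))
    if (is.null(dim(present))) present <- matrix(present, nrow = 1,
                                                 dimnames = list(NULL, cats))
    colnames(present) <- cats
  }

  keys <- list()
  if ("area" %in% by) keys$area <- as.character(scats$area)
  if ("season" %in% by) {
    keys$season <- assign_season(.parse_month(scats$year_month), season)
  }
  if ("transect" %in% by) keys$transect <- as.character(scats$transect)
  grp <- if (length(keys)) {
    interaction(as.data.frame(keys), sep = ".", drop = TRUE, lex.order = TRUE)
  } else {
    factor(rep("all", nrow(scats)))
  }

  out <- lapply(levels(grp), function(g) {
    idx <- grp == g
    diet_table(colSums(present[idx, , drop = FALSE]),
               n_scats = sum(idx), group = g)
  })
  names(out) <- levels(grp)
  out
}

#' Frequency of occurrence (FO)
#'
#' FO_i = 100 n_i / N: the percentage of scats in the group containing
#' item i.  Per-item values can total well over 100% because scats often
#' contain several items.
#'
#' @param table A [diet_table()].
#' @return Named numeric vector of percentages in \[0, 100\].
#' @export
frequency_of_occurrence <- function(table) {
  stopifnot(inherits(table, "diet_table"))
  if (table$n_scats < 1L) stop("FO undefined: N = 0")
  100 * table$counts / table$n_scats
}

#' Percentage of occurrence (PO)
#'
#' PO_i = 100 n_i / sum(n_i): each item's share of all item occurrences.
#' Sums to 100% over items.
#'
#' @param table A [diet_table()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
percent_occurrence <- function(table) {
  stopifnot(inherits(table, "diet_table"))
  tot <- sum(table$counts)
  if (tot < 1) stop("PO undefined: all occurrence counts are zero")
  100 * table$counts / tot
}

# Restrict a count vector to a category list, erroring on absences.
.restrict_counts <- function(counts, categories, what) {
  if (is.null(categories)) return(counts)
  missing_cat <- setdiff(categories, names(counts))
  if (length(missing_cat)) {
    stop(what, ": categories absent from the diet table: ",
         paste(missing_cat, collapse = ", "))
  }
  counts[categories]
}

#' Levins niche breadth (B)
#'
#' B = 1 / sum(p_i^2) with p_i = n_i / sum(n_i).  Ranges from 1 (only one
#' category consumed) to the number of categories (all consumed in equal
#' frequency).  By default B is computed over the 9 standard analysis
#' categories ([diet_categories()]); pass any other category list to
#' change the basis.
#'
#' @param table A [diet_table()].
#' @param categories Character vector of categories to use; they must all
#'   be present in the table.
#' @return The niche breadth statistic (scalar).
#' @export
levins_niche_breadth <- function(table, categories = diet_categories()) {
  stopifnot(inherits(table, "diet_table"))
  n <- .restrict_counts(table$counts, categories, "levins_niche_breadth")
  if (sum(n) <= 0) stop("niche breadth undefined: all counts are zero")
  p <- n / sum(n)
  1 / sum(p^2)
}

#' Morisita's index of niche overlap (C)
#'
#' Overlap between the diets of two groups, with the finite-sample
#' (n - 1)/(N - 1) correction:
#' \deqn{C = \frac{2 \sum_i p_{ij} p_{ik}}
#'   {\sum_i p_{ij} \frac{n_{ij}-1}{N_j-1} +
#'    \sum_i p_{ik} \frac{n_{ik}-1}{N_k-1}}}
#' where p are occurrence proportions (n_i / sum n_i) and N is the number
#' of scats collected for the group.  0 means disjoint diets; identical
#' finite samples give values at (or, through the correction, slightly
#' above) 1 — values are not clipped.
#'
#' @param table_j,table_k Two [diet_table()] objects over the same item
#'   universe.
#' @param categories Optional category restriction; `NULL` (default) uses
#'   all items, which must agree between the two tables.
#' @param n_basis Basis of the `N` in the finite-sample correction:
#'   `"scats"` (default, the number of scats collected for the group) or
#'   `"occurrences"` (sum of item counts) for sensitivity checks.
#' @return The overlap index C (scalar, >= 0).
#' @export
morisita_overlap <- function(table_j, table_k, categories = NULL,
                             n_basis = c("scats", "occurrences")) {
  stopifnot(inherits(table_j, "diet_table"), inherits(table_k, "diet_table"))
  n_basis <- match.arg(n_basis)
  nj <- .restrict_counts(table_j$counts, categories, "morisita_overlap")
  nk <- .restrict_counts(table_k$counts, categories, "morisita_overlap")
  if (is.null(categories)) {
    if (!setequal(names(nj), names(nk))) {
      stop("the two diet tables cover different item sets; ",
           "supply 'categories' to align them")
    }
    nk <- nk[names(nj)]
  }
  Nj <- if (n_basis == "scats") table_j$n_scats else sum(nj)
  Nk <- if (n_basis == "scats") table_k$n_scats else sum(nk)
  if (Nj < 2 || Nk < 2) {
    stop("the finite-sample correction requires N >= 2 in both groups")
  }
  if (sum(nj) <= 0 || sum(nk) <= 0) stop("all-zero counts in one group")
  pj <- nj / sum(nj)
  pk <- nk / sum(nk)
  num <- 2 * sum(pj * pk)
  den <- sum(pj * (nj - 1) / (Nj - 1)) + sum(pk * (nk - 1) / (Nk - 1))
  if (den <= 0) stop("zero denominator in Morisita's index")
  num / den
}
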