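occ_2items <- function(p_rabbit = 0.5, p_trash = 0.2) {
  expand.grid(area = c("urban", "suburban"), season = c("wet", "dry"),
              item = c("rabbit", "trash"), stringsAsFactors = FALSE) |>
    transform(prob = ifelse(item == "rabbit", p_rabbit, p_trash))
}

test_that("scat generator: forced occurrence, determinism, validation", {
  cfg <- scat_sim_config(occ_2items(p_rabbit = 1), transects_per_area = 2,
                         scats_per_transect = 10, seed = 4)
  d <- gen_scat_dataset(cfg)
  expect_true(all(d$scats$rabbit == 1))
  tab <- aggregate_scats(d$scats, by = character())[["all"]]
  expect_equal(frequency_of_occurrence(tab)[["rabbit"]], 100)

  d2 <- gen_scat_dataset(cfg)
  expect_identical(d, d2)

  bad <- occ_2items()
  bad$prob[1] <- 1.2
  expect_error(scat_sim_config(bad), "\\[0, 1\\]")
  uneven <- occ_2items()[-1, ]
  expect_error(scat_sim_config(uneven), "same items")
  expect_error(scat_sim_config(occ_2items(), transects_per_area = 0),
               ">= 1")
})

test_that("scat FO converges to the configured probability", {
  cfg <- scat_sim_config(occ_2items(p_rabbit = 0.5),
                         transects_per_area = 50,
                         scats_per_transect = 50, seed = 101)
  d <- gen_scat_dataset(cfg)  # 50 transects x 2 areas x 2 seasons x 50
  tab <- aggregate_scats(d$scats, by = character())[["all"]]
  n <- tab$n_scats
  expect_equal(n, 10000L)
  fo <- frequency_of_occurrence(tab)[["rabbit"]] / 100
  expect_lt(abs(fo - 0.5), 3 * sqrt(0.5 * 0.5 / n))
  # wet-season scats carry wet months only
  months <- as.integer(sub("^2017-", "", d$scats$year_month))
  season <- assign_season(months)
  expect_true(all(months[season == "wet"] %in% c(11, 12, 1:4)))
})

test_that("empty scats are reported and can be resampled away", {
  occ <- occ_2items(p_rabbit = 0.05, p_trash = 0.05)
  cfg <- scat_sim_config(occ, transects_per_area = 5,
                         scats_per_transect = 40, seed = 6)
  d <- gen_scat_dataset(cfg)
  expect_gt(d$n_empty, 0)
  cfg2 <- scat_sim_config(occ, transects_per_area = 5,
                          scats_per_transect = 40, resample_empty = TRUE,
                          seed = 6)
  d2 <- gen_scat_dataset(cfg2)
  expect_equal(d2$n_empty, 0)
})

test_that("altered-open-space slope shifts anthropogenic items only", {
  cfg <- scat_sim_config(occ_2items(0.5, 0.2), transects_per_area = 3,
                         scats_per_transect = 5, altered_slope = -4,
                         anthropogenic_items = "trash", seed = 12)
  d <- gen_scat_dataset(cfg)
  tr <- d$truth
  expect_true(all(tr$prob[tr$item == "rabbit"] == 0.5))
  shifted <- tr$prob[tr$item == "trash"]
  alt <- d$transects$altered[match(tr$transect[tr$item == "trash"],
                                   d$transects$transect)]
  expect_equal(shifted, plogis(qlogis(0.2) - 4 * alt), tolerance = 1e-12)
})

test_that("whisker generator reproduces the forward model at zero noise", {
  src <- toy_sources_k2()
  cfg <- whisker_sim_config(
    proportions = list(urban = c(low = 0.3, high = 0.7)),
    sources = src, between_sd = c(c13 = 0, n15 = 0),
    within_sd = c(c13 = 0, n15 = 0), n_individuals = 4, seed = 9)
  d <- gen_whisker_dataset(cfg)
  corrected <- tdf_correct_sources(src, trophic_discrimination())
  fm <- forward_model(c(0.3, 0.7), corrected)
  expect_true(all(abs(d$whiskers$d13C - fm$mean[["d13C"]]) < 1e-9))
  expect_true(all(abs(d$whiskers$d15N - fm$mean[["d15N"]]) < 1e-9))

  # single source: subsample means center on its corrected mean
  cfg1 <- whisker_sim_config(
    proportions = list(u = c(low = 1)),
    sources = src[1, ], between_sd = c(c13 = 0, n15 = 0),
    within_sd = c(c13 = 0.5, n15 = 0.5), n_individuals = 6,
    subsample_mean = 30, subsample_sd = 0, seed = 10)
  d1 <- gen_whisker_dataset(cfg1)
  se <- 0.5 / sqrt(nrow(d1$whiskers))
  expect_lt(abs(mean(d1$whiskers$d13C) - corrected$mean_c13[1]), 4 * se)

  expect_error(whisker_sim_config(list(u = c(low = 0.5, high = 0.4)),
                                  src), "sum to 1")
  expect_error(whisker_sim_config(list(u = c(low = 1)), src), "length")
})

test_that("whisker variance components match configured SDs", {
  cfg <- whisker_sim_config(
    proportions = list(g = c(low = 0.5, high = 0.5)),
    sources = toy_sources_k2(),
    between_sd = c(c13 = 1.2, n15 = 0.7),
    within_sd = c(c13 = 0.9, n15 = 1.1),
    n_individuals = 30, subsample_mean = 16, subsample_sd = 7, seed = 14)
  d <- gen_whisker_dataset(cfg)
  # within-individual SD: residuals around each individual's own mean
  within_var <- function(col) {
    sum(unlist(lapply(split(d$whiskers[[col]], d$whiskers$individual),
                      function(v) (v - mean(v))^2))) /
      (nrow(d$whiskers) - length(unique(d$whiskers$individual)))
  }
  expect_lt(abs(sqrt(within_var("d13C")) - 0.9) / 0.9, 0.2)
  expect_lt(abs(sqrt(within_var("d15N")) - 1.1) / 1.1, 0.2)
  # between-individual SD from the latent truth
  expect_lt(abs(sd(d$truth$individuals$latent_c13) - 1.2) / 1.2, 0.35)
  # determinism
  expect_identical(gen_whisker_dataset(cfg)$whiskers, d$whiskers)
})

test_that("covariate generator respects ranges and correlation", {
  cc <- diag(4)
  dimnames(cc) <- list(c("urban", "altered", "roads", "humans"),
                       c("urban", "altered", "roads", "humans"))
  cc["roads", "humans"] <- cc["humans", "roads"] <- 0.9
  cfg <- covariate_sim_config(n_buffers = 500, correlation = cc, seed = 77)
  tab <- gen_covariate_table(cfg)
  expect_true(all(tab$urban >= 0 & tab$urban <= 1))
  expect_true(all(tab$altered >= 0 & tab$altered <= 0.35))
  expect_true(all(tab$roads >= 1 & tab$roads <= 16))
  r <- cor(tab$roads, tab$humans)
  expect_gt(r, 0.8)
  expect_lt(r, 0.97)
  # the default correlation structure is also strongly collinear
  tabd <- gen_covariate_table(covariate_sim_config(n_buffers = 500,
                                                   seed = 78))
  expect_gt(cor(tabd$roads, tabd$humans), 0.7)

  # degenerate ranges give constant columns
  cfg0 <- covariate_sim_config(n_buffers = 10,
                               urban_range = c(0.4, 0.4),
                               altered_range = c(0.1, 0.1),
                               roads_range = c(5, 5),
                               humans_range = c(2, 2), seed = 1)
  tab0 <- gen_covariate_table(cfg0)
  expect_equal(unique(tab0$urban), 0.4)
  expect_equal(unique(tab0$roads), 5)

  expect_error(covariate_sim_config(urban_range = c(-0.1, 1)), "\\[0, 1\\]")
  expect_error(covariate_sim_config(roads_range = c(-2, 5)),
               "non-negative")
  expect_identical(gen_covariate_table(cfg), gen_covariate_table(cfg))
})
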