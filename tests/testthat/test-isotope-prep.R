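test_that("delta notation closed forms", {
  expect_equal(delta_value(0.0112372, 0.0112372), 0)
  expect_equal(delta_value(1.01 * 0.0112372, 0.0112372), 10,
               tolerance = 1e-9)
  expect_equal(delta_value(0.98 * 0.0112372, 0.0112372), -20,
               tolerance = 1e-9)
  expect_error(delta_value(1, 0), "positive")
})

test_that("source summaries use n-1 SDs and flag singletons", {
  samples <- data.frame(source = c("x", "x", "solo"),
                        d13C = c(-23, -22, -25),
                        d15N = c(5, 6, 4))
  expect_warning(st <- summarize_sources(samples), "solo")
  x <- st[st$source == "x", ]
  expect_equal(x$mean_c13, -22.5)
  expect_equal(x$sd_c13, sd(c(-23, -22)))
  expect_equal(st[st$source == "solo", "sd_c13"], 0)
  expect_error(summarize_sources(data.frame(source = character(),
                                            d13C = numeric(),
                                            d15N = numeric())), "empty")

  # recovery of configured distribution within sampling error (3 SE)
  set.seed(11)
  n <- 400
  fig <- data.frame(source = "figs", d13C = rnorm(n, -28.3, 2.2),
                    d15N = rnorm(n, 5.5, 3.4))
  st <- summarize_sources(fig)
  expect_lt(abs(st$mean_c13 - (-28.3)), 3 * 2.2 / sqrt(n))
})

test_that("moment pooling equals pooling the raw samples", {
  src <- reference_sources()
  rg <- combine_sources(src, c("rabbits", "pocket gophers"),
                        "rabbit-gopher")
  row <- rg[rg$source == "rabbit-gopher", ]
  expect_equal(row$mean_c13, (12 * -23.0 + 11 * -23.6) / 23,
               tolerance = 1e-9)
  expect_equal(row$n, 23L)

  # oracle: summarize concatenated raw samples vs pool their moments
  set.seed(3)
  a <- rnorm(12, -23.0, 2.0)
  b <- rnorm(11, -23.6, 2.2)
  raw <- data.frame(source = rep(c("a", "b"), c(12, 11)),
                    d13C = c(a, b), d15N = 0)
  st <- suppressWarnings(summarize_sources(raw))
  pooled <- combine_sources(st, c("a", "b"), "ab")
  direct <- data.frame(source = "ab", d13C = c(a, b), d15N = 0)
  st2 <- summarize_sources(direct)
  expect_equal(pooled[pooled$source == "ab", "mean_c13"], st2$mean_c13,
               tolerance = 1e-12)
  expect_equal(pooled[pooled$source == "ab", "sd_c13"], st2$sd_c13,
               tolerance = 1e-12)

  # combining a source with itself keeps mean and SD
  twin <- source_table(c("p", "q"), -20, 1.3, 5, 0.8, 6)
  self <- combine_sources(twin, c("p", "q"), "pq")
  expect_equal(self$mean_c13, -20)
  expect_equal(self$sd_c13, sqrt(10 * 1.3^2 / 11), tolerance = 1e-12)
  expect_error(combine_sources(src, c("rabbits", "domestic cats")),
               "natural with an anthropogenic")
})

test_that("TDF correction shifts means and inflates SDs", {
  src <- source_table("gs", -22.7, 0.9, 6.6, 1.4, 12)
  corr <- tdf_correct_sources(src, trophic_discrimination())
  expect_equal(corr$mean_c13, -21.2)
  expect_equal(corr$mean_n15, 10.1)
  expect_equal(corr$sd_c13, sqrt(0.81 + 0.25), tolerance = 1e-12)
  ident <- tdf_correct_sources(src, trophic_discrimination(0, 0, 0, 0))
  expect_equal(ident$mean_c13, src$mean_c13)
  expect_equal(ident$sd_c13, src$sd_c13)
  # correction never decreases the SD
  set.seed(5)
  for (i in 1:10) {
    s <- source_table("s", -20, runif(1, 0, 3), 5, runif(1, 0, 3), 5)
    tt <- trophic_discrimination(1.5, 3.5, runif(1, 0, 1), runif(1, 0, 1))
    cc <- tdf_correct_sources(s, tt)
    expect_gte(cc$sd_c13, s$sd_c13)
    expect_gte(cc$sd_n15, s$sd_n15)
  }
  # per-source Delta13C override
  two <- source_table(c("hf", "gs"), c(-20.9, -22.7), c(0.9, 0.9),
                      c(4.9, 6.6), c(0.7, 1.4), c(14, 12))
  ov <- tdf_correct_sources(two, trophic_discrimination(),
                            c13_overrides = c(hf = 2.5))
  expect_equal(ov$mean_c13, c(-18.4, -21.2))
  expect_error(tdf_correct_sources(two, trophic_discrimination(),
                                   c13_overrides = c(nope = 2)), "unknown")
})

test_that("tissue back-calculation and TDF round trip", {
  hf <- back_calculate_source("human food", -18.9, 0.9, 8.5, 0.7, 14)
  expect_equal(hf$mean_c13, -20.9)
  expect_equal(hf$mean_n15, 5.0)
  expect_equal(hf$sd_c13, 0.9)
  # the packaged reference table carries the reported diet-space values
  ref <- reference_sources()
  hf_ref <- ref[ref$source == "human food", ]
  expect_equal(hf_ref$mean_c13, -20.9)
  expect_equal(hf_ref$mean_n15, 4.9)
  expect_equal(hf_ref$sd_n15, 0.7)
  ident <- back_calculate_source("x", -18.9, 0.9, 8.5, 0.7, 14,
                                 delta_c13 = 0, delta_n15 = 0)
  expect_equal(ident$mean_c13, -18.9)
  # back-calculate then correct with the same deltas restores the mean
  rt <- tdf_correct_sources(hf, trophic_discrimination(2.0, 3.5, 0, 0))
  expect_equal(rt$mean_c13, -18.9, tolerance = 1e-12)
  expect_equal(rt$mean_n15, 8.5, tolerance = 1e-12)
})

test_that("anthropogenic threshold picks the right source and scales", {
  src <- reference_sources()
  thr <- anthropogenic_threshold(src, trophic_discrimination(), k_sd = 1)
  expect_equal(as.numeric(thr), -20.3, tolerance = 1e-12)
  expect_equal(attr(thr, "source"), "ground squirrels")
  expect_equal(as.numeric(anthropogenic_threshold(src, k_sd = 0)), -21.2,
               tolerance = 1e-12)
  two <- source_table(c("lo", "hi"), c(-25, -23), c(1, 2), c(5, 5),
                      c(1, 1), c(5, 5))
  expect_equal(as.numeric(anthropogenic_threshold(two)), -19.5,
               tolerance = 1e-12)
  # monotone in k_sd and Delta13C
  ks <- sapply(c(0, 0.5, 1, 2),
               function(k) anthropogenic_threshold(src, k_sd = k))
  expect_true(all(diff(ks) > 0))
  ds <- sapply(c(0, 1, 2), function(d) {
    anthropogenic_threshold(src, trophic_discrimination(c13 = d))
  })
  expect_true(all(diff(ds) > 0))
  only_anthro <- source_table("cats", -16.7, 1.7, 6.6, 0.7, 12,
                              anthropogenic = TRUE)
  expect_error(anthropogenic_threshold(only_anthro), "no natural")
})

test_that("consumer classification uses the natural-leaning tie rule", {
  w <- data.frame(
    individual = rep(c("u1", "r1", "tie"), each = 2),
    area = rep(c("urban", "rural", "rural"), each = 2),
    sex = "F", subsample = rep(1:2, 3),
    d13C = c(-18, -18, -21.6, -21.6, -20.3, -20.3),
    d15N = 5)
  cl <- classify_consumers(w, threshold = -20.3)
  lab <- setNames(cl$individuals$label, cl$individuals$individual)
  expect_equal(lab[["u1"]], "anthropogenic-leaning")
  expect_equal(lab[["r1"]], "natural-leaning")
  expect_equal(lab[["tie"]], "natural-leaning")
  fr <- setNames(cl$area_fractions$pct_anthropogenic,
                 cl$area_fractions$area)
  expect_equal(fr[["urban"]], 100)
  expect_equal(fr[["rural"]], 0)
  expect_error(classify_consumers(w, Inf), "finite")
})
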