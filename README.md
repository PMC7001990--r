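# urbandiet

Diet analysis for carnivores along an urban–rural gradient, combining
two complementary data streams:

* **scat occurrence records** — per-item frequency of occurrence
  (FO = 100·nᵢ/N), percentage of occurrence (PO = 100·nᵢ/Σnᵢ), Levins
  niche breadth (B = 1/Σpᵢ²), and Morisita's corrected niche overlap
  C = 2Σpᵢⱼpᵢₖ / [Σpᵢⱼ(nᵢⱼ−1)/(Nⱼ−1) + Σpᵢₖ(nᵢₖ−1)/(Nₖ−1)];
* **stable isotopes (δ13C, δ15N) measured along vibrissae** — source
  summarization and pooling, trophic-discrimination correction
  (mean + Δ, SD inflated by the TDF uncertainty), back-calculation of a
  human-food source from human hair, a natural-vs-anthropogenic δ13C
  threshold, a from-scratch Bayesian stable-isotope mixing model
  (Dirichlet prior on the diet-proportion simplex, Normal likelihood
  with forward variance Σpₖ²σₖ² plus residual variance, adaptive
  Metropolis on a softmax transform, split-R̂/ESS diagnostics), and the
  WIC/TNW sum-of-squares decomposition of individual specialization;
* **land-use covariate models** — variance-stabilizing transforms, OLS
  ANCOVA-style fits, AIC ranking with relative likelihoods and Akaike
  weights ω = exp(−ΔAIC/2)/Σexp(−ΔAIC/2), and a Pearson collinearity
  screen.

Seeded synthetic-data generators (scat records, whisker profiles,
buffer covariates) with known ground truth make every stage testable
end-to-end, and `run_pipeline()` drives the whole analysis from the
input tables to a written report with a reproducibility manifest.

## Worked example

Scat indices on a simulated two-area dataset:

```r
library(urbandiet)

occ <- expand.grid(area = c("urban", "suburban"), season = c("wet", "dry"),
                   item = c("rabbits", "trash", "domestic cats"),
                   stringsAsFactors = FALSE)
occ$prob <- with(occ, ifelse(item == "rabbits",
                             ifelse(area == "urban", 0.25, 0.55),
                      ifelse(item == "trash",
                             ifelse(area == "urban", 0.25, 0.06), 0.2)))
sim <- gen_scat_dataset(scat_sim_config(occ, transects_per_area = 10,
                                        scats_per_transect = 40, seed = 7))
tabs <- aggregate_scats(sim$scats, by = "area")
round(frequency_of_occurrence(tabs$urban), 1)
#> domestic cats       rabbits         trash
#>          20.0          25.1          25.2
cats <- c("rabbits", "trash", "domestic cats")
levins_niche_breadth(tabs$urban, cats)     # 2.97: broad urban diet
levins_niche_breadth(tabs$suburban, cats)  # 1.95: rabbit-dominated
morisita_overlap(tabs$urban, tabs$suburban, n_basis = "occurrences")
#> [1] 0.801
```

The FO estimates sit at the configured truth (0.25, 0.25, 0.2), the
urban diet is the broader one by construction, and the two areas
overlap substantially but not completely.

Isotopes: threshold, mixing model, and specialization on simulated
whiskers drawn from a known diet over the packaged reference sources:

```r
sources <- reference_sources(combine_rabbit_gopher = TRUE)
thr <- anthropogenic_threshold(sources)   # -20.3 (per mil, d13C)

truth <- c("ground squirrels" = 0.08, "Jerusalem crickets" = 0.05,
           "figs" = 0.06, "domestic cats" = 0.35,
           "rabbit-gopher" = 0.09, "human food" = 0.37)
sim <- gen_whisker_dataset(whisker_sim_config(
  proportions = list(urban = truth[sources$source]), sources = sources,
  c13_overrides = c("human food" = 2.5), n_individuals = 29, seed = 42))

spec <- mixing_spec(whisker_means(sim$whiskers), sources,
                    tdf = trophic_discrimination(),
                    c13_overrides = c("human food" = 2.5), seed = 1)
fit_mixing_model(spec)
#> Bayesian mixing model posterior: 6 sources, 36000 retained draws
#>   converged: TRUE | max R-hat: 1.027 | min ESS: 261
#>               source  mean    sd   q2.5   q25   q50   q75 q97.5
#> 1   ground squirrels  7.06  5.73  0.348  2.56  5.63 10.18  21.2
#> 2 Jerusalem crickets  9.61  7.15  0.283  3.70  8.19 14.20  25.6
#> 3               figs  4.55  3.96  0.149  1.46  3.46  6.58  14.6
#> 4      domestic cats 43.10 10.41 21.725 35.87 43.85 50.92  60.7
#> 5         human food 24.66 15.84  1.272 11.23 22.89 35.70  58.5
#> 6      rabbit-gopher 11.01  9.31  0.435  3.46  8.22 16.49  33.6
```

Every true proportion (in percent: 8, 5, 6, 35, 9, 37) lies inside its
95% credible interval; the wide human-food/domestic-cat intervals are
honest — those two C4-signature sources are only weakly separable from
two isotopes.  The same whiskers decompose into variance components:

```r
variance_components(sim$whiskers)
#>   group isotope      WIC      BIC      TNW     index
#> 1 urban    d13C 1075.594 361.9936 1437.587 0.7481936
#> 2 urban    d15N 2318.255 266.4063 2584.661 0.8969279
```

so ~75% (δ13C) and ~90% (δ15N) of the niche width lies within
individuals — little specialization, as expected from a shared diet
with only individual-level noise.

Applied to a published ΔAIC column, `akaike_weights()` rebuilds the
full model-weight table:

```r
akaike_weights(c(0, 3.88, 4.61, 5.99, 6.29, 26.57, 30.41, 30.95))
#>   delta_aic rel_likelihood weight
#> 1      0.00          1.000  0.748
#> 2      3.88          0.144  0.108
#> 3      4.61          0.100  0.075
#> ...
```

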