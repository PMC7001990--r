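---
title: "Methods: diet analysis across an urbanization gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet analysis across an urbanization gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbandiet)
```

## The scientific problem

Urban landscapes subsidize generalist carnivores with human-associated
food: trash, pet food, ornamental fruit, and domestic animals.  Two
complementary data streams measure how much a population leans on these
subsidies and whether individuals specialize.  Scat contents give a
per-meal occurrence record of identifiable items; stable isotopes
(δ13C, δ15N) of vibrissa (whisker) keratin integrate assimilated
biomass over weeks to months, and — because North American human food
is dominated by corn (a C4 plant) — carry a distinctive carbon
signature relative to the native C3 flora.  `urbandiet` implements the
full computational chain for such a study: occurrence indices and niche
overlap from scats, source preparation and a Bayesian mixing model from
isotopes, a within- versus between-individual variance decomposition
for specialization, and AIC comparison of land-use covariate models —
plus seeded simulators for all four input tables so that every stage
can be validated against known truth.

## Occurrence indices

For a group of `N` scats with `n_i` scats containing item `i`:

* **FO** (frequency of occurrence) `= 100 n_i / N`.  Interpreted per
  item; totals exceed 100% whenever scats contain several items.
* **PO** (percentage of occurrence) `= 100 n_i / Σn_i`; sums to 100%.
* **Levins niche breadth** `B = 1 / Σ p_i²` with `p_i = n_i / Σn_i`,
  computed by default over the nine standard analysis categories
  (`diet_categories()`): birds, reptiles, invertebrates, trash,
  ornamental fruit and seeds, domestic cats, rabbits, ground squirrels,
  pocket gophers.  `B` runs from 1 (monophagy) to the category count
  (uniform use).
* **Morisita overlap** between groups j and k uses the finite-sample
  corrected form

  `C = 2 Σ p_ij p_ik / [ Σ p_ij (n_ij − 1)/(N_j − 1) + Σ p_ik (n_ik − 1)/(N_k − 1) ]`,

  with `p = n / Σn` and `N` the number of scats collected for the
  group.  `C` is 0 for disjoint diets and ≈ 1 for identical ones; the
  correction can push it slightly above 1 and we deliberately do not
  clip.  Two conventions are genuinely open here and are exposed
  rather than hidden.  First, the basis of `N`: the group's scat count
  (the definition we follow) or the occurrence total `Σn`; the
  `n_basis` argument flips between them for sensitivity checks (they
  coincide whenever each scat holds one item).  Second, the item
  universe: breadth is defined on the nine analysis categories, but no
  such restriction is inherent to overlap, so `morisita_overlap()`
  defaults to all shared items and takes a `categories` argument to
  restrict — comparisons between the two bases are then explicit in
  user code instead of implicit in a default.

Presence is counted per scat: an item found twice in one scat counts
once, because FO counts scats, not fragments.

## Isotope source preparation

δ values are carried in per mil throughout; raw isotope ratios appear
only in `delta_value()`.  Source tissue samples are summarized per
source with `n − 1` SDs; a source with a single sample reports SD 0
with a warning (so toy fixtures run) and the mixing model floors all
source SDs at 1e-6, treating them as near-delta distributions.

Trophic discrimination (`trophic_discrimination()`) moves sources from
diet space into consumer-tissue space: `mean' = mean + Δ`,
`SD' = sqrt(SD² + SD_Δ²)`.  Defaults are the keratin values Δ13C =
1.5‰ and Δ15N = 3.5‰ with SD 0.5‰ each; a per-source Δ13C override
(typically 2.5‰ for a human-food source, the carnivore-keratin value)
is available wherever the correction is applied.  Whether the override
keeps the same 0.5‰ SD is not standardized; we default to 0.5‰ and
leave it configurable.

A human-food source is estimated from human hair by subtracting hair
discrimination (2.0‰ for δ13C, 3.5‰ for δ15N); SDs carry through
unchanged.  The packaged reference table stores the reported
diet-space values (−20.9 ± 0.9‰, 4.9 ± 0.7‰) directly, because the
δ15N value derives from the unrounded hair mean and cannot be
recovered exactly from the rounded hair summary.

The **anthropogenic threshold** is the theoretical maximum tissue δ13C
attainable on natural prey alone: the natural source with the highest
mean δ13C, TDF-corrected, plus `k_sd` of that source's SDs (default
1).  With the packaged reference values this is −22.7 + 1.5 + 0.9 =
−20.3‰.  An individual whose mean whisker δ13C exceeds the threshold
is classified anthropogenic-leaning; exact equality classifies as
natural-leaning, because the threshold is a maximum a natural diet can
hold.

Isotopically indistinguishable prey may be pooled a priori before
mixing (`combine_sources()`), e.g. rabbits + pocket gophers into
"rabbit-gopher".  Pooling is exact two-group moment pooling (weighted
mean; within- plus between-source variance), which reproduces what
summarizing the concatenated raw samples would give — including the
small SD shrink when combining a source with itself, which is a
property of the `n − 1` denominator, not an approximation.

## The Bayesian mixing model

Consumers enter as one observation per individual (the mean of the
whisker subsample series), fitted separately per study area, since the
group-level diet is the estimand and individuals have unequal
subsample counts.  For a proportion vector `p` on the K-simplex and
TDF-corrected sources with means `μ_k` and SDs `σ_k`:

* forward mean per isotope: `Σ_k p_k μ_k`
* forward variance: `Σ_k p_k² σ_k²`
* likelihood: each consumer's (δ13C, δ15N) is independent Normal with
  the forward mean and variance `forward var + σ_resid²` per isotope
* priors: `p ~ Dirichlet(α)` (default α = 1, uniform on the simplex);
  residual SDs half-Normal with scale 2‰ (a weakly informative choice
  spanning the spread seen in consumer groups); both configurable.

Sampling works on an unconstrained scale: a softmax transform of the
simplex with the last coordinate as reference (the log-density
includes the transform's Jacobian, `Σ log p_k`) plus log residual SDs.
The sampler is adaptive random-walk Metropolis: a short diagonal
phase tunes per-coordinate scales toward 0.234 acceptance, after which
the proposal switches to a scaled empirical-covariance kernel
(adaptive Metropolis) refreshed every 50 iterations; all adaptation
stops at the end of burn-in, so the retained chain is a valid Markov
chain.  Defaults are 4 chains × 10 000 iterations with 1 000 burn-in —
ample for K = 6 sources — and the run is fully reproducible from the
spec's seed.  Convergence is reported per parameter as split-R̂ and an
autocorrelation-based effective sample size (Geyer initial positive
sequence); any split-R̂ above 1.1 flags the result and warns, never
silently returns.  Elemental concentration weighting is not modelled.

Correctness is checked two independent ways in the test suite: exact
deterministic grid integration over the simplex for K = 2 and K = 3
(agreement within 0.03 on posterior means), and simulation-based
calibration — 20 replicates of 50 consumers generated from a known
six-source proportion vector, requiring the true human-food proportion
inside the 95% credible interval in at least 90% of replicates.

## Individual specialization (WIC/TNW)

For each group and isotope, with individual as the factor: TNW is the
total sum of squares of all subsamples around the grand mean, WIC the
pooled sum of squares around each individual's own mean, and BIC the
between-individual remainder, so WIC + BIC = TNW exactly.  The index
WIC/TNW runs from 0 (strong specialization) to 1 (no individual
variation).  Sums of squares — not mean squares — are used, because the
reported percentage decompositions in this literature are SS ratios;
the two differ under unbalanced subsampling, and the SS form is the
one whose ratios reproduce the published percentages.  Individuals
with a single subsample contribute 0 to WIC but still widen TNW; they
are listed in a warning.  The index is computed per isotope with no
bivariate pooling.  On hierarchically simulated data the index
converges to σ²_within / (σ²_within + σ²_between) as subsample counts
grow, which the property tests check with generous bands.

## Land-use covariate models

Covariate transforms (`sqrt`, `square`, `log`, `arcsine_sqrt`) are
explicit, and a log of zero is an error naming the offending buffer
unless the user configures an offset — real buffer tables contain
exact zeros (a fully natural buffer), and silently shifting them would
change model ranking.  Models are ordinary least squares with
treatment contrasts (alphabetically first level as reference); the
Gaussian log-likelihood is evaluated at the MLE and
`AIC = 2k − 2 logLik` with `k` counting the residual variance.  Akaike
weights depend only on ΔAIC, so any consistent `k` convention
reproduces a published weight column from its ΔAIC column — which is
exactly what `akaike_weights()` applied to a printed ΔAIC vector does.
AIC (not AICc) is the default.  Rank deficiency errors with the
aliased terms named, and `aic_rank()` refuses to compare fits on
differing response data.  `correlation_screen()` provides the Pearson
r / t-test collinearity screen that typically motivates the non-nested
model set.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated:

* **Scats** (`gen_scat_dataset`): items occur independently per scat
  with per-area, per-season probabilities; only marginal FO is used
  downstream, so co-occurrence structure is deliberately not modelled.
  Empty scats are kept and counted in `N` (a config flag resamples
  them), keeping denominator semantics explicit.  An optional
  logit-scale slope ties anthropogenic-item probability to a
  per-transect altered-open-space proportion, so covariate effects can
  be planted and recovered.  Wet-season scats are dated
  November–April, dry May–October.
* **Whiskers** (`gen_whisker_dataset`): a forward model of the mixing
  equations — group mean from the true proportion vector and
  TDF-corrected sources; individual latent means at the
  between-individual SD; subsamples at the within-individual SD;
  subsample counts drawn around 16 ± 7 (floored at 1), the typical
  vibrissa sectioning yield.  Default SDs (between 0.9/0.6‰, within
  1.7/2.4‰ for δ13C/δ15N) are of the magnitude implied by published
  variance-component tables for urban coyote whiskers.  Segments are
  treated as exchangeable: no temporal autocorrelation along the
  whisker, no seasonal signal.
* **Covariates** (`gen_covariate_table`): a Gaussian copula imposes a
  configurable correlation structure (default: roads–humans 0.88,
  roads–urban 0.81, humans–urban 0.78, altered independent) on
  range-scaled uniform marginals, reproducing the strong collinearity
  of urbanization covariates.  The copula preserves rank correlation;
  the Pearson r of the uniform marginals is mildly attenuated, which
  the tests' acceptance bands account for.

Passing tests on these simulations demonstrate that the estimators
recover known truth under the stated noise model — independent item
occurrence, Normal isotope variation, exchangeable segments.  They do
not certify behaviour under features real data may add: item
co-occurrence, non-Normal or drifting isotope baselines, digestibility
bias (items eaten but not assimilated), or spatial structure among
transects.

## Numerical choices and degenerate inputs

* Seeds: every generator and the sampler take an explicit integer
  seed; identical config + seed gives byte-identical output.
* Zero-SD sources get a 1e-6 floor inside the mixing model only.
* Tie at the anthropogenic threshold → natural-leaning.
* `TNW = 0` (all values identical) is an explicit error, not NaN.
* `PO` with all-zero counts, `N = 0`, empty source groups, off-simplex
  proportion vectors (beyond 1e-6), non-positive standard ratios, and
  log-of-zero without an offset are all errors with named culprits.
* Simplex draws are checked to sum to 1 within 1e-9.

Problem sizes in the test suite are chosen for tight-but-fast checks:
grid oracles use 2001-point (K = 2) and 201² (K = 3) grids; calibration
uses 20 replicates × 50 consumers with 2 chains × 2500 iterations;
convergence property tests use 10 000-scat and 30–50-individual
simulations.

## Known limitations

The mixing model is a fixed-effects group model: no hierarchical
individual effects, no informative priors from scat data, no
concentration dependence.  Scat indices carry no sampling-effort
rarefaction and no volumetric reconstruction.  The WIC/TNW index has
no bootstrap interval.  The pipeline consumes covariates as a table;
GIS construction of buffers is out of scope.
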