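---
title: "Methods: Bayesian tree-ensemble isoscapes for bioavailable strontium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian tree-ensemble isoscapes for bioavailable strontium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The radiogenic strontium isotope ratio (⁸⁷Sr/⁸⁶Sr) in plants, water, and
animal tissues tracks the age and composition of local bedrock as filtered
through soils, dust deposition, and sea spray. Because tooth enamel fixes
the ratio ingested in childhood while bone remodels over roughly the last
decade of life, a spatial prediction of the *bioavailable* ratio — an
isoscape — lets bioarchaeologists ask whether a buried individual's tissues
are consistent with having lived at the burial site. `srscape` implements
this workflow end to end: quality screening of georeferenced sample tables,
a bounded logit transform of the ratio response, domain-blocked principal
component reduction of gridded environmental covariates, a from-scratch
Bayesian Additive Regression Trees (BART) sampler with full posterior
uncertainty, gridded prediction with uncertainty layers, region-holdout
evaluation, and posterior-predictive assessment of tissue values against a
site's predicted local range.

## Response transform and screening

Environmental ⁸⁷Sr/⁸⁶Sr values of archaeological interest in Mesoamerica
lie in a bounded band; training tables are screened to the inclusive
interval [0.703, 0.780] (`filter_ratio_range()`), and the same bounds define
the response transform

$$z = \mathrm{logit}\!\left(\frac{r - L}{U - L}\right),
  \qquad L = 0.703,\; U = 0.780,$$

with a clamp margin of $10^{-6}$ on the unit scale so exact bound values
stay finite (`sr_transform()`). Reusing the screening bounds as the
transform interval keeps the two steps consistent; both are configurable.
Regression is performed in $z$; every map product back-transforms *per
posterior draw* and only then summarizes, so medians and quantiles are true
ratio-scale posterior quantiles (means would be Jensen-biased if the order
were reversed, and the tests verify the two orders differ).

Quality control distinguishes removal from flagging. Range screening and
explicit exclusions (`apply_exclusions()`, e.g. fertilizer-contaminated
plants or humans identified as non-local) remove rows; the site-level
robust-z screen (`screen_site_outliers()`) only flags. The screen compares
each value to its site median scaled by $1.4826 \times \mathrm{MAD}$ (floored
at $10^{-7}$ so uniform sites do not divide by zero) and is a generic tool
for implausible site values — it detects simulated fertilizer offsets of
+0.003 at a ≥90% rate with ≲1% false positives at threshold 3 — not a
reconstruction of any specific contaminant assay.

Coordinates are stored as WGS84 longitude/latitude; UTM input (the common
hand-held-GPS format, e.g. Zone 14N for the packaged Oaxaca table) is
converted on ingest with a transverse-Mercator implementation of the
Krüger flattening series (order $n^4$), whose forward∘inverse round-trip is
accurate to well under 0.01 m across a zone.

## Covariate reduction

Covariate rasters arrive as aligned single-band grids tagged with a domain
block (climate, soil, geology, aerosol, terrain, distance). Within each
block, variables are z-scored and eigen-decomposed; the smallest set of
leading components reaching a configurable retained-variance threshold
(default 0.80 per block) enters the design matrix. Blocks whose variables
are individually interpretable — distance-to-coast, basement age — bypass
the reduction, as does any block with fewer than two variables. Sample type
(plant, water, human, soil, …) enters as one-hot indicators so that
heterogeneous compilations can be modeled jointly while each map is
rendered for a single reference type. Cell lookup is by containing cell
under a half-open, north-up, row-major convention; no interpolation is
applied, matching categorical geology bands and the granularity of
kilometre-scale products.

The retained-variance threshold rather than a fixed component count is
exposed because the appropriate dimensionality depends on the raster suite
a user assembles; with the synthetic landscape's two climate fields the
default yields a single climate component.

## The sum-of-trees model

The regression core is the canonical BART model, implemented from scratch
(C++ via Rcpp):

$$z_i = \sum_{j=1}^{m} g(x_i;\, T_j, M_j) + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2),$$

with the standard regularization prior: a node at depth $d$ splits with
probability $\alpha (1+d)^{-\beta}$ (defaults $\alpha = 0.95$, $\beta = 2$);
split rules are uniform over variables and over a per-variable cutpoint
grid (up to 100 interior quantiles of the training values; one-hot columns
split only at 0.5); leaf values are $N(0, \sigma_\mu^2)$ with
$\sigma_\mu = (\max z - \min z) / (2k\sqrt{m})$ on the centred response
(default $k = 2$); and $\sigma^2 \sim \nu\lambda/\chi^2_\nu$ with $\nu = 3$
and $\lambda$ calibrated so the prior places mass $q = 0.9$ below a rough
residual-sd estimate (a saturated linear fit when $p < n$, otherwise the
response sd). Defaults are `m = 200` trees, 1,000 burn-in and 1,000
retained sweeps. All settings are exposed in `bart_config()`.

Each MCMC sweep updates every tree by one Metropolis–Hastings move —
grow (0.25), prune (0.25), change (0.40), or swap (0.10) — evaluated on the
leaf-marginalized likelihood of the tree's partial residuals, then redraws
leaf values from their normal full conditionals and $\sigma^2$ from its
scaled-inverse-$\chi^2$ full conditional. Two implementation decisions are
worth stating precisely:

* **Proposals and the restricted state space.** Grow proposals pick a leaf,
  a variable, and a cutpoint uniformly from the full grid; any proposal
  that would create an empty leaf is rejected outright. The chain therefore
  targets the posterior restricted to trees whose leaves all contain data,
  and the uniform rule prior cancels from the change and swap ratios. The
  test suite verifies this construction two ways: the grow ratio and its
  reversing prune ratio, computed through separate code paths, sum to zero
  to $10^{-10}$ along seeded traces; and on a six-point fixture with a
  frozen $\sigma$, the visit frequencies of a single-tree chain match an
  exhaustive enumeration of prior × marginal likelihood over every valid
  tree to about half a percent.

* **Determinism and stream stability.** All randomness flows through R's
  RNG in a fixed update order (move draw, rule draws, acceptance draw, leaf
  draws in node-index order, then $\sigma$), so a fit is bit-reproducible
  given its seed, and lengthening `n_draw` extends the retained stream
  without altering earlier draws.

Closed forms used by the sampler — the leaf marginal likelihood, the leaf
full-conditional moments, and the $\sigma$ draw — are unit-tested against
adaptive quadrature and prior-moment identities at $10^{-8}$ relative
error.

Posterior prediction evaluates the retained trees; `posterior_predictive =
TRUE` adds the per-draw $N(0, \sigma_d^2)$ observation noise. Maps default
to the median of predictive draws; mean-function credible maps are
available by flag, since published isoscapes rarely state which convention
they use. Variable importance is the proportion of all split rules using
each design column; when read for variable *selection* we use small
ensembles (m ≈ 20), where competition for splits makes usage frequencies
discriminating.

Posteriors serialize to a versioned JSON container in which every double is
a 17-significant-digit decimal, making the round trip bit-lossless.

## Evaluation and the locality assessment

`split_by_region()` partitions compilations by a region tag (a helper lists
the seven countries conventionally delimiting Mesoamerica), supporting
nested holdout designs: train continentally, test regionally; add regional
data, test locally. `compute_metrics()` reports RMSE and $R^2$ in both
logit and raw ratio units; the raw point prediction is the mean of
back-transformed draws, and held-out $R^2$ uses the test-set mean in its
denominator. `evaluate_baseline()` scores an externally supplied
deterministic prediction (for example a mechanistic bedrock model) with the
identical formulas, clamping stray values to the transform bounds with a
warning.

The locality module renders the site-level product: the posterior
predictive distribution of a new measurement at a site's grid cell
(`local_range_at()`), summarized by its median, interquartile range (the
"local" band), and central 95% interval. `assess_tissue()` places a
measured tissue value on a continuous spectrum of locality through the
two-sided tail probability $2\min(\hat F(v), 1 - \hat F(v))$ under the
empirical CDF of the draws (midpoint/Hazen ranks avoid saturation at 0 or
1), and reports a three-way category: *local* within the IQR, *marginal*
between the IQR and the 95% band, *nonlocal* outside. The intermediate
label is this package's convention — the band between IQR and 95% interval
has no established name — and the thresholds are configurable in effect
because the full draw vector is returned. When a measurement standard
error is supplied, the ±2 SE interval is compared against the bands and
the most local category consistent with any point of the interval is
reported, with the disagreement noted. By construction a genuinely local
observation falls in the IQR with probability one half; the suite verifies
50% ± 5 pp by simulation.

## The synthetic landscape

Real continental compilations and global raster stacks are large external
downloads, so recovery, coverage, and calibration claims are tested on a
generator with stored ground truth (`make_landscape()`, `draw_samples()`).
The landscape emulates the statistical structure the analysis assumes:

* geology is a nearest-centre partition into units (default 12 on a
  64 × 64 km grid) with ages uniform on 50–1,000 Ma and bedrock ratio
  $0.7040 + 0.0080 \cdot \mathrm{age}/\mathrm{age}_{\max}$ — older bedrock
  is more radiogenic;
* the true bioavailable field mixes bedrock with a sea-spray endmember
  (0.70918, the IAPSO seawater value) weighted by
  $e^{-d_\mathrm{coast}/\lambda}$ ($\lambda$ = 30 km, the coast being the
  western grid edge) and a dust endmember (0.7100, a generic loess-like
  value) weighted by a smooth dust index;
* covariate rasters (two climate fields, dust, elevation) are smooth
  seeded random fields; a further smooth field independent of the truth
  serves as the pure-noise benchmark covariate. Smoothness matters: a
  white-noise field would be a near-unique row identifier that tree
  ensembles memorize, which no real raster resembles;
* observations add type-dependent Gaussian noise (plant 3 × 10⁻⁴, human
  5 × 10⁻⁴, water 8 × 10⁻⁴, soil 10⁻³ in ratio units — echoing that plants
  average local bioavailable strontium while water integrates transport),
  water samples are first blended (weight 0.3) with a random same-row cell
  farther from the coast, and an optional fraction of plant samples is
  shifted by +0.003 and truth-labelled as fertilizer-contaminated;
* region tags are grid quadrants, supporting holdout experiments.

Default noise scales put the plant-sample spread on the order of 10⁻³,
matching valley-scale plant surveys. Components draw from independent
seeded substreams, so adding a covariate does not perturb sample draws.
What the generator does *not* emulate: geologically faithful terrane
geometry, spatially correlated measurement error, preferential sampling,
and the data-richness gradients of real compilations — so passing
calibration here demonstrates internal correctness of the model and
software, not field performance on real rasters.

Two calibration conventions deserve explanation:

* **Coverage is measured against held-out observations** (truth plus
  measurement noise), not the noiseless latent field, because posterior
  predictive intervals are calibrated for observables; the latent field
  has no nominal coverage level. The calibration experiment draws training
  and held-out samples of a single type (plant, the reference type of the
  maps): with a single global $\sigma$, the homoscedastic model is
  correctly specified for one type at a time, which is the setting in
  which nominal coverage is a meaningful yardstick.
* **Problem sizes.** The packaged experiments use 800 training samples and
  2,000 held-out points at default sampler settings for coverage; ten
  replicates of a 600 + 200 in-region design for the regional-calibration
  contrast; and twenty replicates at m = 20 for importance rankings. These
  sizes give stable Monte Carlo estimates while keeping a full suite run
  in the minutes range.

## Known limitations

* The error model is homoscedastic in logit space; type-dependent noise is
  absorbed into the mean via indicators, not the variance. Predictive
  intervals for a heterogeneous mixture of sample types are therefore
  approximate (the calibration experiment is type-matched for exactly this
  reason).
* Importance rankings on the synthetic landscape place unit age first
  essentially always, but the coastal term is intentionally subtle: the
  sea-spray endmember (0.70918) lies inside the bedrock range
  (0.7040–0.7120), so the coastal pull changes sign with local bedrock and
  its share of explainable variance is small. In replicate landscapes where
  near-coast bedrock happens to sit near the marine value, distance-to-coast
  is genuinely uninformative, and a chance-correlated smooth field can
  outrank it. The packaged twenty-replicate experiment documents the
  observed rate rather than guaranteeing a uniform ranking.
* Raster I/O uses the ESRI ASCII grid format (plain text, GDAL/QGIS
  readable) rather than GeoTIFF, and reprojection support is limited to
  the UTM/geographic conversion above.
* No geographic assignment (inverting the isoscape to propose origins) and
  no diet-catchment mixing: the local range is a single-cell product, and
  users should remember that a site's subsistence catchment may exceed one
  kilometre.

## Reproducibility

`scripts/acceptance.R --seed <int> --out <path>` reruns the fixture
summaries and the synthetic calibration experiments from scratch against
the installed package and writes the resulting quantities as JSON. All
experiment seeds derive from the single `--seed`; the test suite
(`testthat::test_dir("tests/testthat")`) covers every module with the
oracle checks described above.
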