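---
title: "Island-scale reef fish biomass baselines: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Island-scale reef fish biomass baselines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Remote, uninhabited coral reefs carry several times the reef fish biomass of
reefs near people, but remote reefs also differ in oceanography — wave
energy, temperature, and especially the productivity of the surrounding
ocean. Treating any remote reef as "the" pristine baseline therefore
confounds human impact with environmental setting. `reefbl` implements an
island-scale analysis that separates the two: it models island mean fish
biomass as a function of both human-population and environmental covariates,
then predicts each island's expected biomass with the human terms removed,
yielding island-specific baselines and depletion reference points.

## From diver counts to island means

The survey unit is a paired stationary point count (SPC): two divers count
and size (total length, nearest cm) every fish inside adjacent visually
estimated 15 m diameter cylinders. Fish mass follows the standard allometry
$W = a L^b$ (L in cm, W in g; `fish_mass()`). Per cylinder, biomass density
by trophic group is $\sum (\text{count} \times \text{mass}) / (\pi 7.5^2)$
g m$^{-2}$; the site value is the mean of the two cylinder densities
(`site_biomass()`). Two exclusions are applied first (`apply_exclusions()`):
sharks and jacks, whose diver-attraction behaviour biases densities
differently across locations, and sites inside strictly enforced no-fishing
MPAs, which would blur the human-density gradient.

Sites are stratified by depth bin within the forereef. Island means use the
classical area-weighted stratified estimator (`stratified_island_mean()`):

$$\bar{y} = \sum_h w_h \bar{y}_h, \qquad
  \widehat{\mathrm{Var}}(\bar{y}) = \sum_h w_h^2 s_h^2 / n_h,$$

with $w_h$ proportional to hardbottom area in stratum $h$. Strata with one
site contribute zero variance (with a warning), and no finite-population
correction is applied — site frames are effectively infinite relative to the
samples, and the variance reference the original survey literature cites is
not printed anywhere we can check, so we use the textbook estimator and say
so. Islands with fewer than 12 sites or a total-biomass CV above 0.40 are
excluded (`filter_islands()`); these defaults reproduce the published
exclusions (8-site islands with CVs of 47–87% drop; a 12-site island at CV
0.35 survives) and are configurable. Small adjacent islands can be pooled
into one reporting unit (`pool_reef_areas()`): member sites are concatenated
(stratum areas summed) before stratified estimation; oceanographic
covariates are unweighted member means, while populations and forereef areas
are summed so that people-per-hectare stays well defined.

## Covariates

Eight island-scale predictors: CHL (long-term mean chlorophyll-a just
outside the 30 m contour, mg m$^{-3}$ — a proxy for oceanic productivity),
WV (mean wave energy, kW m$^{-1}$), SSTL (mean SST of the coldest month,
°C), HC (% hard coral), CX (mean vertical substrate height, m), AT (atoll
indicator), and two human terms: HUM $= \sqrt{\text{residents} /
\text{forereef ha}}$ and HDIST (same for the population within 200 km but
not resident). The square root tames the extreme right skew of population
densities. A packaged table (`pacific_reef_areas()`) provides these values
for 37 US-affiliated Pacific reef areas. Structural complexity was scored
under two protocols over the years (a 1–5 category scale, later measured
vertical relief); `calibrate_complexity()` regresses height on category at
sites with both and converts categorical sites to predicted height.

## Collinearity screen

`collinearity_screen()` computes the Pearson matrix (AT as 0/1) and VIFs.
On the packaged table WV and SSTL correlate at $r = -0.88$; the default
policy bars any pair with $|r| \ge 0.8$ from co-occurring in a model, and
VIFs are checked within each admissible subset against the a priori cut-off
of 3. The 0.8 threshold is our own default: the analysis this mirrors acted
at 0.88 and tolerated 0.61, so any threshold in between reproduces its
behaviour; 0.8 is the conventional round value in that interval.

## The model ensemble

Every admissible subset of the 8 predictors (192 models under the WV/SSTL
constraint, including the null model) is fitted as a generalized additive
model with gamma family and log link (`mgcv`), continuous terms as
thin-plate smooths with basis dimension $k = 5$ (few response values —
dozens of islands — so larger bases invite overfitting), AT parametric.
Smoothness selection uses mgcv's GCV default; REML is a switch. Model
support uses AICc with $k$ = total effective degrees of freedom plus one
for the gamma scale (so d.f. is fractional, matching how GAM ensembles are
conventionally tabulated), Akaike weights over the *full* model space, and
variable importance as the summed weight of models containing each term.
Models with weight > 0.05 are retained; predictions average the retained
models with renormalised weights on the response scale, with unconditional
variance $\sum_i w_i (se_i^2 + (\hat y_i - \bar{\hat y})^2)$. Averaging on
the response scale matches averaging fitted biomass values; a link-scale
option exists. Full-model-space weighting for importance and retained-set
renormalisation for prediction are deliberate and asymmetric: importance is
a statement about the whole candidate space, prediction about the usable
models.

Non-convergent or failing fits are dropped with a warning and zero weight
rather than aborting the ensemble. AICc is undefined when $n \le k + 1$;
such fits are treated as failed.

## Baselines and depletion

`predict_no_humans()` re-predicts every island with HUM = HDIST = 0;
`depletion()` reports $1 - \text{observed}/\text{predicted}$ with a
first-order delta-method CI treating observed and predicted errors as
independent. 95% intervals are normal approximations (mean ± 1.96 SE) — the
construction is not specified in the source analysis, and at dozens of sites
per island the island means are close to normal. The reference report splits
islands into remote-uninhabited (zero residents, plus configured no-harvest
islands such as Midway and Palmyra that house only staff) sorted by
descending CHL, and populated islands sorted by ascending human density;
depletion is reported only for the populated panel. The reported
uncertainty is the unconditional model-averaging variance only; residual
site-level variance is not added (the baseline is an expected value, not a
new survey draw), and we note that a prediction interval for a fresh survey
would be wider.

## The synthetic world

No raw survey records are distributed with the analysis this package
mirrors, so correctness rests on a generator with known ground truth. The
generator's stated world is fixed, not tuned:

* **40 islands, 30 sites each**, three forereef depth strata with area
  fractions (0.25, 0.50, 0.25) and proportional site allocation.
* **Covariates** uniform over the ranges of the packaged table; 55% of
  islands inhabited with right-skewed densities up to 40 people ha$^{-1}$
  (the observed inhabited maximum), distant densities up to 200 ha$^{-1}$.
* **True effects on log biomass**: CHL log-linear with a 2.2-fold rise
  across its range (the published total-fish contrast); human effect
  $\exp(-\lambda\sqrt{\text{density}})$ with $\lambda = \log 4 / \sqrt{40}$
  so 40 people ha$^{-1}$ depletes 75% — the "steep decline at low density,
  gradual beyond" shape; a mild HDIST decline. Other covariates carry no
  true effect by default, so recovered importance should rank them low.
* **Baseline** 45 g m$^{-2}$ at minimum CHL with no humans, putting
  no-human expectations in the observed 34–99 g m$^{-2}$ span; trophic mix
  (primary 0.42, secondary 0.17, planktivore 0.21, piscivore 0.20) follows
  the published grand means.
* **Site noise**: gamma on site totals (the analysis family) with shape 4 —
  site-level CV of 50%, island-mean CVs near 10% at 30 sites, comparable to
  the reported island CVs (mean 14%, max 35%). The shape is a free knob:
  no site-level variance was published, so this is a realism choice, not an
  inferred quantity. Per-group draws use gamma additivity (shapes
  $\phi p_g$ on a common scale) so totals are exactly
  $\mathrm{Gamma}(\phi)$.
* **Records**: each cylinder × group target mass is decomposed into a few
  records with lognormal lengths, and one closing record whose length is
  solved from the mass remainder — record-implied mass reproduces the site
  draw to machine precision without a full size-spectrum model. Flagged
  shark/jack records and strict-MPA flags (5% of sites) are added on top
  and never count toward the target, so the exclusion step restores truth
  exactly.

What a green recovery test does establish: the pipeline is unbiased for
island means, recovers effect directions and no-human baselines within 10%,
and calibrates depletion near zero when no human effect exists. What it
does not establish: robustness to diver detectability and avoidance,
non-instantaneous counts, backreef/lagoon habitat, covariate measurement
error, or model misspecification beyond gamma noise — all outside the
generator's world.

## Numerical choices and degenerate inputs

* Cylinder pooling averages the two cylinder *densities*; for equal-area
  cylinders this equals pooling masses over combined area, so the ambiguity
  is inconsequential.
* Single-cylinder sites are kept with a warning (strict mode drops them);
  empty cylinders are represented by zero-count records.
* A duplicated-data invariance check on penalized fits must rescale the
  smoothing penalty with the data (or fix smoothing parameters): GCV/REML
  smoothness selection depends on $n$, so literal row duplication changes
  predictions. Unpenalized specs (null, parametric-only) are exactly
  invariant; tests assert the mathematically true forms.
* Perfect collinearity yields VIF = $\infty$, reported rather than dropped;
  constant columns error by name.
* Enumeration order is deterministic (model size, then lexicographic), so
  seeded runs are byte-reproducible end to end.
* Acceptance-grade recovery simulations restrict the ensemble to
  {CHL, HUM, HDIST, HC} (16 models per replicate) to keep 100 replicates
  inside a test-time budget; the 192-model enumeration and the constraint
  machinery are exercised separately.

## Worked example

```{r, eval = FALSE}
library(reefbl)
cfg <- pipeline_config(out_dir = "run1", seed = 7,
                       sim = list(n_islands = 20, sites_per_island = 15),
                       predictors = c("CHL", "HUM", "HDIST", "HC"),
                       min_sites = 0, max_cv = Inf)
res <- run_pipeline(cfg)
print(res$ensembles$total)
print(res$report)
```

## Known limitations

* Biomass from visual surveys is a relative, not absolute, measure; the
  depletion ratios inherit that caveat.
* The gamma/log-link ensemble assumes multiplicative covariate effects on
  island means; interactions are out of scope.
* Adjusted $R^2$ for gamma GAMs is mgcv's variance-explained measure; other
  definitions exist and would shift that column, though not AICc, weights
  or predictions.
* With an empty retained set (cannot happen with cutoff < 1/number of
  models, but possible after convergence failures) prediction errors out
  rather than silently falling back to the full space.
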