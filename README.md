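# reefbl — island-scale reef fish biomass baselines

`reefbl` is an R package for quantitative marine ecologists working with
size-structured diver survey data. It answers a deceptively simple question:
*how much reef fish biomass would an island hold if nobody fished it?*
Remote reefs are the usual stand-in for "pristine", but remote reefs differ
enormously in oceanographic setting — especially the productivity of the
surrounding ocean — so a single borrowed baseline confounds human impact
with environment. `reefbl` fits island-specific baselines instead.

## What it computes

1. **Site biomass** from paired stationary point count (SPC) records: fish
   mass by the allometry *W = a·L^b* (L in cm, W in g), density per 15 m
   diameter cylinder, site value = mean of the two cylinders. Sharks/jacks
   and strictly protected MPA sites are excluded first.
2. **Island means** by the area-weighted stratified estimator over depth
   strata: mean = Σ w_h·ȳ_h, Var = Σ w_h²·s_h²/n_h, with quality filters
   (≥ 12 sites, CV ≤ 0.40) and pooling of small adjacent reef areas.
3. **Collinearity screen**: Pearson matrix and variance inflation factors;
   predictor pairs with |r| ≥ 0.8 may not co-occur in one model.
4. **Model ensemble**: every admissible subset of the eight island
   predictors (AT, CHL, CX, HC, HDIST, HUM, SSTL, WV — 192 models under
   the WV/SSTL exclusion) fitted as a gamma log-link GAM (`mgcv`, basis
   dimension 5), ranked by AICc, with Akaike weights and variable
   importance over the full model space, and model-averaged predictions
   (weight > 0.05 retained set) with unconditional standard errors.
5. **Baselines and depletion**: re-prediction with HUM = HDIST = 0 and
   depletion = 1 − observed/predicted with delta-method CIs, reported as
   two panels (remote-uninhabited sorted by CHL; populated sorted by human
   density).
6. **Synthetic surveys** with known ground truth — the full hierarchy
   islands → depth strata → sites → paired cylinders → fish records — for
   parameter-recovery testing.

A packaged covariate table (`pacific_reef_areas()`) covers 37 US-affiliated
Pacific reef areas (2010-census populations, forereef hardbottom area,
long-term CHL/WV/SSTL climatologies). From it the package reproduces the
screening statistics of the analysis it mirrors: r(WV, SSTL) = −0.88,
r(WV, AT) = 0.61, inhabited densities from < 0.02 to ~38 people per
hectare of forereef.

## Worked example

Simulate a 20-island world, run the whole pipeline, inspect the total-fish
ensemble and the reference points:

```r
library(reefbl)
cfg <- pipeline_config(out_dir = "run1", seed = 7,
                       sim = list(n_islands = 20, sites_per_island = 15),
                       predictors = c("CHL", "HUM", "HDIST", "HC"),
                       min_sites = 0, max_cv = Inf)
res <- run_pipeline(cfg)
print(res$ensembles$total)
print(res$report)
```

```
Gamma log-link GAM ensemble for 'total': 16 models, 2 retained (weight > 0.05)
 CHL HUM HDIST HC  df adj_r2   aicc delta weight
   X   X     X    7.2  0.949 136.77  0.00  0.936
   X   X     X  X 8.0  0.941 142.32  5.55  0.058
Variable importance (all models):
  CHL   HUM HDIST    HC 
1.000 1.000 0.994 0.059 
Reef fish reference points
  10 remote-uninhabited reef areas (sorted high->low CHL)
  10 populated islands (sorted low->high human density)
  depletion at populated islands: 25% to 75%
```

Read: the generator's true drivers (CHL up, HUM/HDIST down) are recovered
with importance ≈ 1 while the null predictor HC ranks at 0.059; the
populated islands' estimated depletion (25–75%) brackets the generator's
truth (75% at the density maximum). `run1/` now holds every intermediate
table (`island_table.csv`, `ensemble_total.csv`, `baselines.csv`, …) plus a
`manifest.json` with seeds, row counts and input hashes; re-running with
the same seed is byte-identical.

There is also a small CLI:

```sh
Rscript -e 'reefbl::reefbl_main()' run --seed 7 --out-dir run1
Rscript -e 'reefbl::reefbl_main()' simulate --seed 7 --out-dir sim1
```

## Layout

* `R/` — survey processing, island aggregation, collinearity screen,
  model ensemble, baselines, synthetic generator, pipeline/CLI.
* `inst/extdata/pacific_reef_areas.csv` — packaged covariate table.
* `vignettes/reef-fish-baselines.Rmd` — model, assumptions, generator
  design, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles.
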