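# betabef

Tools for a multi-community biodiversity–ecosystem-functioning (BEF)
analysis of bacterioplankton: does β diversity between paired communities
increase their summed biomass, and does that effect depend on how the
communities were assembled?

The package targets a repeated marine-transect design — a fixed set of
sites sampled on many cruises, with 16S ASV count tables, a regional
phylogeny, per-site bacterial and HNF biomass (from cell counts via
carbon conversion factors), and environmental covariates. It implements:

* **Diversity** — seeded equal-depth rarefaction, Bray–Curtis
  dissimilarity for every within-cruise site pair, pooled α diversity of
  paired communities, carbon biomass conversion.
* **Assembly** — βMPTI, a tip-shuffle null-model z-score of the
  between-community mean pairwise phylogenetic distance:

  ```
  βMPTI = (MPD_obs − mean MPD_null) / SD MPD_null
  ```

  Negative values mean the two communities hold more closely related taxa
  than expected at random (homogenizing selection); positive values mean
  less related (diversifying selection). Null pools: the pair union
  (default), the cruise pool, or the whole tree.
* **BEF regressions** — hypothesis I: log summed pair biomass on log
  Bray–Curtis, as a cruise-random-intercept mixed model (REML,
  Satterthwaite p, Nakagawa–Schielzeth marginal R²) with backward
  covariate selection around a protected β-diversity term, and as
  per-cruise OLS slopes; hypothesis II: those slopes regressed on the
  per-cruise mean βMPTI across cruises.
* **Phylogenetic signal** — abundance-weighted niche values and a
  permutation Mantel correlogram of niche vs. phylogenetic distances.
* **Synthetic data** — a seeded generator for the full design (14
  cruises × 6 sites by default) with tunable assembly regime (neutral /
  homogenizing / diversifying), lognormal abundances, Brownian niche
  traits, and planted per-cruise β-diversity effects, so every estimator
  is validated against known ground truth.

## Worked example

Simulate the full design with a planted β-diversity effect of 0.17 per
cruise (pair-exact biomass mode, noise SD 0.1) and run the whole
pipeline:

```r
library(betabef)

cfg <- synthetic_config(n_cruises = 14, n_sites = 6, n_taxa = 50,
                        depth = 2000, regime = "neutral",
                        biomass_slope = 0.17, noise_sd = 0.1, seed = 42)
res <- run_all(run_config(synthetic = cfg, biomass_mode = "pair-exact",
                          n_rand = 199, seed = 42, outdir = "demo_run"))

res$h1_model
#> LMM fit: log_summed_biomass ~ log_bray_curtis + (1 | cruise_id)  (n = 210, marginal R2 = 0.446)
#>             term estimate     se  p_value
#>      (Intercept)    3.699 0.0240 1.69e-46
#>  log_bray_curtis    0.176 0.0136 9.11e-15
```

The hypothesis-I mixed model recovers the planted effect (0.176 vs. the
planted 0.17), and the backward selection drops all six environmental
covariates, which carry no planted signal here. Per cruise:

```r
head(res$effects, 4)
#>   cruise_id  slope     se p_value significant n_pairs mean_beta_mpti
#> 1       C01 0.2106 0.0908  0.0372        TRUE      15          1.106
#> 2       C02 0.1299 0.0612  0.0537       FALSE      15         -0.480
#> 3       C03 0.0491 0.0944  0.6120       FALSE      15         -0.044
#> 4       C04 0.2159 0.0831  0.0220        TRUE      15         -0.585
```

Each row is one cruise's β-diversity effect (the OLS slope over its 15
site pairs) next to the cruise's mean βMPTI. The cross-cruise regression
then asks whether the effect strengthens with assembly determinism:

```r
res$h2_model
#> LM fit: slope ~ mean_beta_mpti  (n = 14, marginal R2 = 0.129)
#>            term estimate     se  p_value
#>     (Intercept)   0.2122 0.0293 1.03e-05
#>  mean_beta_mpti   0.0678 0.0489 1.91e-01
```

Under this *neutral* regime the βMPTI coefficient is rightly
nonsignificant (p = 0.19): no slope–determinism relation was planted.
Homogenizing or diversifying regimes (`regime =`, `selection_strength =`)
plant detectable assembly structure; see the vignette for how each
regime is recovered and against which null pool.

`run_all()` writes `pairs.tsv`, `cruise_assembly.tsv`,
`cruise_effects.tsv`, `h1_model.tsv`, `h2_model.tsv`,
`beta_assembly_model.tsv`, `correlogram.tsv`, `selection_trace.txt` and
`manifest.json` to the output directory; identical config and seed give
byte-identical outputs. A thin CLI wrapper lives at
`inst/scripts/run_pipeline.R` (`--config run.yaml [--seed N] [--outdir D]`).

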