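---
title: "Beta diversity, community assembly, and ecosystem functioning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta diversity, community assembly, and ecosystem functioning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betabef)
```

## The scientific question

Biodiversity–ecosystem-functioning (BEF) research mostly asks how the
diversity *within* one community affects that community's function. This
package implements the multi-community extension for bacterioplankton:
across pairs of sampling sites, does compositional dissimilarity
(β diversity) raise the *summed* biomass of the paired communities, and is
that effect conditioned on *how* the communities were assembled? The study
design it targets is a repeated marine transect — six sites revisited on
fourteen cruises — with 16S ASV tables, flow-cytometric bacterial counts,
and standard environmental covariates per site.

Two hypotheses structure the analysis:

* **Hypothesis I.** For the 15 site pairs within a cruise, summed bacterial
  biomass increases with pair Bray–Curtis dissimilarity (both on the log
  scale), after adjusting for environmental covariates.
* **Hypothesis II.** Across cruises, the per-cruise β-diversity effect (the
  hypothesis-I slope fitted per cruise) is more positive in cruises where
  deterministic assembly selected for phylogenetically *dissimilar* taxa,
  as measured by the tip-shuffle statistic βMPTI.

## The assembly statistic: βMPTI

For a site pair with presence-based taxon sets $A$ and $B$ on a rooted
phylogeny, the observed between-community mean pairwise distance is

$$\mathrm{MPD}_{obs} = \frac{1}{|A||B|} \sum_{i \in A}\sum_{j \in B} d(i,j),$$

where $d(i,j)$ is the cophenetic (patristic) distance and shared taxa
contribute zero-distance pairs. Shuffling tip labels $n_{rand}$ times
(999 by default) gives a null distribution, and

$$\beta\mathrm{MPTI} = \frac{\mathrm{MPD}_{obs} -
  \overline{\mathrm{MPD}}_{null}}{\mathrm{SD}(\mathrm{MPD}_{null})}.$$

Negative values: the two communities hold more closely related taxa than
the shuffle expects (homogenizing selection). Positive values: less
related (diversifying selection). The statistic is the negative of the
βNRI/βNTI-family z-scores, so that its sign reads directly as
"similarity below/above random". It is abundance-unweighted: multiplying
all counts by any constant changes nothing, which the test suite asserts.

### The null pool matters

`beta_mpti()` exposes three shuffle pools, and the choice is not
cosmetic:

* `pool = "pair"` (default) permutes labels within $A \cup B$. It asks:
  *given* the taxa this pair of communities drew, are the cross-community
  pairs unusually related? It is the literal reading of "shuffle the tips
  of the phylogeny of all species in the two communities".
* `pool = "all"` permutes all tips of the regional tree. It additionally
  detects that the pool itself is a clustered subset of the region.
* `pool = "cruise"` is the intermediate (taxa observed in that cruise).

The two deterministic regimes are visible against different references,
and the package's validation uses each where it has power. When every
site selects the same clade (homogenizing), $A$ and $B$ can be nearly
identical sets; a within-union shuffle is then close to (in the limit of
identical sets, exactly) invariant, so the pair pool has little or no
power — the clustering lives in the relation between the union and the
region, and the `"all"` pool detects it strongly. Conversely, when sites
select different clades (diversifying), the overdispersion lives in the
partition of the union into $A$ and $B$; the pair pool detects it
strongly per pair, while the regional pool averages clade-adjacency
effects across the 15 pairs of a cruise and can nearly cancel. Degenerate
nulls (zero spread, e.g. identical presence sets under the pair pool) are
reported as missing values with a warning, never as numbers.

Each site pair draws its null from an RNG stream derived from
`(seed, cruise, site_a, site_b)`, so βMPTI values are independent of the
order in which pairs are processed and reruns are bit-identical.

## Diversity and biomass inputs

Counts are standardized to a common depth by a single without-replacement
draw per site (multivariate hypergeometric, via `vegan::rrarefy`),
defaulting to the minimum observed site total — the "rarefy once to the
minimum" convention. A coverage-based standardization is deliberately not
bundled: with no stated target coverage there is no defensible default,
and the depth-standardized Bray–Curtis values are what the regressions
consume. Bray–Curtis dissimilarity, pooled richness and pooled Shannon
entropy (nats) come from the rarefied counts; pair-level covariates are
the arithmetic means of the two sites' values, and pair biomass is the
arithmetic sum. Cell densities convert to carbon at
$2\times10^{-14}$ g C/cell (bacteria) and $4.7\times10^{-12}$ g C/cell
(HNF), reported as µg C/L.

## The regression stages

All responses and the β-diversity regressor enter on the natural-log
scale; pairs with Bray–Curtis exactly 0 are dropped with a warning (their
log is undefined). Environmental covariates are log-transformed likewise.

* `fit_mixed()` — hypothesis I: Gaussian linear mixed model with a random
  intercept per cruise, REML, Satterthwaite p-values (lme4/lmerTest), and
  the Nakagawa–Schielzeth marginal R² (fixed-effect variance over total).
  A singular random-intercept fit falls back to OLS with a warning, which
  also covers the zero-between-cruise-variance limit where the mixed model
  must reproduce pooled OLS.
* `backward_select()` — starts from all covariates and repeatedly removes
  the non-protected term with the largest p ≥ α (default 0.05), refitting
  until the rest are significant. The β-diversity term is always
  protected; pooled Shannon diversity can be added to the protected set
  for the robustness variant. The removal order is recorded in a
  selection trace. Note a statistical property of any such stepwise rule:
  a pure-noise covariate survives exactly when its final-examination p
  falls below α, so with $k$ independent nulls the probability that all
  are removed is about $(1-\alpha)^k$ (≈ 0.86 for $k=3$, α = 0.05) — the
  procedure is implemented as described, and its validation asserts rates
  consistent with that expectation rather than perfection.
* `fit_cruise_slopes()` — hypothesis I per cruise: OLS of log summed
  biomass on log Bray–Curtis over the cruise's pairs; the slope is the
  cruise's β-diversity effect. Cruises with fewer than 3 usable pairs, or
  zero variance in the regressor, are skipped with a warning (an error
  only if no cruise is fittable).
* `cross_cruise_regression()` — hypothesis II: OLS of the per-cruise
  slopes on the per-cruise mean βMPTI, with optional cruise-level
  covariates subjected to backward selection while the βMPTI term is
  protected. With few cruises, trailing covariates are excluded up front
  so the protected term keeps residual degrees of freedom.
* `beta_vs_assembly()` — the supporting check that β diversity itself
  rises with βMPTI, as a cruise-random-intercept mixed model.

## The synthetic-data generator

No field data ship with the package; `simulate_bef_dataset()` generates
the full study design with known ground truth, and every validation claim
rests on it. Defaults mirror the target design: 14 cruises × 6 sites,
13,129 reads per site (the depth floor the rarefaction step standardizes
to), a planted β-diversity effect of 0.17 per cruise, and biomass
intercepts giving summed pair biomasses around 40 µg C/L — realistic for
coastal bacterioplankton at ~20 µg C/L per site.

* **Phylogeny**: a Yule (pure-birth, rate 1) tree. The simplest generator
  with strictly positive branch lengths; regime behaviour does not hinge
  on the tree model.
* **Assembly regimes**: a niche trait evolves on the tree by Brownian
  motion (rate `trait_sigma`). Site sampling weights are
  $\exp(-s\,(t_i - o)^2)$ around a site optimum $o$: one shared optimum
  per cruise under homogenizing; optima spread across the trait range
  (quantiles 0.05–0.95) under diversifying. Gaussian trait selection is
  the minimal mechanism producing MPD-detectable clustering or
  overdispersion. Under `neutral`, relative abundances come from a
  lognormal species-abundance distribution (sdlog 2) with per-site
  lognormal(0, 0.5) perturbations. The high-variance SAD matters: an
  even abundance model at these depths puts every taxon in every site,
  which collapses the pair-union null; the lognormal's rare tail gives
  the presence turnover real ASV tables show.
* **Biomass**: `mode = "site"` builds site biomass from each site's mean
  dissimilarity to its cruise neighbours (a positive pair-level
  association whose sign follows the planted slope); `mode = "pair-exact"`
  emits pair observations directly from
  $\log B = a_c + b_c \log \mathrm{BC} + \varepsilon$, which exists
  solely to test the regression stages in isolation against exact ground
  truth.
* **Environment**: covariates drawn on shelf-sea gradients (temperature
  18–28 °C, salinity ≈ 33.5 PSU, lognormal nutrients, PAR, chlorophyll).
* **Seeding**: one master seed; every cruise, stage and site pair derives
  a sub-stream via `derive_seed()`, so runs are bit-reproducible and
  components can be regenerated independently.

What the generator does *not* emulate: sequencing error and chimeras,
spatial dispersal structure, temporal autocorrelation between cruises,
and realistic ASV richness (thousands). Passing validation therefore
shows the estimators recover known effects under the stated mechanisms —
not that those mechanisms exhaust real ocean data.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle or a
planted truth, at sizes chosen to keep the full run in a few minutes:

* the between-community MPD kernel against a naive double loop (100
  random trees ≤ 20 tips, agreement to 1e-9), and against an independent
  implementation (`picante::comdist`);
* the 999-shuffle null against exhaustive enumeration of all tip
  permutations on ≤ 7-tip pools (agreement within 3 Monte Carlo SE);
* null calibration on 200 independent neutral site pairs (50 taxa, depth
  2000): βMPTI mean within ±0.3, SD within 0.8–1.2. Independent
  replicates are essential here — pairs sharing one tree are strongly
  correlated and make the 200-pair mean itself a noisy quantity;
* regime recovery on 20 independent replicate cruises per regime
  (selection strength 5, trait sigma 1): homogenizing mean βMPTI < −0.5
  against the regional pool, diversifying > +0.5 against the pair pool,
  with observed margins several times those bounds;
* hypothesis-I recovery: exact interpolation of noise-free planted
  slopes, and ~95% CI coverage of the planted slope across 100 noisy
  replicates (14 cruises × 15 pairs, noise SD 0.1);
* hypothesis-II recovery: slopes planted as a positive linear function of
  each cruise's *realized* mean βMPTI (gain 0.08 on a βMPTI spread of
  several units), recovered as a positive cross-cruise coefficient in
  ≥95/100 datasets, with permuted βMPTI keeping p ≥ 0.05 at the nominal
  rate. Planting against the realized statistic, rather than the
  selection-strength knob, is deliberate: realized βMPTI is dominated by
  the tree and optimum realization, so strength is a poor proxy for a
  cruise's determinism and would confound a test of the regression
  stage;
* backward selection on a planted-signal design (1 true covariate, 3
  nulls, n = 210), with protection exact and overall recovery at the
  $(1-\alpha)^3$ rate discussed above.

## Phylogenetic signal (Mantel correlogram)

Using phylogeny to read assembly processes presumes that related taxa
have similar habitat preferences. `niche_values()` estimates a taxon's
preference as the relative-abundance-weighted mean of an environmental
variable over all cruise-sites; `niche_distances()` standardizes several
such axes and takes Euclidean distances. `mantel_correlogram()` splits
the cophenetic distances into classes (Sturges' rule by default) and
correlates niche distances with within-class membership; negative r in
short-distance classes is phylogenetic signal. P-values come from
seeded taxon-label permutations, two-sided, Holm-corrected across classes
(progressive corrections are an alternative; Holm is uniform and
conservative). Classes with fewer than 3 pairs are reported as missing.

## Numerical and design choices

* Natural logs throughout; coefficients are base-covariant.
* Two-sided tests at α = 0.05; `significant` flags are always derived
  from the stored p-values.
* Missing covariates propagate as `NA` and drop case-wise per model.
* The marginal R² and the β-diversity coefficient's p-value are reported
  as separate quantities of the hypothesis-I model.
* HNF biomass is carried as an optional covariate (pair mean), off by
  default in the selections.
* `run_all()` writes plain TSVs plus a JSON manifest (config echo, seed,
  package and R versions, input checksums, stage log); identical config
  and seed give byte-identical outputs.

## Limitations

* βMPTI is an index of the *collective* deviation from a tip-shuffle
  null; it does not partition assembly into selection, dispersal and
  drift fractions, and no nearest-taxon (βNTI-style) variant is included.
* The pair-level observations within a cruise share sites, so the 15
  pairs are not independent; the cruise random intercept absorbs only the
  between-cruise part of that structure, as in the target design.
* Coverage-based rarefaction beyond equal-depth subsampling is out of
  scope.
* With few cruises, the cross-cruise regression's covariate set is
  truncated rather than regularized; results with < ~10 cruises should be
  read as descriptive.
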