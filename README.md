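# urbanvar

Partitioning behavioral variance along urbanization gradients.

## What this package is for

Urbanization changes not only the *mean* of animal behavior but also its
*variance* — and variance is what selection acts on. For repeatedly measured
behavioral traits (e.g. breath rate under restraint, handling aggression
scores, open-field exploration counts in great tits), the questions are:

1. Is total phenotypic variance higher in urban than in forest habitats?
2. Is that driven by among-individual differences (V<sub>i</sub>) or by
   within-individual variability (V<sub>r</sub>)?
3. Does variation increase continuously with the proportion of impervious
   surface (ISA) around nest boxes, and at which spatial scale (100 m, 250 m,
   1000 m)?

`urbanvar` implements the full analysis pipeline as tested, reusable R code,
exercised end-to-end on synthetic data with exact ground truth.

## The model

For observation *j* of individual *i* in variance group *g* (habitat or
sampling location), a latent trait value is

```
l_ij = x_ij' beta + u_i + y_year(ij) + o_obs(ij) + e_ij
u_i ~ N(0, V_i[g]),  y ~ N(0, V_y),  o ~ N(0, V_o),  e_ij ~ N(0, V_r[g])
```

with group-specific ("heterogeneous") among-individual and residual
variances. Response families: Gaussian (identity), ordinal threshold /
probit (7 categories scored 0–3 by 0.5; V<sub>r</sub> fixed at 1), and
Poisson with log-normal overdispersion (counts; variances on the latent log
scale). Fitting is by Gibbs sampling with Metropolis latent updates
(Poisson) and collapsed cutpoint updates (ordinal); see the methods
vignette.

Per posterior draw, the decomposition and comparison statistics are

```
V_p  = V_i + V_y + V_f + V_r          (V_f = variance of sex + hour effects;
                                       observer variance V_o excluded)
CV_x = sqrt(V_x) / marginal mean      rpt = V_i / V_p
lnCVR_x = log(CV_x,urban / CV_x,forest)
lnRR    = log(mean_urban / mean_forest)
lnRPT   = log(rpt_urban / rpt_forest)
```

The continuous analysis is two-step: a location-grouped model yields a CV
per location per posterior iteration; each iteration's CVs are regressed on
centered/scaled mean ISA and within-site variance ISA, coefficient draws
are pooled across iterations, and the buffer radius with the largest
average Bayesian R² is the "scale of effect".

## Worked example

Simulate a Gaussian trait where urban among-individual variance is doubled
(true lnCVR_I = 0.5·log 2 ≈ 0.347), fit the habitat model, decompose and
compare:

```r
library(urbanvar)
spec <- variance_spec("gaussian", V_i = c(1, 2), V_r = c(1, 1),
                      V_y = 0.1, V_o = 0.1, intercept = 10,
                      n_individuals = 300)
tab <- simulate_observations(spec, seed = 42)          # 880 obs, 600 birds
fit <- fit_hetvar(tab, model_config("gaussian", "by_habitat",
                                    n_iter = 6000, burn_in = 1000,
                                    thin = 5, seed = 1))
cvs <- decompose_variance(fit, tab)
effect_sizes(cvs)$lnCVR_I
```

Printed output (this exact run):

```
lnCVR_I = 0.338 [0.11; 0.583]*, P(>0) = 1.00, fold = 1.4 (more)
```

Read: urban birds are about 1.4 times more variable among individuals than
forest birds; the 95% credible interval [0.11; 0.583] excludes zero (the
`*`) and covers the simulated truth 0.347. The same run gives
`lnRR = 0.00674 [-0.0492; 0.0607]` (no mean difference, as simulated) and
`lnRPT = 0.334 [0.0291; 0.727]*` (higher urban repeatability). For
reporting-grade inference use the `model_config()` defaults
(65,000 iterations), which target effective sample sizes above 1000; the
short chains above are for illustration.

The end-to-end pipeline (synthetic raster → ISA buffers → both models →
effect sizes → gradient regression → scale of effect) runs with:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "urbanvar"))
```

or from a shell via the CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "urbanvar", package = "urbanvar"))') \
    run-all --seed 42 --out demo_run
```

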