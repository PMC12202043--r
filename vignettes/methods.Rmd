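---
title: "Methods: heterogeneous-variance models for behavioral variance along urban gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous-variance models for behavioral variance along urban gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(urbanvar)
```

# The scientific problem

Repeatedly measured behavioral traits decompose into consistent differences
*among* individuals and variability *within* individuals. Comparing these
components between habitats — and along a continuous urbanization gradient —
asks whether cities inflate or erode behavioral diversity, and whether any
change sits in among-individual differences (the substrate of selection) or
in within-individual plasticity and noise. This package implements that
comparison as a three-stage pipeline: heterogeneous-variance Bayesian mixed
models, posterior variance decomposition with mean-standardized effect
sizes, and a posterior-propagated two-step regression on impervious-surface
metrics.

# The model and its assumptions

For observation $j$ of individual $i$ in variance group $g$ (habitat, or
sampling location):

$$l_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + u_i + y_{year(ij)} +
o_{obs(ij)} + e_{ij}$$

with $u_i \sim N(0, V_i[g])$, year effects $\sim N(0, V_y)$, observer
effects $\sim N(0, V_o)$ and $e_{ij} \sim N(0, V_r[g])$. Group-specific
$V_i$ (and $V_r$) are the point: "heterogeneous variance" means the random
effect variances themselves differ by group.

Three response families share this Gaussian core through a working latent
variable $l$:

* **Gaussian** — $l$ is the observed value.
* **Ordinal (probit threshold)** — the observed score (7 categories, 0–3 in
  0.5 steps) is the interval of $l$ between cutpoints
  $c_1 < \dots < c_6$. Identifiability requires fixing the latent residual
  variance at 1 and one cutpoint at 0; consequently no residual variance is
  reported for ordinal traits and no within-individual CV is computed.
* **Poisson (log-normal)** — counts are $\mathrm{Pois}(e^{l})$; the
  residual $e_{ij}$ acts as log-normal overdispersion and *is* the
  within-individual variance, on the latent log scale. All ordinal/Poisson
  variances and means are reported on the latent scale so CVs are
  internally consistent; a data-scale option (the log-normal
  back-transform $e^{\mu + V/2}$) exists but is off by default.

Two canonical structures mirror the two analyses: the **habitat model**
(two groups, habitat × {sex, age, date, hour²} interactions, heterogeneous
year and observer variances implemented as group-nested effects) and the
**location model** (one group per sampling location, no interactions,
homogeneous year and observer variances — dropping what a 9-group model
cannot support). `model_config(variance_grouping =)` selects the defaults;
each flag is overridable.

Key assumptions: individuals belong to exactly one group; random effects
are Gaussian on the latent scale; repeated measures are exchangeable given
the fixed effects and assay rank; no among-/within-trait correlations
(multivariate models are out of scope).

# Sampling

The Gaussian conditionals (fixed effects under a flat prior, all random
effects, all variances under inverse-gamma priors) are conjugate and
Gibbs-updated in vectorized R. Poisson latents are updated by
per-observation random-walk Metropolis — valid to vectorize because the
$l_{ij}$ are conditionally independent given the Gaussian part — with
proposal scales adapted during burn-in toward 0.44 acceptance. Ordinal
liabilities are truncated-normal draws; the free cutpoints get a joint
random-walk Metropolis update on log-spacings with the liabilities
*integrated out* (the classic data-augmented uniform update mixes far too
slowly at realistic sample sizes), after which liabilities are redrawn from
their full conditional — a partially collapsed Gibbs step.

**Priors.** Each variance gets an inverse-gamma prior with shape = rate =
$\nu/2$, $\nu = 0.002$, $V = 1$ (the weakly informative default
parameterization familiar from animal-model software); fixed effects get
improper flat priors. `prior_nu`/`prior_V` are config switches; the prior
sensitivity test doubles the prior scale and requires < 10% movement in
variance posteriors at 300+ individuals. A parameter-expanded prior was
considered for variances near zero but not implemented; the scale switch
plus the documented sensitivity check covers the cases the pipeline
generates.

**Defaults.** `n_iter = 65000, burn_in = 15000, thin = 50`, targeting
effective sample sizes above 1000 for every parameter. Tests and the demo
configs use documented shorter chains (roughly 1–6k iterations); this is a
runtime concession, and the diagnostics (`effective_sample_size()`,
Geweke-based `convergence_check()`) make the cost visible rather than
hiding it. The Heidelberger–Welch test was replaced by Geweke + ESS: same
intent (stationarity of the retained chain, adequate information content),
simpler and fully testable contract — iid chains pass at the nominal rate,
an injected mean shift is flagged.

# Variance decomposition and effect sizes

Per draw and group: $V_p = V_i + V_y + V_f + V_r$ **exactly** (an audited
identity, not an approximation), where $V_f$ is the variance across the
group's observed rows of the linear predictor restricted to the
*biologically relevant* fixed effects — by default sex and the hour
polynomial (circadian structure). Observer variance is measurement, not
biology: tracked, never in $V_p$.

Marginal means average predictions over a **balanced** sex × age grid
(equal weights, not observed frequencies — the simplest reading of
"marginalized across sex and age", documented as a choice since observed
frequencies are also defensible), with continuous covariates at within-group
sample means, assay rank 0, and protocol at the current (post-2017) level.

Effect sizes are computed draw-by-draw so posterior correlation between
groups is preserved: $\mathrm{lnCVR}_x = \log(CV_{x,u}/CV_{x,f})$,
$\mathrm{lnRR} = \log(\bar y_u/\bar y_f)$, $\mathrm{lnRPT} =
\log(rpt_u/rpt_f)$. lnRPT is the *log* of the repeatability ratio — the
"ln" prefix and reported scales make this reading unambiguous even where
prose omits the log. Intervals are equal-tailed quantiles by default (an
HPD switch exists; which convention the comparison literature used is
unstated, and equal-tailed is the more reproducible default). CVs of
interval-scale ordinal traits are interpretable only because the latent
mean is away from zero; they are flagged as non-comparable across studies.

# The two-step gradient analysis

Step 1: the location model yields per-iteration, per-location CVs.
Locations with fewer than 30 observations are excluded (strictly fewer; 30
stays). Step 2: for *each* iteration, regress that iteration's CVs on
centered/scaled mean ISA and variance ISA; pool all coefficient draws. The
step-2 engine is exact conjugate Bayesian linear regression under flat
priors (draw $\sigma^2$ from its scaled-inverse-$\chi^2$ marginal, then
coefficients from the matching normal), 100 draws per iteration — it
reproduces the "one Bayesian regression per iteration" contract without an
external sampler and is auditable against least squares. Pooling never
shrinks below the step-2-only uncertainty; a test asserts this.

Bayesian $R^2$ per iteration is
$\mathrm{var}(\hat y)/(\mathrm{var}(\hat y) + \sigma^2)$ averaged over that
iteration's draws (draws of the error variance, not a point estimate — the
more fully Bayesian reading of an ambiguous description), then averaged
across iterations per spatial scale. The **scale of effect** is the scale
with maximal average $R^2$; ties break toward the *smallest* scale, the
more conservative claim about spatial reach. A Spearman mean–variance
correlation (exact permutation p for $n \le 8$, asymptotic otherwise)
motivates mean-standardization in the first place.

# Landscape quantification

ISA rasters are planar grids in $[0,1]$ (10 m default resolution). A pixel
belongs to a circular buffer iff its **center** lies within the radius
(inclusive) — raster zonal convention; the original GIS workflow leaves
edge-pixel treatment unstated, so this is our documented choice, validated
against an exhaustive per-pixel oracle. Habitat classification: forest iff
mean ISA at 1000 m is strictly below 5% (exactly 5% is urban, since "below
5%" defines forest). Raster I/O is Esri ASCII grid only: no R GeoTIFF
reader is available in the supported dependency set, and the format is
plain text, which the deliverable requires anyway.

# The synthetic world

`variance_spec()` defaults state the emulated design: 2 habitats (1 forest
+ 8 urban locations) or 9 locations; 200–1200 individuals per trait
(default 300 per group); repeats distributed {1: 0.70, 2: 0.18, 3: 0.07,
4: 0.05} — a stand-in consistent with "1 to 11 breeding attempts, 22–46%
of birds repeated", since the full empirical distribution is unpublished;
9 study years (2014–2022) with the protocol switch at 2017; 6 observers;
sex/age Bernoulli(0.5); day-of-year uniform on 90–180; decimal hour
uniform on 7–20. Ordinal thresholds default to near-equal category
probabilities under the implied total latent variance. Substreams
(design / individuals / years / observers / residuals) are seeded
independently from the master seed, so enlarging one stream does not
perturb the others.

What the generator does **not** emulate: spatial autocorrelation of
individuals within locations, unbalanced observer workloads, measurement
conversion error across the protocol change, missing data, or
trait–trait correlations. A green recovery test therefore establishes that
the estimator recovers the stated generative structure — not that it is
robust to these real-data features.

Exact ground truth (`ground_truth()`) is closed-form: latent-scale CVs from
the specified variances and the balanced-grid mean, $V_f$ from Bernoulli
and uniform-covariate moments — never from simulation.

# Numerical choices and degenerate inputs

* Continuous covariates are centered at sample means in the design, so
  "prediction at the mean" is a zero contribution and intercepts are
  interpretable group means.
* Rank-deficient fixed designs abort with the aliased columns named; a
  group with no repeated individuals warns (its $V_i$/$V_r$ split is
  prior-driven) but fits.
* Truncated-normal draws use inverse-CDF sampling with probability floors
  of $10^{-12}$; cutpoint likelihoods floor category probabilities at
  $10^{-300}$ before logging.
* $rpt = 1$ boundaries (all variance among individuals) are flagged with a
  warning; non-positive marginal means make CVs undefined and abort with
  the draw and group identified.
* Variance draws from the inverse-gamma conditionals are strictly positive
  by construction, keeping all log-ratios defined.

# Known limitations

* Pure-R sampler: adequate for the tested sizes (~1–3 s per thousand
  iterations at ~10³ observations) but not for very large data; the
  natural upgrade path is an Rcpp core.
* Ordinal cutpoint mixing, though greatly improved by the collapsed
  update, still dominates the autocorrelation budget for ordinal fits.
* Model b's residual structure defaults to heterogeneous-by-location with
  a homogeneous switch; which was used originally is not fully explicit.
* No spatial autocorrelation modeling, no nonlinear ISA–variance
  relationships, no multivariate extensions — all deliberately out of
  scope.
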