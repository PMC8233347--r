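---
title: "Modelling coral bleaching vulnerability with reefvuln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coral bleaching vulnerability with reefvuln}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefvuln)
```

`reefvuln` projects coral occurrence, percent cover and bleaching
probabilities over a coastal grid with Bayesian hierarchical spatial
models, and overlays the three projections into a bleaching-vulnerability
map with hotspot classification. This vignette is the package's own
account of the models, the synthetic study conditions, the numerical
choices, and what the tests do and do not establish.

## The hierarchical models

Occurrence at site $i$ is Bernoulli with a logit link; the positive
percent responses (cover, percent bleached) are conditional-to-presence
lognormal:

$$Y_i \sim \mathrm{Bernoulli}(\pi_i), \qquad
  \mathrm{logit}(\pi_i) = \alpha^{(Y)} + X_i\beta + W_i^{(Y)}$$
$$Z_i \mid Y_i = 1 \sim \mathrm{Lognormal}(\mu_i, \sigma^2), \qquad
  \log(\mu_i) = \alpha^{(Z)} + X_i\beta + W_i^{(Z)}$$

The two hurdle components are fitted independently (the two-step
construction), each with its own coefficient vector; sharing coefficients
across components has no biological justification here. The lognormal is
parameterised on the natural-log scale, $\log Z \sim N(\mu, \sigma^2)$,
and responses are percents in $(0, 100]$: the simulator caps draws above
100 and counts them, since percent cover cannot exceed the benthos.

The spatial terms $W$ are zero-mean Gaussian fields with Matérn
covariance. We use the practical-range convention
$\kappa = \sqrt{8\nu}/\textrm{range}$, so the correlation has fallen to
about 0.14 at distance `range`; with $\nu = 0.5$ the correlation is
exactly $\exp(-2d/\textrm{range})$. Smoothness $\nu$ defaults to 1 — a
common choice for environmental fields — and is exposed, not asserted to
match any particular prior study. Distances are planar in decimal degrees
by default, adequate for a narrow coastal strip a few degrees wide;
great-circle (km) is available, in which case ranges are in km.

Fixed effects carry vague Normal(0, 100) priors. The Matérn
hyperparameters get weak lognormal hyperpriors centred on a field
standard deviation of 1 and a range of 30% of the domain diagonal.

## Inference

Fits commit to a model contract — posterior summaries, draws, and
pointwise log-likelihoods — rather than to a particular engine. The
engine supplied here is a Laplace approximation on the *whitened* latent
vector $u = (\alpha, \beta, \tilde w)$, where $W = \sigma_w L^\top
\tilde w$ and $L$ is the Cholesky factor of the Matérn correlation over
the distinct site cells, so the joint prior precision is always diagonal.
Newton iterations with step halving find the mode; the Gaussian
approximation at the mode supplies draws and the marginal likelihood.
Matérn hyperparameters are estimated by maximising that marginal
likelihood plus hyperprior (Nelder–Mead, warm-started between
evaluations), or on a coarse deterministic grid (`hyper_method = "grid"`,
the cheaper default inside model selection). For the Gaussian
(log-response) likelihood the "Laplace" step is exact, and the
observation variance $\sigma^2$ is integrated over a 15-point grid whose
width matches the local curvature of the log-evidence, so $\sigma^2$
carries genuine posterior uncertainty into the WAIC/LCPO computations.

This is the same structural approximation family (nested Laplace) used by
standard spatial-SDM toolchains; we validate it by parameter recovery on
synthetic truth, not by matching another implementation: across 20 seeded
replicates at $n = 800$ the 95% credible intervals for the intercept and
both covariate effects covered the truth in all replicates, and the
median absolute bias of the posterior means shrinks as $n$ grows through
100, 400, 1600 (see `tests/testthat/test-acceptance.R`, which computes
exactly this).

A caution the tests make explicit: when a covariate is itself a smooth
spatial gradient, it competes with the latent field, and coefficient
estimates attenuate while the field absorbs signal. The synthetic
defaults are designed so covariates carry substantial non-trend variation
(below); with purely deterministic gradient covariates, identifiability
degrades and interval calibration with it.

## Model selection

WAIC uses the pointwise definition
$\mathrm{elpd}_i = \log \tfrac1S \sum_s e^{\ell_{is}}$,
$p_i = \mathrm{Var}_s(\ell_{is})$,
$\mathrm{WAIC} = -2\sum_i(\mathrm{elpd}_i - p_i)$. The conditional
predictive ordinate is the harmonic-mean estimator
$\mathrm{CPO}_i = (\tfrac1S\sum_s e^{-\ell_{is}})^{-1}$ and
$\mathrm{LCPO} = -\tfrac1n\sum_i \log \mathrm{CPO}_i$; observations with
non-finite CPO are flagged, not dropped. (LCPO is sometimes described in
applied work as ranging from 0 to 1; the standard definition implemented
here is unbounded above, so no such bound is asserted.)

Forward selection starts from the intercept-only null without a spatial
effect and greedily adds the candidate that most improves the *combined*
criterion. There is no canonical definition of "combined", so the
package defines it as the rank sum of WAIC and LCPO within each
comparison, ties broken by WAIC — both raw values are always reported so
users can re-rank. The spatial effect is offered after the covariate
search (spatial-last; configurable to never). An exhaustive mode
evaluates all subsets for up to 5 candidates.

## Prediction and scenarios

Surfaces are posterior predictive means through the link: the mean over
draws of $\mathrm{plogis}(\eta)$ for occurrence, of
$\exp(\eta + \sigma^2/2)$ for the conditional mean, and of the hurdle
expectation $\pi\,e^{\mu + \sigma^2/2}$ (component draws paired by index)
for expected cover. The latent field is carried to unsampled cells by its
GP conditional mean, $A = R_{cn} R_{nn}^{-1}$ applied to each posterior
field draw — a linear interpolator of the draws that is exact at the
fitted nodes (the in-sample invariant is checked at 1e-6). We chose this
over barycentric interpolation on a triangulation because it respects the
fitted covariance, needs no triangulation machinery, and degrades
gracefully at the mask edge.

Future scenarios shift SST by +1 °C and SSS by +1 PSU (mid-century,
2040–2050) and +3 °C / +1.5 PSU (end-century, 2090–2100), holding every
other layer constant — future projections of the remaining variables are
treated as unavailable, which makes the scenario projections
conservative. Future stacks are standardized with the *current* means and
standard deviations, so a +3 °C shift stays visible as $+3/\mathrm{sd}$
in covariate space. The fitted spatial field is held fixed across
scenarios (no refitting); zeroing it instead is a documented toggle we
decided against, because the field encodes persistent unmeasured habitat
structure, not climate. Cells whose covariates leave the fitted range are
flagged as extrapolation but still projected — projecting to unsampled
conditions is the point of the exercise, and the flag keeps it honest.

## Vulnerability

Each projection is divided by its own sea-cell maximum (guarding against
all-zero surfaces), the three standardized surfaces are multiplied, and
the resulting $[0,1]$ surface is classified by the lower and upper
quartiles of the *current* projection — type-7 (linear interpolation)
percentiles, a convention that matters and is therefore pinned in a test
with a hand-computed example. Fixed external bounds (default 0.21, 0.78)
are available verbatim as an override. Classes are half-open,
$[0, q_{low})$, $[q_{low}, q_{high})$, $[q_{high}, 1]$, which closes the
gaps that rounded printed bounds would leave. Future surfaces are
classified against the current thresholds — required for class-area
changes (e.g. "the low-vulnerability area halves") to be meaningful.
Note that with thresholds computed as true quartiles, the hotspot class
necessarily holds about 25% of sea cells; a hotspot share of a few
percent can only arise from fixed external thresholds, which is why both
modes exist without asserting either as canonical. Kernel density
estimates (Gaussian kernel, `nrd0` bandwidth, common evaluation lattice)
summarise how the value distribution moves across scenarios.

## Synthetic study conditions

The generator is first-class, tested code: a regular 0.08° lattice with a
contiguous coastal sea band; one raster per covariate built as a smooth
monotone gradient plus a seeded Matérn noise field; latent Matérn fields
per response; Bernoulli/lognormal observations at distinct sea cells
(optionally several pooled assemblage records per site); and
scenario-shifted stacks.

Default conditions, chosen once as a plausible coastal strip: SST spans
21–28 °C along latitude (noise sd 0.4 °C, range 0.5°); salinity and
productivity run cross-shelf (river-plume geometry); turbidity and
bathymetry follow oblique gradients; pH and O2 are weak latitudinal
trends dominated by local noise. Trend directions and noise scales are
sized so distinct drivers remain statistically distinguishable — typical
pairwise |r| is 0.4–0.65, so GVIF/correlation screening is exercised
without routinely discarding the scenario drivers. Field simulation uses
exact dense Cholesky of the Matérn covariance: at desk scale the
contract is the covariance, not the factorisation.

What the generator does *not* emulate: anisotropy and coast-following
correlation, observation error in percent-cover estimates, preferential
sampling of reef sites, species-level thermal tolerance differences, and
temporal dynamics (acclimatisation, connectivity). Passing tests
therefore establish that the pipeline recovers what its own model class
generates — a necessary check of correctness, not evidence about any
real coastline.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: separation (all-presence or
all-absence) errors; fewer than 10 conditional records error; zero
variance layers refuse to standardize naming the layer; perfect
collinearity reports infinite GVIF rather than erroring, and the
screening tie-breaks (highest corrected GVIF first, then the member of
the worst pair with the larger mean |r|, alphabetical on ties) make the
audit trail deterministic. Matérn matrices carry a 1e-8 jitter;
likelihood curvatures are floored at 1e-10. Every generator and fit takes
a seed, and the pipeline derives per-stage child seeds from one global
seed so stages can be rerun in isolation; reruns are bit-identical.

The bundled configurations run a 20×20-cell grid with 150 sites per
response (the smoke pipeline) and a 40×40 grid with 500 sites (the
acceptance script); the recovery studies in the test suite use 100–1600
sites on a 40×40 all-sea grid. These sizes keep the full suite
comfortably within a desktop coffee break while exercising every code
path at the scale the dense-Cholesky engine targets (up to ~2000 latent
nodes).

## Known limitations

* The Laplace/MAP-II engine understates hyperparameter uncertainty for
  the Bernoulli field (fixed-effect intervals are validated by the
  recovery study; field-hyperparameter intervals are not reported).
* Expected-cover surfaces inherit lognormal tail sensitivity; capped
  draws (>100%) are counted and warned about but not re-modelled.
* GeoTIFF rasters are not read or written; the raster interchange format
  is long CSV (`lat,lon,name,value`), and observations are plain CSV.
* The screening order (GVIF-first vs correlation-first) changes which of
  two near-duplicates survives; both orders are supported and audited.
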