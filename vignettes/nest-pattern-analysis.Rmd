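---
title: "Disentangling endogenous and exogenous drivers of nest spatial pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling endogenous and exogenous drivers of nest spatial pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestpp)
```

## The scientific problem

Sessile organisms whose "individuals" are colonies — here, arboreal ant
nests distributed over the shade trees of a coffee plantation — often show
strongly clustered spatial patterns. Two very different mechanisms can
produce such clustering. *Exogenous* heterogeneity (tree density, terrain,
moisture) imposes a template the organisms merely reflect; *endogenous*
dynamics — colony reproduction by short-range budding opposed by
density-dependent mortality from natural enemies — generate pattern even on
a homogeneous template. `nestpp` implements a point-process workflow that
separates the two: summary statistics conditioned on the available habitat,
competing intensity models for each hypothesis, an explicit cluster process
for the budding mechanism, and goodness-of-fit machinery that asks which
model family can actually reproduce the observed clustering.

The data model is an annual census: every tree in a rectangular plot is
mapped (coordinates in metres), and every nest sits on a tree, so nest
patterns are subsets of tree patterns. The default window is a 670 m
square (about 45 ha). A coarse (20 m) elevation raster supplies terrain
covariates.

## Summary statistics and the habitat-conditioned null

Clustering is quantified with the pair correlation function
$g(r)$ — the relative density of point pairs at ring distance $r$, equal
to 1 under complete spatial randomness — and with Ripley's
$K(r)$ and its variance-stabilised transform $L(r) = \sqrt{K(r)/\pi}$.
All estimators use the translation edge correction
$e_{ij} = |A| / ((W-|\Delta x_{ij}|)(H-|\Delta y_{ij}|))$, which is exact
for rectangular windows; the Ripley isotropic correction is deliberately
not implemented. The PCF kernel is Epanechnikov with half-width
$h = 0.26/\sqrt{\bar\lambda}$ (Stoyan's rule) unless overridden, and the
default scale grid is 1–100 m in 1 m steps.

Because nests can only occupy trees, raw clustering statistics confound
nest behaviour with tree arrangement. The null model is therefore *random
allocation*: nests are repeatedly re-assigned to trees by sampling without
replacement, and the observed PCF is compared with pointwise envelopes
formed from the $\lfloor(n+1)\alpha/2\rfloor$-th and
$\lceil(n+1)(1-\alpha/2)\rceil$-th order statistics of the simulated
curves (the 25th and 976th of 1000 at $\alpha = 0.05$). Each scale is
classified `clustered`, `dispersed` or `ns`. These are pointwise, not
global, envelopes: the per-scale type-I error is $\alpha$, and the suite
verifies this calibration empirically.

## Covariates

Six surfaces on the 20 m grid form the two competing covariate sets:

* **endogenous** — `nest`: Gaussian-kernel density (bandwidth 20 m) of the
  *previous* year's nests; `nest2`: its square, allowing hump-shaped
  density dependence.
* **exogenous** — `trees`: kernel density of the current year's trees;
  `elev`, `slope`, `wet`: terrain.

The 20 m bandwidth places 95% of each kernel's weight within 40 m of its
centre (the univariate two-sigma rule), which is why model effects are
reported as counts within a 40 m disc. No edge correction is applied to
the kernel densities, so near-border densities are biased low; tests that
need exact normalisation use interior patterns.

Density variables are divided by their standard deviation pooled over all
cells of all model years (population sd — the grids are exhaustive), but
*not* centred, so they remain non-negative; terrain variables are
normalised to mean 0, sd 1 over the plot. `nest2` is the square of the
*scaled* density; the divisor is recorded in the stack metadata so the
alternative convention is recoverable. Slope is computed as a tangent
(rise/run) by Horn's 3x3 method with one-sided differences on the border;
the wetness index is $\ln(A_c/s)$ with $A_c$ from single-direction D8
flow accumulation (ties broken in the fixed order E, SE, S, SW, W, NW, N,
NE; every cell contributes its own 400 m²) and $s$ floored at $10^{-3}$.
Tangent slope was chosen over degrees or percent because it is the
standard convention inside the wetness ratio.

## Intensity models

Both hypotheses are expressed as log-linear inhomogeneous Poisson process
(IPP) intensities $\lambda(z) = \exp(\beta_0 + \beta^\top X(z))$, fitted
by Berman–Turner quadrature: dummy points on a 10 m grid (four per
covariate cell), counting weights `tile area / points in tile`, and a
weighted Poisson IRLS solve. The quadrature error at these settings is far
below sampling error at a few hundred nests. The homogeneous null is the
intercept-only special case, whose MLE is exactly $n/|A|$ — a property the
tests assert to $10^{-6}$. Models are compared by AIC computed from the
quadrature log-likelihood; only AIC *differences* within a year are
meaningful, and the suite checks the differences on synthetic data rather
than absolute values. Per-coefficient inference uses two-sided normal Wald
tests, matching the usual reporting convention for these models.

## The Thomas cluster layer

Budding is modelled by an inhomogeneous Thomas cluster process (ITCP):
mother points form a Poisson process of intensity $\kappa$, each mother
receives Poisson-many offspring displaced by isotropic Gaussian($\sigma$)
vectors, and the offspring mean varies with the environment so that
$\lambda(z) = \kappa\,\mu(z)$. Fitting is the standard two-step method:
the IPP supplies $\beta$ (and hence $\mu(z)$ up to $\kappa$) unchanged,
then $(\kappa, \sigma)$ minimise the contrast
$\int_0^{r_{max}} (\hat K(r)^q - K_\theta(r)^q)^2\,dr$ between the
intensity-weighted empirical $K$ and the closed form
$K_\theta(r) = \pi r^2 + (1 - e^{-r^2/4\sigma^2})/\kappa$, with
$q = 1/4$ and $r_{max} = 100$ m by default (the analysed scale range).
Optimisation is Nelder–Mead over $(\log\kappa, \log\sigma)$ from twelve
dispersed starts; a brute-force grid search serves as the oracle in the
tests. The search is boxed to $\kappa \le 10\,\bar\lambda$ and
$0.5 \le \sigma \le r_{max}$: beyond those limits the contrast surface is
flat (a Thomas process with more mothers than points, or clusters wider
than the analysed range, is empirically indistinguishable from the
boundary case), and unbounded $\kappa$ or $\sigma$ makes the fitted model
impossible to simulate. Inverse-intensity weights in $\hat K$ are floored
at $\lambda_{min} = 10^{-8}$ m$^{-2}$.

Clustering inflates the uncertainty of $\beta$ without moving the point
estimates. The adjusted covariance is the sandwich
$\Sigma + A^{-1} B A^{-1}$, where $A = \sum_u X X^\top \lambda \Delta$ is
the Fisher information accumulated on the covariate grid and
$B = \sum_{u,v} X(u) X(v)^\top \lambda(u)\lambda(v)
(g(\|u-v\|)-1)\Delta^2$ carries the fitted Thomas pair correlation
($g - 1$ truncated below $10^{-4}$, beyond about $6\sigma$). Using the
fitted model's own covariance for the first term (rather than $A^{-1}$
re-approximated on the grid) makes the construction exactly reduce to the
unadjusted covariance in the Poisson limit and guarantees adjusted
variances are never smaller — both asserted in the tests. The practical
consequence mirrors the field analysis: coefficients significant under
the IPP lose significance once clustering is acknowledged.

## Inference

**Parametric bootstrap.** $(\kappa, \sigma)$ intervals come from
simulating the fitted ITCP (inhomogeneous simulation is exact: a
homogeneous Thomas draw at the intensity maximum, independently thinned by
$\lambda(z)/\lambda_{max}$, with the mother process laid on a window
dilated by $4\sigma$ so that under 0.01% of offspring mass is truncated)
and refitting by minimum contrast with the original IPP intensity held
fixed — the two-step structure of the estimator. Percentile intervals use
the $\lceil(m+1)\alpha/2\rceil$ / $\lfloor(m+1)(1-\alpha/2)\rfloor$ order
statistics (3rd and 97th of 99); refit failures are dropped, counted, and
more than 10% flags the result unreliable.

**Goodness of fit.** The MAD test simulates the fitted model and compares
$T = \max_r |\hat L(r) - \bar L(r)|$ over 0–100 m against the same
statistic for each simulation, using the leave-self-out mean for the
simulated curves and the rank p-value $(1 + \#\{T_i \ge T\})/(n+1)$.
$p < 0.05$ rejects the model at the 95% acceptance level.

**Thresholds.** The endogenous prediction curve $f(x)$ — expected nests
in a 40 m disc given the lagged count $x$, all other covariates at plot
means, with `nest2` co-varying as the square — is scanned on a 0.1-count
grid and crossings with the diagonal $f(x) = x$ are refined by bisection
to $10^{-3}$. With a log-quadratic intensity the curve is necessarily
above the diagonal as $x \to 0$, so the "Allee" structure appears as a
dip: a downward crossing into the dip, then an upward crossing out of it
(reported as the Allee boundary), then — for a controlled population — a
final downward crossing at high density, the break-even control
threshold. A downward crossing below an upward one is classified as the
dip entry, not break-even; if the curve never comes back down the
threshold is reported absent (a growing population predicts increase
everywhere), which is an outcome, not an error. All crossings are
exported. Threshold intervals propagate coefficient uncertainty by
multivariate-normal draws from the (adjusted) covariance — full bootstrap
refitting would multiply cost for little gain at these sample sizes.

## The synthetic generator

No field census is distributed with the package, so a generator produces
data with the statistical structure the analysis assumes. Its defaults
are the study conditions: a 670 m square plot; 4000 trees; nine annual
censuses with thinning from the fourth year at 9.7% per year, which
leaves 60% of the initial trees by the final census (the first reduced
census appears the year after management changes — consistent with
surveys early in the season); nests initialised on 250 random trees;
budding at 0.35 expected daughters per nest per year with 8 m Gaussian
dispersal, daughters snapped to the nearest unoccupied tree within two
dispersal standard deviations (else discarded — budding cannot create
nests off trees); and survival decreasing logistically in the lagged
20 m-kernel nest density. The survival half-point is 40 nests per 40 m
disc with width 8: combined with the budding surplus this puts the
deterministic break-even of the *dynamics* near 30 nests per disc, the
level the fitted models should rediscover. An optional Allee penalty
(35% extra mortality below 2 nests per disc) produces the low-density
dip. These choices are made once, on demographic grounds; they are not
tuned to any test outcome.

The generator reproduces: endogenous clustering (its patterns leave the
random-allocation envelope at small scales), a rising nest population
(roughly +40 to +50 nests per year at the defaults, against a shrinking
tree population), and the model-adequacy asymmetry — an exogenous ITCP
that the MAD test accepts and an endogenous ITCP it rejects, because the
lagged-density covariates already encode the clusters and the Thomas
layer then over-predicts clustering. It does *not* emulate: observation
error in the census, tree recruitment (trees are only removed, never
added), multigenerational cluster structure, anisotropic dispersal, or
any mechanistic natural-enemy submodel. Passing tests therefore validate
the statistical machinery under the assumed data-generating structure,
not the ecology of any particular system.

Exact Thomas draws (`simulate_thomas_homog`, `simulate_thomas_inhom`) are
first-class generator outputs used for parameter-recovery and calibration
testing against the closed forms
$K_\theta$ and $g_\theta(r) = 1 + e^{-r^2/4\sigma^2}/(4\pi\sigma^2\kappa)$.

## Numerical conventions and problem sizes

* One seed per top-level call; internal stages derive deterministic
  sub-streams, so whole-pipeline runs are byte-reproducible.
* Cells are half-open with cell-centre registration; covariates are
  evaluated at quadrature and data points by bilinear interpolation.
* Envelope order statistics use the floor/ceiling convention; bootstrap
  percentile intervals the ceiling/floor convention (3rd/97th of 99).
* IRLS convergence at relative tolerance $10^{-12}$, at most 50
  iterations; non-convergence and singular designs are distinct errors.
* The test suite runs its Monte Carlo studies at deliberately modest
  sizes — 200 seeds for the closed-form oracles, 100 for parameter
  recovery, 30 outer replicates for bootstrap coverage, 500 replicates
  for envelope calibration, 200 for MAD calibration — chosen so the whole
  suite completes in a few minutes while keeping binomial noise within
  the asserted tolerances. The pipeline's production defaults (1000
  envelope simulations, 999 bootstrap and MAD simulations) match the
  published analysis constants.

## Known limitations

* Absolute AIC values depend on the quadrature discretisation; only
  within-year differences are comparable, and only differences are
  asserted anywhere.
* The adjusted covariance accumulates $B$ on the 20 m grid — an
  approximation validated by Monte Carlo, not an exact integral.
* Kernel densities carry negative edge bias; fitted intensities near the
  border inherit it.
* The random-allocation pool is *all* censused trees; no size or species
  filtering of "available" trees is attempted.
* The Thomas layer is two-generation; patterns formed by deeper budding
  genealogies are approximated, not represented.
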