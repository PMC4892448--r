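# nestpp

Spatial point-process analysis that disentangles **endogenous**
(density-dependent, self-organised) from **exogenous** (habitat-driven)
pattern formation in annual censuses of sessile organisms — the motivating
case being arboreal ant nests distributed over the shade trees of a
coffee plantation, where colonies reproduce by short-range nest "budding"
and are repressed by density-dependent natural enemies while the farm's
tree population is thinned over time.

## What it computes

For each census year (with the previous year as the endogenous lag):

1. **Habitat-conditioned clustering test.** The pair correlation function
   g(r) of the nest pattern over 1–100 m, with translation edge
   correction, against pointwise 95% Monte Carlo envelopes from random
   reallocation of nests to the available trees — so detected clustering
   is clustering *beyond* what the tree arrangement imposes.
2. **Competing intensity models.** Log-linear inhomogeneous Poisson
   process (IPP) fits by Berman–Turner quadrature for an endogenous
   covariate set (lagged 20 m-kernel nest density and its square) and an
   exogenous set (tree density, elevation, slope, topographic wetness
   ln(Ac/s)), compared by AIC against a homogeneous null.
3. **Cluster layer.** An inhomogeneous Thomas cluster process over each
   IPP trend, λ(z) = κ·µ(z), fitted by two-step minimum contrast on the
   intensity-weighted K̂ against the closed form
   K(r) = πr² + (1 − exp(−r²/4σ²))/κ; coefficient covariances inflated
   for clustering by a pair-correlation sandwich.
4. **Inference.** Parametric-bootstrap percentile CIs for (κ, σ); a
   maximum-absolute-deviation (MAD) goodness-of-fit test on the
   L statistic over 0–100 m; and the break-even / Allee threshold
   analysis of the endogenous prediction curve (expected nests in a 40 m
   disc versus last year's count, crossings with the diagonal f(x) = x).

A synthetic-data module generates tree censuses with a thinning schedule,
terrain rasters, budding nest dynamics with logistic density-dependent
survival, and exact Thomas-process draws for parameter-recovery and
calibration testing. See the methods vignette
(`vignettes/nest-pattern-analysis.Rmd`) for the model details and every
numerical convention.

## Worked example

```r
library(nestpp)

w      <- plot_window(670, 670)                      # ~45 ha plot
trees  <- gen_tree_series(w, 4000, 2004:2012,
                          thin_start = 2007, thin_frac = 0.097, seed = 5)
census <- simulate_nest_dynamics(trees, dynamics_params(), seed = 6)
dem    <- gen_dem(w, cell = 20, relief = 40, smoothness = 150, seed = 8)

cfg    <- pipeline_config(n_envelope = 99, n_boot = 99, n_mad = 99, seed = 7)
report <- run_pipeline(census, dem, cfg)
print(report)
```

```
pipeline report: 8 model years
  2005: 307 nests / 4000 trees; AIC null 5091 exo 5061 endo 4726; MAD p exo 0.800 endo 0.040
  2006: 398 nests / 4000 trees; AIC null 6392 exo 6344 endo 5927; MAD p exo 0.930 endo 0.060
  2007: 498 nests / 4000 trees; AIC null 7775 exo 7717 endo 7222; MAD p exo 0.830 endo 0.040
  ...
  2012: 749 nests / 2402 trees; AIC null 11081 exo 10912 endo 10276; MAD p exo 0.980 endo 0.030
```

Reading the row for 2007: the endogenous IPP explains far more
information than the exogenous one (AIC 7222 vs 7717 against a null of
7775) — last year's nest density is the dominant predictor — yet the MAD
test *rejects* the endogenous cluster model (p = 0.04) while accepting
the exogenous one (p = 0.83): once the lagged-density covariates encode
the clusters, stacking a Thomas process on top over-predicts clustering,
whereas the exogenous trend needs (and gets) the cluster layer to absorb
it. `write_report(report, "out/")` exports the coefficient, AIC, Thomas
parameter, envelope and threshold tables as CSV plus a JSON digest.

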