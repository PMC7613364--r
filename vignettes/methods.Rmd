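---
title: "Gap-filling vegetation time series with pooled GPR hyperparameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-filling vegetation time series with pooled GPR hyperparameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofill)
```

## The model and its assumptions

Each pixel of an image time series contributes irregular, cloud-interrupted
observations $y_i$ of a vegetation descriptor (LAI in m²/m² throughout this
vignette) at times $t_i$, in days since a configurable epoch. `phenofill`
models them as $y_i = f(t_i) + e_i$ with $e_i \sim \mathcal N(0, \sigma_n^2)$
and a zero-mean Gaussian process prior on $f$ under the squared exponential
kernel

$$k(t_i, t_j) = \sigma_f^2 \exp\!\left(-\frac{(t_i - t_j)^2}{2 l^2}\right).$$

The assumptions this encodes: the seasonal trajectory is smooth (infinitely
differentiable sample paths — appropriate for canopy development, not for
step changes such as harvest captured between two acquisitions); noise is
additive, Gaussian and independent across acquisitions; and the prior mean
is zero, so predictions revert to zero far from data rather than to a
climatological mean. We deliberately do not mean-centre the observations (a
flag exists at the fitting level for users who want to); with length-scales
of a few weeks the prior-reversion regime is only entered in gaps much
longer than any the generator or typical Sentinel-2 collections produce.

The kernel is noise-free; the noise variance enters the training covariance
$C = K + \sigma_n^2 I$ exactly once. (Formulations that also embed a
$\sigma_n^2\delta_{ij}$ term inside the kernel would double-add it when the
predictive equations add $\sigma_n^2 I$ again; the single addition is the
standard resolution and the one consistent with the predictive and
marginal-likelihood expressions used here.) The predictive variance reported
for a new time includes the noise term, $c_* = k(t_*,t_*) + \sigma_n^2$ —
it is the variance of a new *observation*, which is the quantity usually
mapped as reconstruction uncertainty. Whether to report latent-only variance
was an open choice; the observation variance was kept because the $c_*$
definition above is the one the predictive equations state.

## Training

The hyperparameter triple is optimised on the log scale,
$(\log(1/l), \log\sigma_f, \log\sigma_n)$, which enforces positivity and is
also the scale on which hyperparameter tables for crops are conventionally
reported. `train_hyperparameters()` runs L-BFGS-B with the analytic gradient
(the trace identity $\tfrac12\,\mathrm{tr}((\alpha\alpha^\top - C^{-1})\,
\partial C/\partial\theta_j)$, chain-ruled into the log parameterisation)
from `n_restarts = 5` initial values drawn uniformly from the prior box

| parameter | range | rationale |
|---|---|---|
| $\log(1/l)$ | $[-6, -1]$ | $l$ from ~3 days to ~400 days |
| $\log\sigma_f$ | $[-2.5, 1]$ | signal sd from 0.08 to 2.7 LAI |
| $\log\sigma_n$ | $[-3.5, 0]$ | noise sd from 0.03 to 1 LAI |

which brackets published crop values by a wide margin, plus one
deterministic moment-based start ($l = \mathrm{span}/20$,
$\sigma_f = \mathrm{sd}(y)$, $\sigma_n = 0.3\,\mathrm{sd}(y)$). The
moment start matters in practice: on a few percent of pixels every random
start drifts into the "all noise" optimum ($\sigma_f \to 0$,
$\sigma_n \approx \mathrm{sd}(y)$), which has a dramatically lower marginal
likelihood than the seasonal fit but is locally stable; a start near the
data scale reliably escapes it. The best converged likelihood wins.
Convergence uses a relative objective tolerance of about $10^{-6}$
(`factr = 1e7`), a projected-gradient tolerance of $10^{-5}$ and at most 200
iterations per start; everything is deterministic given the seed.

Numerical choices: all solves go through a Cholesky factorisation of $C$,
shared by prediction, likelihood and gradient — never an explicit inverse
for the data path (the gradient's trace term uses `chol2inv` of the same
factor). If factorisation fails the diagonal receives escalating jitter from
$10^{-10}$ to $10^{-4}$ of the mean diagonal (recorded in the fit); during
optimisation a failed factorisation becomes a large finite penalty so the
line search can back off. Negative predictive variances from rounding are
clipped at zero with the clip magnitude recorded. Pixels with fewer than
`min_obs = 4` valid acquisitions are flagged, never fitted.

## Pooling

`sample_parcels()` draws up to 100 parcels of at least 50 pixels per crop
class (without replacement, seeded), using the parcel-id raster when one is
provided and 4-connected components of same-class pixels otherwise — an
external parcel map cannot be assumed. `train_per_pixel()` optimises each
sampled pixel independently; failures are recorded and excluded, never
imputed. `average_hyperparameters()` then takes the unweighted arithmetic
mean of the log triples within each class (θ per crop) and over all trained
pixels (θ global). Averaging in log space was a design choice the linear
scale could equally have claimed; the log mean is scale-invariant and
matches the convention in which such tables are reported. The global entry
is pixel-weighted — every trained pixel counts once — so with unbalanced
classes it is *not* the mean of the crop columns; the shipped preset table
(`theta_presets()`) exhibits exactly this distinction (crop-column mean
−3.6426 vs global −3.6430 in $\log(1/l)$).

## Reconstruction and the cost model

`reconstruct_stack()` fits every pixel with the resolved hyperparameters
(fixed single θ, global average, per-crop with global fallback for unmapped
classes, or the conventional per-pixel optimisation) and predicts on a
common grid — by default a regular 10-day step over the observed span, a
standard reconstruction step for decametric products; per-acquisition grids
are one argument away. Predictions are allowed anywhere, but points outside
the observed span simply revert toward the prior.

With fixed hyperparameters the estimator is embarrassingly regular: pixels
sharing both a θ and a valid-acquisition pattern share one Cholesky
factorisation, and the per-pixel work reduces to triangular solves. The
shared path is *numerically identical* to the naive per-pixel loop (asserted
to $10^{-10}$ in the tests) — it changes cost, never the estimate.
`count_training_ops()` exposes the cost model: per-pixel mode pays one
optimisation (tens of likelihood evaluations, each one factorisation) per
pixel; fixed-θ modes pay zero optimisations and one factorisation per
distinct (θ, cloud-pattern) pair. That ratio — optimiser iterations times
restarts to a handful of solves — is what makes precalculated
hyperparameters roughly two orders of magnitude faster at scene scale,
independent of hardware.

## Phenology

`detect_seasons()` finds local maxima whose topographic prominence is at
least 10% of the series range (default), flanks each with the deepest
minimum towards the neighbouring peak (series endpoints act as minima), and
takes the season base level as the mean of the two flanking minima — a
per-season base, consistent with defining amplitude as maximum minus the
mean of the flanking minima. Seasons narrower than 30 days at 20% of their
own amplitude are discarded as blips. Both defaults are package choices; no
reference values exist for them.

`season_metrics()` places SOS where the rising limb crosses
$\mathrm{base} + 0.2\,\mathrm{amplitude}$ — the *last* upward crossing
before the peak, linearly interpolated between grid points — and EOS at the
*first* downward crossing after it; taking the crossings adjacent to the
peak is the conservative reading when noisy flanks cross the level several
times. DOM is the grid argmax (no sub-grid refinement), LOS = EOS − SOS.
For the seasonal integrals two conventions circulate without a standard
definition; this package fixes: **green area** = trapezoidal integral of the
curve *above the base level* between SOS and EOS, **blue area** = integral
of the curve itself (above zero) over the same window — the TIMESAT-style
small/large integral pair. The two differ by base × LOS exactly, which the
tests pin with a lifted-triangle fixture. A season is assigned to the
calendar year containing its DOM.

On a daily grid the crossings of clean double-logistic curves are recovered
within 1 day; on the default 10-day reconstruction grid the linear
interpolation keeps SOS/EOS errors well below the grid step.

## The synthetic scene generator

`generate_scene()` emulates the setting the method targets: a parcel mosaic
(square parcels, classes in shuffled round-robin) of nine crop classes with
distinct double-logistic seasonal curves — winter cereals and rape greening
up early, summer crops peaking mid-year, a long-season alfalfa — with LAI
bases of 0.2–0.5 and amplitudes of 2–4.8 m²/m²; a 5-day revisit with ±1 day
jitter over two years (~146 acquisitions, the same order as multi-year
Sentinel-2 collections); additive Gaussian noise of 0.1 LAI; small per-pixel
perturbations (3 days on season dates, 5% on amplitude) so parcels are not
exact replicas; and cloud gaps as spatially correlated random discs whose
intensity is calibrated to an expected 25% masked area per acquisition —
correlated gaps, not i.i.d. pixels, so the distinct-valid-pattern logic of
the fast path is actually exercised. The curve centres are placed so the
20%-amplitude crossings equal the declared SOS/EOS in closed form, giving
every pixel an analytic phenology truth. `generate_gp_series()` draws
exactly from the zero-mean GP the training code assumes, for hyperparameter
recovery checks.

What the generator does *not* emulate: retrieval-induced correlated errors,
outliers and undetected cloud contamination, within-parcel spatial
correlation of noise, double-cropping and mowing cycles, or reflectance
physics. Passing tests on this scene therefore demonstrate the estimator's
internal consistency and the harmlessness of hyperparameter pooling under
the stated noise model — not robustness to retrieval artefacts in real
imagery.

## Problem sizes used in the checks

The test suite and the acceptance script run: oracle comparisons on 100
random problems of up to 50 observations; gradient checks on 100 draws of up
to 20; hyperparameter recovery as the median over 20 replicates of
300-observation GP series at crop-scale hyperparameters
$(\log(1/l), \log\sigma_f, \log\sigma_n) = (-3.6, -0.5, -1.7)$; fast-path
equivalence on a cloudy 20 × 20 scene; and the pooled-vs-per-pixel
comparison on the default 60 × 60 scene with 20 trained pixels per class
(180 per-pixel optimisations) — parcel-level sampling rather than exhaustive
per-pixel training is also how the method is meant to be deployed. On that
scene the global-average reconstruction stays within ~2% variation of the
per-pixel reference with per-class mean correlations above 0.99, and season
dates agree to ~1 day MAD.

## Known limitations

* Exact GPR is $O(n^3)$ in the number of valid acquisitions per
  factorisation; collections much longer than a few hundred acquisitions per
  pixel would need sparse approximations, which are out of scope.
* Only the squared exponential kernel is provided; Matérn-family kernels
  (rougher sample paths) are not implemented.
* The zero-mean prior pulls long-gap predictions toward zero LAI rather than
  toward a seasonal climatology; reconstructions inside gaps longer than a
  few length-scales should be read together with their uncertainty band.
* Season matching between two parameterisations pairs records by pixel,
  calendar year and nearest DOM (within 90 days); crops with two true
  seasons per calendar year would need a finer slot definition.
* The file interface stores cubes as scaled 32-bit-float TIFF planes with a
  JSON sidecar; georeferencing metadata is carried through opaquely, not
  interpreted.
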