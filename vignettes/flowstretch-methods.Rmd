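---
title: "Models and methods behind flowstretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flowstretch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowstretch)
```

## The experiment being modeled

In a flow-stretching primer-extension assay, a ~7.2 kb primed single-stranded
M13 DNA is tethered between a glass surface and a 2.8 um bead, and laminar
flow applies a constant ~3 pN force. Conversion of entropically coiled ssDNA
to extended dsDNA by a polymerase lengthens the tether, so the bead moves,
and dark-field imaging of the bead at 0.5 s exposures reads out cumulative
synthesis. Two polymerases with very different single-molecule rates act on
the same primer terminus through the beta sliding clamp: the fast replicative
Pol III core and the slow Y-family TLS polymerase Pol IV. Traces therefore
show alternating processive synthesis events, attributable to one polymerase
or the other by rate, separated by pauses. The measurement noise is dominated
by thermal fluctuations of the tethered bead, about 70 bp SD per 0.5 s frame
in synthesis units.

The package provides (i) a generative model of this experiment with full
ground truth, (ii) the image-level layer (bead rendering and sub-pixel 2D
Gaussian localization) for validating tracking, (iii) trace segmentation into
events and pauses with rate-based polymerase classification and processivity
statistics, and (iv) the pre-steady-state kinetic analysis used for bulk
nucleotide-incorporation measurements (burst fits, hyperbolic
kobs--[dNTP] fits, catalytic efficiencies).

## Generative model

Each molecule alternates **pauses** and **events**:

* Pause durations are exponential with total rate equal to the sum of
  per-species binding rates (`pause_exit_rates`); the binding species is
  chosen with probability proportional to its rate. Binding rates are
  proportional to polymerase concentration; the proportionality constants
  are not published quantities, so drivers set the rates directly.
* An event by species $s$ draws a per-event rate from a log-normal
  distribution (median `pol{s}_rate_median`, geometric SD `pol{s}_rate_gsd`)
  and a nucleotide extent from an exponential distribution with per-nt
  termination hazard `pol{s}_term_hazard`, truncated at the template end and
  at the end of the observation. The mean extent is 1/hazard.
* An optional `displacement_hazard` adds a competing per-nt termination risk
  to active Pol III events only, modeling disruption of ongoing Pol III
  synthesis by the Pol IV catalytic domain; 0 models the displacement-dead
  T120P variant. Competing exponential hazards add, so a displacement hazard
  equal to the intrinsic hazard exactly halves the mean Pol III extent.
* Observed positions are true cumulative synthesis sampled on the frame grid
  plus i.i.d. Gaussian noise (`noise_sd`, default 70 bp).

Defaults (template 7,249 nt; 0.5 s frames; 70 bp noise; 3 pN) are the stated
experimental conditions. The per-event rate distributions and hazards are
**not** published for this assay; the defaults -- Pol III median 150 bp/s,
Pol IV median 10 bp/s, both with geometric SD 1.4; termination hazards
1/1200 and 1/350 per nt; pause exit 0.05 /s; 100 s observations -- are
placeholder values chosen once to be realistic for these enzymes and well
separated around the 45 bp/s classification cutoff. Simulations are fully
reproducible: a master seed derives per-condition seeds by a fixed counter
scheme, and identical seed + config gives bit-identical output.

What the generator deliberately does **not** emulate: correlated (OU) bead
noise -- only a white-noise SD is quoted for the real assay; stage drift;
force or calibration fluctuations; sequence-dependent rates;
mid-event polymerase exchange (the analysis model assigns one polymerase per
processive event); lesions on the single-molecule template (the real assay
used undamaged DNA). Passing tests on synthetic data therefore validate the
*estimators* under the stated noise model, not the microscopy itself.

## From bead displacement to bases

At constant force the extension gain per nucleotide synthesized is the
difference between dsDNA extension per bp and ssDNA extension per nt:

* dsDNA: worm-like chain with the Marko--Siggia interpolation
  $F = (k_BT/P)\,[1/(4(1-z)^2) - 1/4 + z]$, solved for the fractional
  extension $z$ by bracketed root finding to a force residual below
  $10^{-9}$ pN (persistence length 50 nm, 0.34 nm/bp contour).
* ssDNA: freely-jointed chain,
  $x = L_{ss}\,[\coth(Fb/k_BT) - k_BT/(Fb)]$ with Kuhn length
  $b = 1.5$ nm and 0.56 nm/nt contour.

At 3 pN and 298 K this gives ~0.122 nm per nt (positive: dsDNA is longer
below the ~6 pN crossover). These polymer constants are standard literature
values, not measurements from this assay, so every entry point equally
accepts a user-supplied scalar `calibration()`; all quantitative analysis is
done in bp space where the assay's own numbers (70 bp noise, 45 bp/s cutoff)
live.

## Bead rendering and localization

Synthetic stacks render the bead as a symmetric 2D Gaussian integrated over
pixels, plus constant background and Poisson shot noise, with true sub-pixel
centers recorded. Localization fits the same five-parameter model
(background, amplitude, x, y, width) by Levenberg--Marquardt least squares
from a centroid initialization; tracking re-centers the region of interest
on the previous fit, bridges up to 2 failed frames linearly, splits the
trace on longer gaps, and rejects stacks with more than 50% failures. The
flow axis is the image x axis by convention. Pixel size, PSF width and ROI
half-width (7 px) are unpublished for the real instrument, so tracking is
validated purely on rendered fixtures: localization is unbiased to < 0.01 px
at high SNR and its error decreases monotonically with photon budget.

## Trace segmentation

Segmentation fits a piecewise-linear model by penalized least squares:
changepoints minimize

$$\mathrm{SSE} + \beta\,(\#\text{changepoints}), \qquad
  \beta = \lambda\,\hat\sigma^2 \log n,$$

with each segment an independent OLS line of at least 2 frames. The search
is an exact $O(n^2)$ dynamic program over all placements (near-ties are
resolved toward fewer segments), so the implementation can be checked
verbatim against an exhaustive enumeration oracle on short traces -- one of
the package's property tests.

Numerical choices:

* **Noise scale** $\hat\sigma$: MAD of second differences divided by
  $\sqrt 6$. Second differencing is exactly trend-free on piecewise-linear
  signal, so the estimate is not inflated during fast synthesis the way a
  first-difference estimator is; the first-difference form
  (MAD/$\sqrt 2$) is available as an option.
* **Penalty** $\lambda = 3$: one extra segment costs slope, intercept and
  breakpoint location, i.e. three BIC terms. In simulation benchmarks at
  default conditions this value maximized event-classification accuracy;
  smaller penalties admit noise-slope fragments and larger ones leave short
  events merged with flanking pauses.
* **Labels**: segments with $|\text{slope}| \le 2$ bp/s are pauses, the rest
  events. Events smaller than 210 bp (3 x the 70 bp noise SD) or shorter
  than 3 frames are merged into neighboring pauses; adjacent same-label
  segments are merged; the merge loop runs to a fixpoint and is idempotent.
  Retrograde segments (negative slope) are kept as flagged slow-class
  segments, not synthesis.
* **Classification**: event rate $\ge$ 45 bp/s is Pol III, below is Pol IV;
  the boundary value is assigned to the fast class. On single-polymerase
  simulations at default conditions this cutoff places ~95--99% of detected
  events on the correct side; the residual errors are event+pause mixture
  segments below the time resolution, the same limitation the real assay's
  "~95% capture" reflects.
* An optional recursive local refinement of the changepoint search
  (`local_refine`) exists but is off by default: in benchmarks it resolved
  some short events at the cost of slow edge fragments and a net accuracy
  loss.

## Processivity statistics

Per-condition summaries report the raw mean +/- SEM of event extents (the
figure-style quantity) and a truncation-corrected estimate. Detection of
events is *soft* near the noise floor: short events do not justify
changepoints, so the effective detection limit is well above the 210 bp
demotion rule. Because exponential extents are memoryless, restricting to
events of at least $c$ bases and subtracting $c$ from their mean is unbiased
for the underlying mean processivity for any $c$ at which detection is
complete; measured detection completeness saturates above ~700 bp at default
conditions, and the package uses $c = 600$ bp for processivity estimation.
Events touching the first or last frame of a trace are censored by the
observation window and excluded from summaries by default. Remaining biases
-- merging of events across sub-frame pauses, template exhaustion -- inflate
both conditions of a ratio similarly and largely cancel; with a displacement
hazard equal to the intrinsic hazard the estimated Pol III processivity
ratio is 0.5 within bootstrap error (a package acceptance test).

Condition comparisons use the two-sided Wilcoxon/Mann--Whitney rank-sum
test: exact by full enumeration of the permutation null (on midranks)
whenever $n_a + n_b \le 20$, otherwise a normal approximation with
tie-corrected variance and continuity correction; two-sided p is twice the
smaller tail, capped at 1. Ratios of mean processivities carry a seeded
percentile bootstrap CI (default 2,000 resamples).

## Kinetic analysis

Gel band quantitation converts extended/(extended+unextended) signal ratios,
zero-point corrected and scaled by the primer/template concentration, into
product (floored at 0). Single-turnover time courses follow the burst
equation

$$y(t) = A\,(1 - e^{-k_{obs} t}) + C,$$

fit by bounded Levenberg--Marquardt least squares (unweighted by default;
this equation is sometimes printed without the negative sign, which would
diverge -- the standard decaying form is implemented).
Initialization uses the data range for $A$, the earliest point for $C$ and a
log-linearization for $k_{obs}$; non-convergence and rate constants
collapsed onto the 0 boundary are flagged but still returned. The
concentration dependence $k_{obs} = k_{pol}[\mathrm{dNTP}]/(K_d +
[\mathrm{dNTP}])$ is fit the same way, with standard errors from the fit
covariance and a "poorly constrained" flag when $K_d$ exceeds 10 x the
largest sampled concentration (the regime reported in tables only as a
lower bound). Noiseless round trips recover generating parameters to
$10^{-6}$ relative, and noisy fits are cross-checked against zooming
grid-search oracles in the tests.

Catalytic efficiency is $k_{pol}/K_d$ in $\mathrm{M^{-1}s^{-1}}$, reported
at 3 significant figures at or above 1,000 and 2 below, matching the usual
table precision. The bundled table of published constants for wild-type
Pol IV and Pol IV-T120P is checked by recomputing each efficiency and
comparing at the printed precision, tolerating one unit in the last printed
digit (one row differs by that one unit from exact rounding); exactly one
row -- T120P with dTTP opposite undamaged dA -- is internally inconsistent
by ~5-fold and is flagged rather than silently corrected. Efficiencies
below 10% of the correct-pair efficiency are labeled misincorporation.

## Problem sizes and reproducibility

The test suite and the analysis drivers use 40--200 frame traces and
60--300 molecules per condition, sizes at which every stochastic check has
3-sigma headroom against its tolerance; the classification and noise
self-consistency checks use 200 molecules per condition, and the
processivity-recovery check uses 300 molecules under sparse-event
conditions (pause exit 0.01 /s) where the assay time resolution can
actually separate events. All randomness flows from explicit seeds, and the
simulate-segment pipeline is bit-reproducible end to end.
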