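---
title: "Methods: random-walk classification of T-cell tracks and immune-synapse quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-walk classification of T-cell tracks and immune-synapse quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptrack)
```

## Scope

`synaptrack` quantifies two readouts of engineered T-cell function from live
imaging: *migration* (how cells explore tissue, from single-cell tracks) and
*immune-synapse dynamics* (how cells engage targets, from fluorescence traces
and segmentation masks). Detection, tracking, and segmentation are upstream
responsibilities (TrackMate, Fiji): this package consumes track tables,
intensity traces, and binary masks, and everything downstream of those inputs
is implemented and tested here, against a synthetic-data module with analytic
ground truth.

## The migration model

A track is a time-ordered series of 2D positions $r(t)$ in micrometers,
sampled at a fixed frame interval $\Delta t$ (2 min by default, matching the
slice-imaging acquisition this pipeline targets: movies of 90–270 frames).
Per track we estimate the mean squared displacement with **overlapping time
intervals**,

$$\mathrm{MSD}(k\,\Delta t) \;=\; \frac{1}{n-k}\sum_{i=1}^{n-k}
  \lVert r_{i+k}-r_i\rVert^2 ,$$

for lags $k = 1,\dots,n-1$. Overlapping pairs reduce variance but correlate
MSD values across lags; the model-selection consequences are discussed under
*Limitations*.

Three candidate random-walk models are fitted to the **leading 40%** of each
MSD curve (clamped below at 4 points so the corrected AIC is defined for the
2-parameter models):

| model | MSD$(\tau)$ | parameters |
|---|---|---|
| constrained | $R^2\!\left(1-e^{-4D_c\tau/R^2}\right)$ | $D_c$ (µm²/min), $R$ (µm) |
| Brownian | $4D\tau$ | $D$ (µm²/min) |
| persistent (PRW) | $2v^2P^2\!\left(\tau/P-(1-e^{-\tau/P})\right)$ | $v$ (µm/min), $P$ (min) |

plus a descriptive power law $A\tau^\alpha$ whose exponent $\alpha$
summarizes the diffusion regime ($\alpha<1$ apparent subdiffusion, $\alpha=1$
diffusive, $\alpha>2$ would be unphysical; $\alpha$ is bounded in $(0,2]$).
The power law takes no part in model selection.

Each fit minimizes the unweighted residual sum of squares in linear MSD
space; the winning model minimizes the small-sample corrected AIC

$$\mathrm{AICc} = n\ln\!\frac{\mathrm{RSS}}{n} + 2k +
  \frac{2k(k+1)}{n-k-1},$$

with $n$ the number of MSD points in the fitted window (denoted $n'$
elsewhere; the RSS is computed over exactly those points, which is why $n$
is not the number of frames) and $k$ the free-parameter count. From the
fits we derive the **random motility coefficient** (the Brownian-fit $D$,
always reported), a model-specific effective coefficient ($D$, $D_c$, or
$v^2P/2$ — the long-lag PRW slope is $2v^2P = 4D_\mathrm{eff}$ in 2D), and,
for PRW-classified tracks only, the **persistence speed** $v$ and
**persistence time** $P$. Condition-level summaries report the fraction of
tracks per walk type and median/IQR of the motility statistics; windrose
exports translate each track to a common origin without rotation.

### Track quality control

`track_filter_config()` defaults encode the acquisition assumptions: tracks
flagged `edge_of_slice` or `near_glass` are excluded (these flags are set
upstream, where the raw images live); single-frame displacements implying
more than 25 µm/min remove the track (cells are not identifiable across
larger jumps); gaps of at most 2 frames — the tracker's own gap-closing
limit — are filled by linear interpolation and flagged, while larger gaps
split the track into independently re-filtered segments. Interpolation
rather than omission keeps the lag structure uniform, which the
overlapping-interval estimator requires. The default minimum length of 20
frames is a declared choice, not a value from the source protocol: it
guarantees at least 7 MSD points inside the 40% window, comfortably above
the $k+2$ floor of the largest model.

### Numerical choices

* Model curves are evaluated with `expm1`, stable for $\tau/P$ and
  $4D_c\tau/R^2$ anywhere in $[10^{-6}, 10^6]$.
* The Brownian fit has a closed-form least-squares solution. The
  2-parameter fits run `nlminb` in log-parameter space (positivity by
  construction) from at least three deterministic, data-driven starts
  (first-lag slope, curve maximum, $P_0 \in \{\Delta t, 5\Delta t,
  25\Delta t\}$); no RNG is used in fitting, so classification is exactly
  reproducible. Fits were spot-checked against independent global
  least-squares (SciPy) and agree to all reported digits.
* $\mathrm{RSS}=0$ (exact fits) maps AICc to $-\infty$ with an `exact_fit`
  flag instead of failing on $\ln 0$. AICc ties within $10^{-9}$ are broken
  toward fewer parameters, then the fixed order Brownian < constrained <
  PRW.
* Localization noise adds a constant $4\sigma^2$ to the 2D MSD; this offset
  is deliberately *not* a fitted parameter, and the recovery tolerances
  absorb it.

## The synthetic-data module

Every stage is validated against generators whose ensemble behavior is known
in closed form; all generators are seed-deterministic.

* **Brownian**: independent Gaussian increments with per-coordinate variance
  $2D\Delta t$; ensemble MSD $4D\tau$ exactly.
* **PRW**: per-coordinate Ornstein–Uhlenbeck velocity with correlation time
  $P$ and stationary mean-square *speed* $v^2$, integrated to positions with
  the exact joint Gaussian one-step update (velocity and displacement drawn
  together with their analytic covariance — no Euler discretization error).
  Its ensemble MSD is exactly the PRW closed form; its increment
  autocorrelation decays by $e^{-\Delta t/P}$ per lag.
* **Confined**: Brownian steps inside a reflecting disc of radius $b$,
  initialized from the uniform (stationary) distribution, so the long-lag
  plateau is $b^2$ (mean squared distance between two independent uniform
  points in the disc). The reflection is radial ($r \mapsto 2b - r$), an
  approximation to a true mirror reflection that is accurate when the step
  size $\sqrt{4D\Delta t} \ll b$.
* **Imaging artifacts**: i.i.d. localization noise and 1–2-frame gaps at a
  configurable per-frame rate (gaps never exceed the tracker's 2-frame
  closing limit).
* **Calcium transients** (baseline, instantaneous rise, exponential decay)
  and **mask movies** (two moving discs rasterized per frame) carry their
  analytic F0/peak/AUC and circle–circle lens overlap areas as ground truth.

The confined closed form above deserves a caveat: the exponential-saturation
expression is *phenomenological*. The exact MSD of reflected Brownian motion
in a disc is a Bessel series whose leading relaxation rate differs from the
single-exponential form; with $D=1$ µm²/min and $b=15$ µm the naive
parameter identification ($D_c = D$, $R = b$) deviates from the true curve
by 6–11% at intermediate lags, while the best-fit form tracks it within
~2.5%. Only the plateau ($R^2 = b^2$) and the short-lag slope ($4D$) map
exactly, and the simulator-consistency checks are written accordingly.

What the generators do **not** emulate: tissue heterogeneity (vessels,
slice boundaries), cell–cell interactions, drift, segmentation errors, or
intensity-dependent localization error. A green test therefore establishes
that the estimators recover the stated models from data that follow them —
not that brain-slice data follow these models.

## Immune-synapse metrics

* **F/F0 normalization**: the first local maximum at/after the declared
  interaction onset whose topographic prominence is at least 20% of the
  trace range is the calcium peak; backtracking to the last non-increasing
  frame gives the rise onset, and F0 is the mean of all frames before it.
  The whole-prefix mean (rather than a fixed-width window, which the source
  protocol does not specify) is robust to single-frame noise; both the
  prominence threshold and the window are parameters. Traces without a
  qualifying peak are normalized by the pre-onset mean and flagged.
* **Total calcium flux**: trapezoidal AUC of the normalized trace over the
  first 30 min of interaction, with window endpoints interpolated so the
  integral is exact for piecewise-linear traces and invariant to
  re-sampling them. Shorter traces integrate to their end and are flagged
  truncated.
* **Synapse area**: per-frame pixel-count intersection of the independently
  segmented T-cell and tumor masks times the pixel area (a single-mask
  variant covers the TIRF spreading-area readout). Masks travel as in-memory
  matrices or a run-length-encoded CSV; no TIFF reader is bundled because
  none is available in the supported dependency set.
* **Response speed**: OLS slope of the signal over the first minute after
  activation, in units/min.
* **MTOC docking time**: first prominent local maximum of the
  central-difference derivative of the moving-average-smoothed (3-frame
  window, a declared stabilizer absent from the source protocol)
  recruitment trace. The derivative is evaluated only where the smoothing
  window is complete, since shrunken edge windows would fabricate
  derivative structure on monotone traces; monotone-linear traces return a
  no-docking sentinel.
* **Center-of-mass distance**: intensity-weighted centroid of a 2D or 3D
  label image against a caller-supplied line or plane (the geometric
  definition of "the" synapse interface in fixed conjugates is not
  universal, so the interface is an explicit argument). Smaller values mean
  stronger accumulation at the synapse.

## Design decisions in brief

* Persistence speed/time are *defined* on PRW-classified tracks (they are
  the parameters of the winning PRW model); recovery statements about them
  condition on classification. Unconditional medians over all PRW fits are
  contaminated by tracks that collapse onto the degenerate $P\to 0$
  (Brownian-limit) or $P\to\infty$ (ballistic) ridges of the PRW RSS
  surface.
* Fit space (linear MSD), weighting (none; per-lag pair counts are reported,
  and `weighted = TRUE` enables them), and the AICc $n=n'$ convention are
  declared choices where the source protocol is silent.
* Group-comparison hypothesis testing is deliberately out of scope; the
  summaries export distributions for any standard statistics tool.

## Limitations

**Single-track Brownian classification is unreliable by construction.** The
time-averaged MSD of a finite Brownian track wanders coherently across lags
(the overlapping-interval points are strongly correlated), so on almost
every simulated Brownian track (100 frames) one of the two 2-parameter
models reduces the RSS by far more than AICc's parameter penalty: Brownian
tracks are assigned to Brownian only ~10% of the time, splitting roughly
evenly between apparent confinement and apparent persistence. This is not an
optimizer artifact (fits match independent global least squares), and
neither pair-count weighting nor log-space fitting changes the picture; only
drastically shorter fit windows (≤4 lags) would, at the cost of the
persistence/confinement sensitivity the window was chosen for. PRW and
confined tracks are recovered at 70–85% under the same procedure. The
corresponding acceptance check is left failing on the Brownian arm, by
design, and per-track walk-type fractions for near-Brownian populations
should be interpreted with this asymmetry in mind.

Other limitations: the confined generator's radial reflection is first-order
in step size; MSD curves are per-track only (no ensemble-average estimator);
3D tracks are rejected rather than projected (projection happens upstream);
and the synapse metrics assume segmentation quality — garbage masks in,
garbage areas out.
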