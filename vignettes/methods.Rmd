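---
title: "Measuring retinal venous pulse wave velocity from photoplethysmographic video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal venous pulse wave velocity from photoplethysmographic video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retpwv)
```

## The measurement problem

Retinal veins within the optic disc pulsate with the cardiac cycle. In
green-channel video of the optic disc, the intensity at a vessel pixel
fluctuates as the blood column under it thickens and thins, so the *timing*
(phase) of the pulsation at each point along the vein encodes how the pulse
wave travels. If the first-harmonic phase $\psi(x)$ decreases with distance
$x$ along the vessel at rate $d\psi/dx$ (radians/mm), the wave moves toward
increasing $x$ and its signed velocity is

$$\mathrm{PWV} = \frac{2\pi}{T\,d\psi/dx} \quad \text{(mm/s)},$$

with $T$ the cardiac period. The distance–phase profiles of disc veins show
a characteristic V shape: an initial linear down trend (a wave running
*retrograde* to venous flow, i.e. from the disc center outward, negative
PWV) followed by a linear up trend (an *anterograde* wave running with the
flow, positive PWV). The vertex — the first local minimum after the first
local maximum of the normalized profile — is the **turning point**,
interpreted as the meeting point of two opposing pulse waves. Near it the
pulse amplitude forms a hump whose width is a natural per-video spatial
unit.

This package implements that measurement end to end: video preprocessing,
per-pixel harmonic regression, phase-gradient PWV estimation on both sides
of the turning point, hump-width fitting, the distance metrics D1–D5,
study-level summaries, and a synthetic generator that makes every stage
verifiable against known ground truth.

## Signal model

Each centerline pixel's blood-column series $s(t)$ over three cardiac
cycles is modeled as

$$s(t) = m + \underbrace{a_1\sin\omega t + b_1\cos\omega t +
a_2\sin 2\omega t + b_2\cos 2\omega t}_{\text{periodic}} +
\underbrace{g(t)}_{\text{broken stick}} + \varepsilon_t,$$

with $\omega = 2\pi/T$. The blood-column value is the Beer–Lambert
transform of normalized pixel intensity, $s = -68\,\ln I$, $I \in (0,1]$
(intensity divided by the bit-depth maximum, which keeps $s \ge 0$ and
makes the absorption-factor scale reproducible). The pieces are:

* **Periodic component** — a second-order Fourier series at the cardiac
  frequency. The pulsation amplitude is its peak-to-trough over one cycle;
  the first-harmonic phase $\psi_1 = \operatorname{atan2}(b_1, a_1)$
  carries the wave timing. Under this phase-lead convention
  ($a\sin\omega t + b\cos\omega t = R\sin(\omega t + \psi)$), a wave
  travelling toward increasing distance produces a decreasing $\psi$, so
  the down trend maps to a negative PWV with no sign patching. The
  generator and the estimator share this convention; a direction-semantics
  test pins it.
* **Broken stick** — a continuous piecewise-linear trend with knots at the
  cycle boundaries $t = T, 2T$, absorbing slow lighting drift. We take the
  conventional reading of a "broken stick" as continuous at the knots; the
  hinge basis $(t, (t-T)_+, (t-2T)_+)$ makes the per-cycle slopes the
  cumulative sums of its coefficients.
* **Errors** — first-order autoregressive, capturing frame-to-frame
  temporal correlation.

### Fitting

`fit_pixel()` uses feasible generalized least squares: whitened
(Prais–Winsten) OLS alternating with re-estimation of the AR(1)
coefficient from the lag-1 autocorrelation of the raw-scale residuals,
until the coefficient moves less than $10^{-4}$ (at most 50 iterations).
Standard errors come from the whitened normal equations with variance
$\mathrm{RSS}/(n - p)$. A numerically exact fit (zero residuals) carries no
information about the error process; $\rho$ is then reported as 0 and the
fit flagged converged.

One numerical choice deserves emphasis. With $p = 8$ design columns in
$n = 75$ frames, the naive residual lag-1 statistic is substantially biased
toward zero — the fitted trend and harmonics absorb part of the noise
autocorrelation — which narrows the standard errors and, downstream, the
phase confidence intervals. `fit_pixel()` therefore applies a
moment-matching correction by default (`rho_correction = TRUE`): the exact
expectation of the statistic under the design,
$g(\rho) = \mathrm{offdiag}(M\Sigma_\rho M)/\mathrm{tr}(M\Sigma_\rho M)$
with $M$ the design's annihilator, is inverted on a grid. The correction
centers the estimator and restores phase-CI coverage into its nominal
range; the test suite measures both. The raw estimator remains available.

### Phase confidence intervals

`phase_ci()` draws `n_mc = 1000` independent normal samples of
$(a_1, b_1)$ from their estimates and standard errors, computes
$\psi^* = \operatorname{atan2}(b_1^*, a_1^*)$, re-centers each draw to the
$2\pi$ branch nearest $\hat\psi_1$ (so an estimate near $\pm\pi$ cannot
produce a wrapped, artificially wide interval), and reports 2.5/97.5
percentile bounds. Sampling ignores the coefficient covariance by default;
`use_covariance = TRUE` enables joint sampling for sensitivity analysis.
A zero-amplitude fit has undefined phase and is flagged degenerate rather
than raised.

### Pulsation amplitude

The periodic component is evaluated on a 1000-point grid over one cycle
and the grid extrema are refined by local univariate optimization, so the
reported peak-to-trough is exact to optimizer tolerance rather than grid
resolution. This matters for the noiseless self-checks, where grid
quantization would otherwise leak a systematic $\sim 10^{-5}$ relative
error into every amplitude and through it into the hump-width fit.

## Wave geometry

`analyze_profile()` works on the normalized profile (first pixel set to
zero; jumps larger than $\pi$ repaired by $2\pi$ — defensive only, as real
profiles show no wrapping):

* **Turning point** — the first local maximum closest to the origin (index
  1 qualifies when the profile starts on a down trend) and then the first
  local minimum whose *topographic prominence* (height above its key col,
  the scipy/pracma definition) reaches `min_prominence`. The default
  threshold is three times the median per-pixel phase CI width, tying
  "significant" to the estimated phase uncertainty. A profile with no
  qualifying minimum raises a "no turning point" error — the video is
  excluded, exactly as a monotone profile would be. Extrema are located on
  the raw profile; a window-3 moving median is available behind
  `smooth = TRUE` but off by default.
* **Trend lines** — unweighted ordinary least squares of phase on distance
  over the closed down-trend interval $[i_{\max 0}, i_{\mathrm{turn}}]$
  and up-trend interval $[i_{\mathrm{turn}}, i_{\max 1}]$, the slope
  converted to a signed PWV by $2\pi/(T \cdot \text{slope})$. A zero slope
  reports NaN with a degenerate flag. (Weighting by phase CI was
  considered and left out: the estimator is specified as a plain
  least-squares line.)
* **Up-trend end** — the first local maximum past the turning point with
  prominence at or above the threshold; if none qualifies (e.g. a strictly
  increasing tail), the global maximum of the post-turn segment is used
  and flagged weak.
* **Hump width** — nonlinear least squares (Levenberg–Marquardt,
  `minpack.lm`) of $A e^{-(x-\mu)^2/2\sigma^2} + c$ to the
  distance–amplitude curve, $\sigma > 0$ constrained, full profile first
  and a half-max window as fallback; $HW = 2\sigma$. The baseline $c$ is
  included because real amplitude profiles do not decay to zero; on a pure
  Gaussian it is absorbed exactly. The position of maximum amplitude is
  the argmax of the per-pixel amplitudes, not the fitted $\mu$ (both are
  reported).
* **Distances** — $D_1 = |x_{\mathrm{turn}} - x_{\mathrm{maxamp}}|$,
  $D_2 = x_{\mathrm{turn}} + \text{offset}$, $D_3 = D_1/HW$,
  $D_4 = D_2/HW$, $D_5 = x_{\mathrm{maxamp}} + \text{offset}$, where the
  offset is the Euclidean distance from the optic disc center to the path
  start. A missing hump width leaves $D_3, D_4$ missing and the rest
  intact. The identities $D_3 \cdot HW = D_1$ and $D_4 \cdot HW = D_2$
  hold exactly by construction and are asserted on every analyzed video.

## Preprocessing

* **Sharpness** — variance of the 3×3 Laplacian response; Gaussian blur
  strictly lowers it, and ties break to the lowest frame index.
* **Registration** — intensity-based affine registration of every frame to
  the sharpest: a coarse integer-translation search followed by BFGS on
  the six affine parameters with analytic gradients (chain rule through
  the bilinear warp), minimizing the interior MSE. Both images are
  pre-smoothed by a 1-px Gaussian for *estimation only* — bilinear
  interpolation attenuates high frequencies unevenly across subpixel
  offsets, which otherwise biases the optimum measurably — and the
  original frames are resampled under the estimated transform. Frames
  whose optimization does not converge are flagged; more than 20%
  flagged is an error.
* **Centerline** — Zhang–Suen thinning of the manually delineated vein
  mask to a single-pixel skeleton. A skeleton with a branch point is
  rejected with a mask-cleanup message (study veins are non-branching by
  construction). The path starts at the skeleton pixel closest to the
  disc center; when that pixel is interior, the longer arm is walked,
  matching paths that start near the disc center and run outward.
  Distances accumulate 1 or $\sqrt2$ pixel units, scaled by
  mm-per-pixel = disc height (mm) / disc height (px). No vessel
  segmentation is attempted — masks are inputs.

## The synthetic generator

`wave_ground_truth()` + `generate_series()` realize the model above with
known parameters: a piecewise-linear phase ramp with slopes
$2\pi/(T\,v)$ on each side of the meeting point `x_turn`, a Gaussian
amplitude hump $A(x)$ over a constant signal baseline, first plus second
harmonic, broken-stick drift with knots at the cycle boundaries, and
per-pixel AR(1) noise. `render_frames()` optionally rasterizes the series
into frames (vessel pixels carry $e^{-s/68}$ quantized to the stated bit
depth) with known per-frame affine jitter, emitting the true masks and
transforms so the preprocessing chain can be tested end to end.

Default scene, chosen once as the study conditions and used by the tests
and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| `n_pixels`, `mm_per_px` | 60 px, 0.01 mm | sub-millimeter paths, as in disc veins |
| `fps`, `cardiac_period` | 25 Hz, 1.0 s → 75 frames | three full cycles |
| `speed_retro`, `speed_antero` | −30, +20 mm/s | magnitudes of reported disc-vein PWVs |
| `x_turn` | 0.40 mm | turning point in the distal half of the path |
| `amp_peak`, `amp_mu`, `amp_sigma` | 6, 0.30 mm, 0.20 mm | hump peaked between disc center and turning point; width at the broad end of observed hump widths so pulsation stays measurable along the full path |
| `baseline` | 30 | keeps rendered intensities mid-range |
| `h2_ratio` | 0.3 | venous pulses are far from sinusoidal |
| `drift_slopes` | (0.5, −0.3, 0.2) /s | visible but small lighting drift |
| `rho`, `noise_sd` | 0.3, 0.06 (1% of peak) | frame-to-frame correlation; noise low enough that phase CIs are narrow relative to the ~0.08-rad down-trend excursion, reproducing the clean, clearly segmentable profiles real recordings show |

Two physics caveats are intentional. The generator imposes *kinematic*
phase ramps — no vessel-wall mechanics, no pressure coupling — and the
Gaussian amplitude hump is an assumption consistent with the hump-width
estimator, not a derived superposition law. Passing the recovery tests
therefore shows the *estimator* is correct and calibrated, not that real
veins follow this generative model.

The noise default deserves its own note. The phase excursion over a
sub-millimeter path at tens of mm/s is small (≈0.06–0.08 rad per branch).
At noise levels much above ~2% of peak amplitude, the per-pixel phase
uncertainty exceeds the entire turning-point prominence, and no local
extremum detector — including this one — can segment the profile; the
correct behavior there is the "no turning point" exclusion, which is what
the implementation does. The 1% default emulates recordings in the regime
where the method is actually usable, and the test suite demonstrates both
regimes.

Rendered scenes default to a *textured* static background (a smooth random
field, `texture_sd = 0.05`). A perfectly flat background would leave the
pulsating vessel as the frames' only structure, making intensity-based
registration ill-posed by construction — the registration would chase
brightness changes. Real fundus frames are rich in static texture;
`texture_sd = 0` restores a flat background for tests that want one.

## Study-level statistics

`summarize_by_subject()` reports per-subject medians and IQRs of the
signed S1/S2 with a pooled mean/IQR row; `summarize_distances()` gives the
min/max/mean/SD/median/IQR table for D1–D4. All quantiles use linear
interpolation between order statistics (R type 7), fixed and documented
because IQRs are reported artifacts. `select_matched_pressures()`
operationalizes "similarly matched" induced pressures: for each subject,
the five in-range videos minimizing total absolute deviation from a common
evenly spaced pressure grid (16–45 mm Hg), solved by monotone-assignment
dynamic programming with ties broken toward lower pressures; subjects
without five in-range videos are flagged and excluded. The
`pitman_morgan()` test of equal variances for paired samples uses the
correlation of pairwise sums and differences, $t = r\sqrt{(n-2)/(1-r^2)}$
on $n-2$ df; zero variance in sums or differences yields a flagged
degenerate result with $p = 1$. Linear mixed models are deliberately not
wrapped: they are off-the-shelf fits on the output table, which is
structured so any statistics environment can consume it.

## Problem sizes and what the checks show

The self-checks run at the default scene (60 pixels × 75 frames): 50
seeded recovery runs for the headline experiment, 500 simulations for
phase-CI coverage, 200 for hump-width robustness, 10,000 for the
Pitman–Morgan size, and three rendered scenes (72×90 px, 75 frames, 1-px
jitter) for the registration round-trip — sizes at which the estimator's
bias and spread are measured directly rather than assumed. The rendered
round-trip scene uses a straight vessel so that the generator's uniform
distance grid coincides with the drawn centerline's arc length; on a
curved scene the two differ by the arc factor, which is a property of the
fixture's parameterization, not of the estimator (curved scenes are tested
separately for centerline recovery and at looser tolerance end to end).

## Known limitations

* Phase estimates beyond the up-trend end are ignored by design; real
  profiles show no discernible trend and large CIs there.
* The cardiac period is an input; the periodogram fallback
  (`estimate_cardiac_period()`) assumes the cardiac peak dominates after
  detrending.
* Registration assumes mostly static scene content; it is intensity-based
  MSE, with interpolation order fixed to bilinear.
* The pressure-matching objective is one defensible reading of "similarly
  matched"; any deterministic selector can be substituted upstream of the
  summaries.
* Induced IOP is metadata; its computation from ophthalmodynamometer
  force is out of scope, as are mixed-model inference and clinical
  interpretation.

## A worked synthetic example

```{r example, eval = FALSE}
truth <- wave_ground_truth(seed = 1)
series <- generate_series(truth)
result <- pwv_pipeline(series)
result
plot(result)
```
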