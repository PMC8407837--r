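---
title: "Lookup-table localization for astigmatic 3D SMLM: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lookup-table localization for astigmatic 3D SMLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generators do and do not emulate, and the design decisions
taken where the method leaves room.

## The model and its assumptions

A single fluorophore imaged through a cylindrical lens produces an
elliptical Gaussian spot whose widths encode its axial position. The
package models the expected counts in a fit window as

$$\mu_{ij} = \theta_{bg} + \theta_p \,
  \mathrm{PSF}_{ij}(\theta_x, \theta_y, \theta_z)$$

with the unit-peak astigmatic Gaussian of `psfValue()`:
$\sigma_x(z)$ and $\sigma_y(z)$ are cubic B-splines calibrated from a
bead z-stack, and $\varphi$ is an in-plane rotation of the ellipse.
The assumptions this buys:

* **One emitter per fit window.** The non-maximum suppression is
  deliberately not a multi-emitter deconvolution; overlapping emitters
  are out of scope, and experiments (and the simulators) are designed
  with a minimum emitter distance.
* **The Gaussian approximates the real PSF.** Phase-retrieved or
  measured PSF templates are not implemented; the lookup-table
  machinery would accept any model with first derivatives, but only
  the sampled and pixel-integrated Gaussians are built in.
* **Least squares, not maximum likelihood.** The fit minimizes
  unweighted squared residuals because only first derivatives are then
  required; the Cramér–Rao bounds are reported as the benchmark an
  unbiased estimator could at best reach, not as the fit's own
  precision.

The pixel-integrated variant (`psfValueIntegrated()`) integrates the
Gaussian over each pixel (separable erf form, $\varphi = 0$ only) and
is rescaled by $2\pi\sigma_x\sigma_y$ so integrated intensities convert
to peak intensities; its central value approaches 1 only asymptotically
as $\sigma$ grows, which is the convention adopted here.

## Coordinates and the lookup-table grid

Pixel centers sit at integer coordinates, x along columns, y along
rows, both 0-based in pixel units; z is in nm with the focal plane of a
synthetic calibration at 0. One convention, used everywhere.

The grid covers lateral offsets $[-r_{xy}/2, +r_{xy}/2]$ inclusive in
steps of $\Delta_{xy}$ and the axial interval
$[z_{focus} - r_z/2, z_{focus} + r_z/2]$ in steps of $\Delta_z$;
$r/2$ must be an integer multiple of the step so the grid is symmetric
with a center point. The defaults — window 9 px, $\Delta_{xy} = 0.1$ px,
$r_{xy} = 4$ px, $\Delta_z = 25$ nm, $r_z = 1000$ nm — give
$41^2 \times 41 = 68\,921$ templates (170 MB in double precision).
Published template counts for nominally similar parameters are
internally inconsistent, so the count is derived from the convention
and reported by `show()`, never hard-coded. Positions snap to the grid
by rounding half away from the center, a fixed and documented
tie-break. Between-template interpolation is deliberately absent: the
discreteness is the method.

## Detection

Maxima are identified on the raw image (a pixel not smaller than its 8
neighbors) and scored by the mean of the 3×3 block around them — the
"mean of nine pixels" modification that makes suppression robust to
single-pixel noise. Competing maxima within a Chebyshev radius of
`floor(window/2)` (i.e. a window-sized suppression square) are resolved
greedily in decreasing-score order, ties lexicographically by
(row, col), so detection is deterministic. A window-sized square rather
than a window-sized radius is used because a 9 px radius would suppress
legitimate emitter pairs at the benchmark's own 7.5 px minimum
distance.

The local background is the mean along the boundary line of an
11 px square (even sides are supported with a half-open convention),
and a candidate survives when its **smoothed score** exceeds
background + threshold. Thresholding the raw peak pixel instead
(`peakStatistic = "raw"`) is supported but discouraged at high EM gain,
where a single pixel's excess-noise standard deviation is about half
the signal; for the same reason $\theta_p$ is initialized from the
score rather than the raw peak, which is nevertheless reported in the
candidate table. The threshold itself is subjective and
experiment-dependent; for the synthetic benchmark the package uses 5×
the background-pixel noise standard deviation of the camera model,
$\sqrt{2 g^2 c + \sigma_{ro}^2} \approx 74.6$ counts, i.e. 375 counts.

## Fitting: termination, acceptance, tolerances

Iterations follow the normal-equations Gauss–Newton update with the
Jacobian assembled from the template channels; the 5×5 system is solved
through its Cholesky factor (the normal matrix is symmetric by
construction), and a numerically non-positive-definite system
terminates the fit as `degenerate` rather than erroring. Initialization:
$\theta_{x,y}$ at the window center, $\theta_z$ at the focal plane,
$\theta_{bg}$, $\theta_p$ from the candidate search.

Termination: convergence (rounded position unchanged **and** relative
changes of $\theta_{bg}$, $\theta_p$ below `tol = 1e-3`, a value the
method itself does not prescribe), the iteration budget
(`maxIterations = 5`; the discretization is what makes such a small
budget workable), or the position leaving the lateral/axial range.

**Acceptance** is the one place this package deviates from a literal
"converged-only" rule: a fit that exhausts its 5 iterations while
staying inside the grid *is* the best discrete fit the method produces,
and excluding such fits would discard roughly half of all emitters
under the benchmark's EMCCD noise — far below the recovery the method
is known to reach. The default `accept = "in_range"` therefore keeps
`converged` and `max_iterations` fits with positive peak and a position
strictly inside the grid; `accept = "converged"` restores the stricter
rule.

CRLBs come from the inverse Fisher information with per-pixel variance
$\mu$ (Poisson) or, when an EMCCD model is supplied,
$2 g (\mu - \text{baseline}) + \sigma_{ro}^2$ — the Gaussian
approximation carrying the electron-multiplying excess-noise factor 2.

## What the generators emulate — and what they do not

`applyEMCCDNoise()` models the counting chain as
Poisson(QE·photons + spurious) photoelectrons, Gamma-amplified with
mean gain $g$ (the standard EM-register approximation, excess-noise
factor 2), Gaussian readout noise, baseline offset, integer rounding.
Not modeled: per-pixel gain/offset maps, charge smearing, sCMOS-style
correlated noise.

The 3D Siemens star places emitters uniformly in 20 filled 9° sectors
(alternating with 20 blank ones) of an annulus, with per-frame
rejection sampling enforcing the 7.5 px minimum distance. The axial
staircase is read as 20 sectors at $z_0 = -450 + 45k$ nm, $k = 0..19$
(the phrase "−450 to 450 in 45 nm steps" is arithmetically 21 levels
for 20 sectors; this package uses 20 levels topping out at +405 nm),
plus Normal(0, 25 nm) jitter recorded in the ground-truth column `z0`.
Emitters carry **constant integrated flux**: the expected peak is 2000
counts in focus and falls as $1/(\sigma_x\sigma_y)$ with defocus. A
constant-peak reading would make every defocused emitter as bright as a
focused one, removing the very mechanism (photons spread over more
pixels, lower SNR) that limits recovery at the axial extremes.

The synthetic calibration (`defaultStarCalibration()`) uses the
standard defocus curves
$\sigma_{x,y}(z) = \sigma_0\sqrt{1 + ((z \mp \delta)/z_R)^2}$ with
$\sigma_0 = 1.3$ px, $\delta = 250$ nm, $z_R = 350$ nm — realistic
values for a cylindrical-lens setup at 100 nm pixels, chosen once.
Real calibrations are asymmetric and setup-specific; recovered
fractions on real data will shift with the steepness of the true
curves, so passing synthetic tests demonstrates correctness of the
machinery, not a guarantee for any particular microscope.

The blinking generator is a per-fluorophore dark/on/bleached Markov
chain whose activation rate rises linearly with UV power — enough to
exercise the feedback controller's closed loop, but with no aggregation
into realistic photophysics (no multiple dark states, no power-dependent
bleaching).

## Evaluation choices

Matching uses per-frame globally optimal one-to-one assignment
(Jonker–Volgenant shortest augmenting paths) on 3D distances, gated at
250 nm lateral / 500 nm axial — the 2016 localization-challenge gates,
configurable. Efficiency is
$E = 100 - \sqrt{(100(1-JI))^2 + (\alpha\,\mathrm{RMSE})^2}$ with
$\alpha = 1\,\mathrm{nm}^{-1}$ lateral and $0.5\,\mathrm{nm}^{-1}$
axial, overall the mean of the two. FRC uses 1-bin rings, a 3-ring
moving average (the smoothing width is not prescribed anywhere, so it
is fixed here), resolution at the first crossing of 1/7, and reports
*all* crossings because discretely fitted data can dip more than once.
FRC rendering follows the standard 25 nm Gaussian blobs on 16.67 nm
pixels. The max-z histogram renderer keeps the highest axial position
per super-resolution bin and refreshes the color render every 10
frames; a bin holding a localization at exactly z = 0 is
indistinguishable from an empty bin in the returned map (an occupancy
mask disambiguates internally for rendering).

## Feedback controller

Strictly-below-threshold counts (25/frame) over 5 consecutive frames
trigger the controller; the first trigger turns the laser on at one
power step (5 mW — the turn-on power is not prescribed, so it is one
step), later triggers add a step, clamped at a 50 mW safety maximum
(invented, documented). The streak re-arms after every trigger and
resets on any frame at or above threshold. The controller is a pure
function of state and input, so runs replay exactly.

## Problem sizes used by the tests

The test-suite benchmark is a 10%-scale rendition of the full star —
22 500 emitters over 500 frames with all physical parameters unchanged
(fractions are scale-free; their binomial standard error at this scale
is under 0.3 percentage points). The continuous reference fitter runs
on a 150-frame subset in the suite and on the full 500 frames in
`scripts/acceptance.R`. The step-size comparison refits 100 frames with
$\Delta_{xy} = 0.05$ px / $\Delta_z = 10$ nm (a 1.7 GB table, the main
cost of refinement). Monte-Carlo CRLB checks use 250 replicates.

## Known limitations

* No multi-emitter fitting, drift correction, or automated (Bayesian /
  GMET) thresholding; the threshold is a user decision.
* The integrated PSF model requires $\varphi = 0$ (it falls back to the
  sampled model with a warning otherwise).
* `readStack()` materializes the TIFF stack page list in memory; true
  lazy streaming would need a chunked reader.
* The discrete fitter's errors contain a grid-quantization component
  (up to half a step per axis); with the default steps this is small
  against the noise-limited precision, which is the regime the method
  is intended for.
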