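---
title: "Quantifying single-cubosome fusion with supported lipid bilayers"
author: "cubofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cubosome fusion with supported lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubofuse)
```

## The problem

Cubosomes — nanoparticles of a bicontinuous cubic lipid phase, typically
monoolein-based — are candidate drug nanocarriers whose mode of
interaction with cell membranes decides how they deliver cargo. A clean
way to watch that interaction is to form a supported lipid bilayer (SLB)
on glass as a model membrane and image dye-loaded cubosomes by total
internal reflection fluorescence (TIRF) microscopy: the evanescent field
only excites the ~100 nm above the substrate, so docking and fusion of
individual particles appear as bright spots that land, linger and then
fade while a fluorescent halo spreads into the bilayer.

The discriminating observable is the decay of the spot's peak intensity
$I_\mathrm{max}(t)$ after fusion starts. If the particle merely released
its dye at a point, 2-D diffusion would dilute the peak concentration as
$c_\mathrm{max} \sim 1/t$, i.e. a fitted power law $I = a\,t^{-n}$ with
$n = 1$. Whole-particle fusion predicts something much slower, and that
difference is what this package quantifies.

## The finite-source scaling model

Treat the docked particle as a cube of side $R(t)$, density $\rho$,
feeding lipid and dye into a bilayer of height $h$ where it diffuses
laterally with coefficient $D$. Mass balance gives

$$\rho R^2 \dot R = -D h\, \delta c,$$

with the sign chosen so the particle sheds mass. The driving gradient
across the expanding fluorescent footprint of diameter $L$ is, by Fick's
law,

$$\delta c = \frac{c_\mathrm{max} - c_{L/2}}{L/2},$$

with three modelling commitments taken literally from the physics of a
2-D source: the peak concentration decays as $c_\mathrm{max} = A/t$;
there is no dye outside the footprint, so $c_{L/2} \equiv 0$; and the
footprint grows diffusively, $L = B\sqrt t$. Together,
$\delta c = (2A/B)\, t^{-3/2}$ — `delta_c_profile()` evaluates this and
its log–log slope is $-3/2$ exactly.

Writing $C = 2 A D h / (B \rho)$, the cube of the side length obeys
$\mathrm d(R^3)/\mathrm dt = -3C\,t^{-3/2}$, so

$$R^3(t) = R_0^3 - 6C\left(t_\mathrm{start}^{-1/2} - t^{-1/2}\right).$$

`integrate_shrinkage_ode()` integrates the ODE numerically
(`deSolve::lsodar`, with a root that clamps $R$ at zero once the
particle is spent) and is validated against this closed form to a
relative $10^{-6}$. Two regimes follow:

* **Self-similar branch** (`power_law_branch()`): when
  $R_0^3 = 6C\,t_\mathrm{start}^{-1/2}$ the constants cancel and
  $R(t) = (6C)^{1/3} t^{-1/6}$. With the peak intensity proportional to
  $R$ (the dye is homogeneous in the particle, and TIRF reads the
  column above the footprint centre), this is the hallmark prediction
  $I_\mathrm{max} \propto (Dh/\rho)^{1/3} t^{-1/6}$, i.e. $n = 1/6$.
* **Depletion**: a smaller $R_0$ reaches $R = 0$ at the closed-form
  root; the trajectory records the depletion time.

Two numerical oracles pin the ingredient scalings rather than assuming
them: `simulate_point_release_2d()` solves
$\partial_t c = D \nabla^2 c$ by explicit finite differences (compiled;
reflecting boundaries conserve mass exactly; a CFL guard refuses
unstable steps) and reproduces the Green's-function peak
$M/(4\pi D t)$, hence the $n = 1$ reference; `footprint_diameter()`
measures the half-maximum footprint of that solution and recovers
$L = 4\sqrt{D t \ln 2} \propto \sqrt t$.

### The $t = 0$ singularity

The $t^{-3/2}$ gradient diverges at $t = 0$, and the time-integrated
form as printed diverges if integrated from zero. Everything is
therefore regularised at a start time $t_\mathrm{start} > 0$, by
convention one frame interval (0.03 s); the self-similar branch is
exactly the solution on which the choice of $t_\mathrm{start}$ drops
out of the exponent. `fusion_model_params()` refuses
$t_\mathrm{start} \le 0$.

## The synthetic movie generator

No raw microscopy data accompany the study this package operationalises,
so `render_movie()` generates TIRF movies with the statistical structure
the analysis assumes, and every downstream stage is tested against that
ground truth:

* bilayer background with per-pixel multipliers — 1 for a single
  bilayer, exactly 2 for a stacked double-layer patch, < 1 for dark
  domains;
* particles performing 2-D Brownian motion (`brownian_path()`,
  per-axis step variance $2D\,\Delta t$) before docking;
* after docking and a dwell, a decaying spot
  $I(\tau) = a\,(\tau + t_\mathrm{off})^{-n}$ above background, with
  Gaussian width growing as
  $\sigma^2(\tau) = \sigma_\mathrm{psf}^2 + g^2 \tau$ (diffusive
  footprint growth with rate $g$ in um s$^{-1/2}$);
* Poisson shot noise on the gain-scaled signal plus Gaussian read
  noise, applied last; the noiseless movie is available.

The amplitude $a$ is parameterised as the coefficient of the power law
in seconds (counts·s$^n$) — the same $a$ a fit of $I = a t^{-n}$ to the
extracted trace reports — so a noiseless rendering round-trips its
$(a, n)$ through the fitter exactly. The rendered peak at fusion onset
is $a\,t_\mathrm{off}^{-n}$ counts; `amplitude_for_peak()` converts a
desired docking peak (e.g. an SNR target) into $a$. The time offset
$t_\mathrm{off}$ defaults to one frame interval, keeping the first
rendered sample finite; it is recorded in the ground-truth table.

Defaults are the acquisition conditions of the imaging this emulates:
0.16 um px$^{-1}$, 0.03 s frames, a ~1.3 px PSF sigma (diffraction
limited at that calibration), 100-count bilayer background with
2-count read noise, lognormal particle sizes of arithmetic mean 200 nm
(log-sd 0.3, the right-skewed distribution such preparations show)
modulating the event amplitude proportionally and the pre-docking
diffusion coefficient inversely (Stokes–Einstein).

What the generator does *not* emulate — photobleaching, axial motion,
evanescent-depth weighting, protein coronas, fractal domain boundaries,
cell-shaped backgrounds — bounds what passing tests prove: the pipeline
is validated against an idealised model of the imaging, not against the
full physics of a real experiment.

## Tracking and sizing

`detect_spots()` is Crocker–Grier-style: Gaussian smoothing minus a
boxcar local background, 3×3 local maxima above a robust threshold
(default 2.5·mad of the frame — about 8 sd of the bandpassed noise),
strongest-first exclusion of candidates closer than one spot diameter,
and centroid refinement (sub-0.2 px on clean spots).
`link_tracks()` links greedily by increasing displacement with a fixed
tie order and a gap memory. `compute_msd()` computes the time-averaged
MSD and fits $\langle r^2\rangle = 4 D \tau$ through the origin,
down-weighting long lags as pairs/lag$^4$: per-lag estimates of a
time-averaged MSD have variance growing like lag/track-length and are
strongly correlated, so an unweighted fit over many lags is dominated by
noise; in the small-lag limit the weighted fit approaches the lag-1
estimator, which is maximum-likelihood for pure Brownian motion when
localisation noise is negligible. `stokes_einstein_diameter()` converts
$D$ to a hydrodynamic diameter (defaults 298 K, 0.89 mPa s).

## Event analysis

`segment_events()` declares a docking where a track's rolling positional
spread over 8 localisations stays under 2 px *and* the track holds that
position afterwards — the persistence clause is what separates docking
from a chance cluster of Brownian steps. The fusion onset inside the
docked episode is located on a PSF-matched amplitude readout (once the
footprint outgrows the PSF, the matched value drops with both the
fading peak and the width mismatch, so the plateau-to-decay kink is
several times sharper than on any single pixel) in two stages: a coarse
trigger where the trailing 5-frame mean first falls clearly below the
early-plateau median, then a least-squares change point inside a local
window around the trigger, with the decay constrained to start at the
plateau level (a single regression on a kinked log-time regressor).
Scoring locally keeps the long tail of the decay — whose log-log shape
need not be exactly linear for a matched readout — from tipping the
comparison; the estimate is exact on noiseless traces and a frame or
two of jitter at SNR 10. The onset also yields the dwell. Fragmented
tracks can re-dock at an already-claimed site, so only the earliest
event within 4 px of a docking position is kept.

`extract_trace()` offers three readouts. The default, `"gauss_amp"`,
estimates the per-frame amplitude of a Gaussian centred at the tracked
position by weighted least squares, with the width per frame obtained
from the mass ratio of two concentric pixel disks — inverted against the
ratio curve of the *discrete* pixel sets, since the continuous-integral
ratio is a few percent off on a jagged disk — and regressed as
$\sigma^2 = \sigma_\mathrm{psf}^2 + b\tau$ (only the slope is free;
the intercept is the instrument PSF; weights follow from error
propagation, since the inversion loses conditioning once the spot
outgrows the disks). This readout is unbiased under sub-pixel centre
offsets and footprint spreading; any fixed-pixel readout decays too
slowly as the spreading Gaussian flattens over its neighbourhood, and a
per-frame aperture maximum is an upward-biased order statistic on noisy
data. Both alternatives (`"peak_pixel"`, `"aperture_max"`) remain
available; the aperture maximum is exact on noiseless movies.

`fit_power_law()` fits $\log I$ on $\log t$ by OLS (Theil–Sen
optional), with time measured from the onset frame and the first point
one frame interval later. At the pipeline level (`fit_events()`) the
samples are first averaged in linear intensity over logarithmic time
bins (8 per decade): naive log–log fitting at low SNR is biased two
ways — the concavity of the log pulls faint samples down, and dropping
individual samples that fluctuate below a noise floor selects the
upward fluctuations — and binning removes both at the cost of a
negligible curvature error. `fusion_time()` implements the operational
definition — time from the peak until the trace stays within
$k\sigma$ (default 2) of background for 3 frames — and reports
unresolved decays as censored rather than dropping them, which keeps
fusion-time distributions honest. `aggregate_events()` summarises per
condition, and `plot_exponent_scatter()` overlays the $n = 1/6$ and
$n = 1$ reference lines.

`fusion_ensemble_study()` wires the whole chain together: events on the
self-similar branch ($n = 1/6$), lognormal sizes, camera noise at a mean
docking SNR of 10, rendered into seeded movies and pushed through
detection, linking, segmentation and fitting. Segmentation treats one
docked episode per track; repeated partial-fusion episodes on a single
track are out of the segmenter's scope.

## Bilayer-formation kinetics

`coverage_curve()` thresholds each frame (fixed threshold, or Otsu
computed once on pooled frames so the cut is common to the whole movie)
and reports the covered fraction. `fit_erf_growth()` fits

$$\theta(t) = \frac{\theta_\mathrm{max}}{2}
  \left[1 + \operatorname{erf}\!\left(\frac{t - t_c}{\sqrt 2\,\tau}\right)\right],$$

a three-parameter form chosen so the maximum growth rate
$\theta_\mathrm{max}/(\tau\sqrt{2\pi})$ occurs at $t_c$; the fitted
gradient is the corresponding Gaussian. Data with $R^2 < 0.5$ are fitted
but flagged rather than refused. `count_domains()` counts connected
components above threshold under selectable 4/8-connectivity (labelling
is done in-package; a minimum area of 4 px suppresses shot-noise
specks). `simulate_nucleation_growth()` provides the oracle: Poisson
nucleation in space–time, radial growth with merging on contact, an
analytic event log (nucleations, and the union–find-filtered contacts
that actually join two clusters), producing the expected sigmoidal
coverage and a domain count that rises, peaks and collapses to one.
Real domains grow with fractal boundaries; radial growth is a deliberate
simplification, adequate for testing counting and coverage logic but not
boundary morphology.

## Numerical choices and problem sizes

* Diffusion solver: explicit FTCS with step $0.9\,\Delta x^2/(4D)$;
  accuracy is checked against the Green's function, so the scheme choice
  is free. Scaling checks use a 512² grid over two decades of time; unit
  tests use 101–201² grids.
* ODE: `lsodar`, relative tolerance $10^{-10}$, validated against the
  closed form; the state variable is $R^3$, which is linear in the
  forcing and immune to the $R \to 0$ singularity.
* Seeds: every stochastic component takes an explicit integer seed;
  identical prescriptions and seeds give bit-identical movies, tracks
  and tables.
* The ensemble study runs 200 events (10 movies of 20 events on 128²
  frames, 300 frames at 0.03 s) — enough that the Monte-Carlo error on
  the mean exponent (~0.001–0.002) is far below the width of the event
  distribution, while a full run stays in the minutes range on one
  core.
* Degenerate inputs: blank frames yield empty detections; all-background
  movies yield $\theta \equiv 0$; constant traces fit $n = 0$; fits with
  fewer than 8 usable points are refused with a reason; tracks shorter
  than 10 points are skipped for MSD.

## Interfaces

TIFF stacks are written 16-bit with the calibration in a YAML sidecar
(the linked TIFF library does not expose the description tag on write;
`read_stack()` also parses `pixel_size_um=` entries from description
tags written by other software, and falls back to configured values
with a logged notice). Tables are CSV with stable headers
(`track_id, frame, t_s, x_um, y_um, mass`;
`event_id, condition, x_um, y_um, t_land_s, dwell_s, fusion_time_s,
censored, a, n, r2`), summaries JSON, configuration YAML with unknown
keys rejected and all defaults echoed next to the outputs. Coordinates
are pixel-centred, origin top-left, x along columns, physical units um;
times are seconds from the first frame. `run_pipeline()` drives the
stages (`simulate`, `track`, `fuse`, `coverage`, `model-check`, `all`),
and `inst/scripts/cubofuse.R` is a thin shell wrapper around it.

## Known limitations

* The intensity model is the non-saturated-membrane regime; lipid
  exchange with a saturated bilayer is out of scope.
* The exponent pipeline assumes one fusion episode per docked track.
* Fusion times of slowly decaying bright events are frequently censored
  at the movie end — a property of the power-law tail, reported as such.
* The erf parameterisation of coverage growth and the threshold
  definition of the footprint diameter are conventions; both are
  exposed as parameters rather than claims.
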