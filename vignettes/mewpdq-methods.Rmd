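---
title: "Joint projection-domain quantification of Th-227 and Ra-223: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint projection-domain quantification of Th-227 and Ra-223: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mewpdq)
```

## The quantification problem

Thorium-227 conjugates are alpha-particle radiopharmaceutical therapies.
After administration, Th-227 decays to Ra-223, which redistributes
independently, so dosimetry requires estimating the regional activity of
*both* isotopes.  Both emit X- and gamma-rays detectable by SPECT, but the
task is hard: administered activities are orders of magnitude below
conventional SPECT (extremely low counts), the two emission spectra overlap
heavily (crosstalk), and the usual image-degrading effects (attenuation,
collimator blur, scatter) apply.

`mewpdq` implements a multiple-energy-window projection-domain
quantification method: instead of reconstructing voxel images and averaging
over volumes of interest (VOIs), it estimates the K regional uptake values
of each isotope *directly* from the projection counts acquired in several
energy windows.

## Statistical model

With VOI indicator functions $\phi_k(\mathbf r)$ and constant uptake
$\lambda_k$ per region, the expected counts in projection bin $m$ (spatial
bin $\times$ energy window) are

$$\bar g_m = \sum_{k=1}^{K} H^{Th}_{mk}\lambda^{Th}_k
           + \sum_{k=1}^{K} H^{Ra}_{mk}\lambda^{Ra}_k + \psi_m ,$$

where $H^{Th}, H^{Ra}$ are $M\times K$ regional system matrices (expected
counts per unit uptake concentration in each VOI, per isotope) and $\psi$
is the stray-radiation noise mean, constant within each energy window and
proportional to the window width.  Counts are independent Poisson.  Writing
$H = [H^{Th}\; H^{Ra}]$ and $\lambda = (\lambda^{Th}, \lambda^{Ra})$, the
maximum-likelihood estimate is obtained by the multiplicative EM iteration

$$\lambda_k^{(t+1)} \;=\; \frac{\lambda_k^{(t)}}{\sum_m H_{mk}}
  \sum_m H_{mk}\, \frac{g_m}{(H\lambda^{(t)})_m + \psi_m},$$

applied jointly to both isotope blocks with the shared composite
denominator — this is what compensates crosstalk: photons of either isotope
in any window are explained by a single coupled model.  The likelihood is
non-decreasing at every iteration (asserted in the tests), non-negativity
is preserved, and exact zeros are absorbing.

Defaults: a flat positive initialization whose total matches
$(\sum_m g_m - \sum_m \psi_m)$ divided by the total sensitivity, and a
fixed 1000-iteration protocol (`runMewPdq(..., maxIter = 1000)`); an
optional early stop on the maximal relative change (`tol`) is available.
Division guards skip bins whose model mean underflows `1e-30`.  The number
of unknowns ($2K = 8$ in the pelvic setting) is tiny compared with $M$, so
the problem is far better posed than voxel reconstruction.

## Emission spectra and energy windows

Line tables for Th-227 and the Ra-223 chain (Ra-223 with its short-lived
daughters Rn-219, Po-215, Pb-211, Bi-211, Tl-207) are bundled as plain
text, compiled from public decay-data tabulations (NNDC NuDat / ICRP 107);
lines below `1e-4` photons/decay are dropped (configurable floor).  The
detector energy response is Gaussian with relative FWHM
$\propto 1/\sqrt{E}$ anchored at 9.8% at 140 keV (NaI statistics; only the
anchor is a measured quantity).  The per-line window weight is the exact
Gaussian mass of the half-open window $[low, high)$ times the line
intensity.

Default windows are W1 74–94, W2 140–168, W3 216–256, W4 256–288 keV — a
documented package convention bracketing the radon/radium K X-rays (W1),
the 144/154 keV Ra-223 lines (W2), the Th-227 236/256 keV photopeaks
(W3/W4) and the 269/271 keV Ra-223/Rn-219 photopeaks (W3/W4 boundary
region).  The overlap is intentional: each window receives photons from
both isotopes, and the estimator exploits the differing spectral signatures.

## The simplified projector

A full Monte-Carlo transport model is deliberately out of scope.  The
forward model is: per energy group, attenuated parallel-beam line
integrals (attenuation scaled to the group energy through bundled
NIST-derived mass-attenuation tables for water and bone), distance-
dependent Gaussian collimator + intrinsic blur (3.9 mm intrinsic; 1.6 mm
FWHM/cm slope, a high-energy general-purpose-like value; 200 mm radius of
rotation chosen as a tight auto-contour for this torso), the exact
per-line window weights, and an optional broad-Gaussian scatter surrogate
(default scatter-to-primary fractions 0.30/0.15/0.10/0.08 per window,
50 mm FWHM — a documented convention; set to 0 to disable).  Projection
bins are congruent with the phantom grid; rows are ordered u, v, angle,
window.

Numerical choices that matter:

* Emission lines are pooled into energy groups (`energyGroupKeV`, default
  10 keV; desk profile 20 keV) for attenuation scaling; window weights stay
  exact per line.  Lines whose total window weight is below `1e-6` of
  their intensity are pruned.
* Depth-dependent blur is applied in `nDepthBands` bands (default 8; desk
  profile 5) whose kernels are truncated at $4\sigma$.
* The in-plane rotation of activity uses mass-conserving bilinear
  *splatting* (total activity of interior voxels is preserved exactly),
  while the smooth attenuation maps use bilinear gathering.  Forward and
  back projector are exact adjoints (verified numerically to machine
  precision), which guarantees that the truth is a fixed point of the
  voxel EM baselines and that likelihoods are monotone.
* Count level: `calibrateSensitivity()` scales the detection efficiency so
  the standard phantom yields a target total of `2e5` expected counts over
  all windows in 30 min — the extreme low-count regime of alpha-RPT SPECT.
  The absolute detected-count total of a real system is not available, so
  this target is an explicit, configurable study condition; regional
  precision scales as $1/\sqrt{\text{counts}}$.

System matrices are built by projecting unit-concentration indicators of
each VOI — analytic expectations, with no Monte-Carlo variance.  Because
simulation and estimation share this projector, all evaluations are
*matched-model*: they isolate estimator behaviour from model mismatch,
mirroring the original evaluation design in which one simulator served
both roles.

## Digital phantoms and the virtual imaging trial

The anatomy is a parametric stand-in for a licensed anthropomorphic
phantom: an elliptical-cylinder torso (semi-axes 120 x 85 mm, axial extent
two voxels short of the grid so small rigid motions stay inside the field
of view), a two-lobed pelvic bone (lobes at x = ±60 mm with semi-axes
50/42/52 mm), an ellipsoidal gut compartment, and a spherical bone lesion.
Only the VOI topology and uptake statistics matter to the estimator.
Attenuation is water-like in soft tissue (lesion and gut included) and
bone-like in bone at 1.55 g/cm³ effective density, scaled per photon
energy.

Standard uptake follows the clinically derived ratios
(background : bone : gut : lesion) = 12 : 30 : 100 : 300 for Th-227 and
2 : 5 : 25 : 20 for Ra-223, scaled so the combined total is 11 MBq split
5 : 1 between the isotopes (the ~82 h time point); both the split and
per-isotope totals are arguments.

Intra-regional heterogeneity uses a lumpy (sum-of-Gaussians) texture:
Poisson lump count, uniform centres in the region, isotropic width
$\sigma_k$, masked by the region support and rescaled so the regional mean
is preserved *exactly*; a zero-lump draw leaves the region homogeneous
(the alternative — an all-zero region — would contradict the mean
constraint).  Mixtures $W f_{het} + (1-W) f_{hom}$ interpolate
heterogeneity levels without moving regional means.  The same spatial
texture modulates both isotopes (a shared-vasculature assumption; the
study design does not specify otherwise).

The virtual imaging trial samples lesion diameter from
$\mathcal N(33.75, 12.64^2)$ mm truncated to [10, 60] mm (the lower bound
is the population convention; the upper bound guarantees containment in
the parametric bone), lesion centres uniformly within the bone subject to
full containment (bounded retries), per-region uptake ratios independently
from $\mathcal N(\mu, (0.1\mu)^2)$ truncated at zero, and a lognormal body
scale (log-SD 0.08) truncated to [0.85, 1.15] so every torso fits the
imaging grid.  One Poisson realization per patient.

Rigid misregistration shifts/rotates the activity and attenuation maps by
trilinear resampling while the VOI labels (and the system matrix built
from them) stay deliberately stale — the SPECT/CT mismatch design.

## Figures of merit and the Cramér–Rao bound

For repeated realizations of one patient: normalized bias
NB $= (\overline{\hat\lambda} - \lambda)/\lambda$, normalized standard
deviation NSD (population, $1/n$, so that NRMSE² = NB² + NSD² holds
exactly), and NRMSE.  Across a patient population with one realization
each, the ensemble NB is the *signed* mean of the per-patient normalized
errors (reported alongside its absolute value) and the ensemble NRMSE is
their rms; the signed mean is the definition consistent with an ensemble
bias far below the ensemble rms error.

The Poisson Fisher information for the composite parameter restricted to
an energy-window subset is
$F_{ab} = \sum_{m \in \text{subset}} H_{ma}H_{mb} / \bar g_m$; the
CRLB-derived NSD is $\sqrt{(F^{-1})_{aa}}/\lambda_a$.  Along nested window
subsets the information can only grow, so the CRLB-NSD is non-increasing —
the quantitative case for using all four windows.  A singular Fisher
matrix (e.g. the single-window dual-isotope problem on some geometries)
falls back, on request, to an eigenvalue-floored pseudo-inverse with a
warning.

## Reconstruction-based baselines

DOSEM is a joint dual-isotope ordered-subset EM over the voxel basis using
the same projector matrix-free (an explicit voxel system matrix would be
prohibitively large).  Defaults are 40 iterations x 15 subsets; the desk
profile uses 2 x 8 (16 updates, a clinically typical count).  With one
subset it is exactly dual-isotope MLEM (the tests verify this against an
independently coded R loop).  Regional estimates are voxel means over the
VOIs, optionally followed by a Rousset-style geometric transfer matrix
(GTM) correction whose K x K matrices are built by reconstructing each
VOI's noiseless expected projection (at the acquisition's count scale)
with the same protocol — a matched pipeline; the K reconstructions run as
one batch.  Triple-energy-window scatter subtraction is deliberately not
implemented: primary-photon crosstalk cannot be estimated from side
windows.

A finding worth recording: under the severe collimator blur and low-count
conditions of this application, the recon-based GTM leaves a 20–30%
residual lesion bias even on noiseless data, because limited-angle MLEM
retains a null space and its regional means are not additive across
sources.  The correction demonstrably reduces the lesion bias and recovers
truth to within ~10% only in a well-posed (blur-free, well-sampled)
fixture — consistent with the known limitation of reconstruction-based
quantification that motivates the projection-domain method.

## Problem sizes and profiles

All experiment drivers are pure functions of (config, seed), with
per-patient and per-realization seeds derived from the master seed by a
counter-based scheme.  Three profiles:

* `test` — 32x32x24 at 8.85 mm, 8 views; seconds per experiment (unit
  tests).
* `desk` (default) — 42x42x30 at 7.08 mm, 16 views, 60 patients, 25
  realizations, DOSEM 2x8, 20 keV grouping, 5 depth bands; minutes per
  experiment on one CPU.  The acceptance script runs this profile.
* `paper` — 128x128x96 at 2.21 mm, 60 views, 50 realizations, 60
  patients, DOSEM 40x15, 10 keV grouping.

The desk grid and view count were fixed from projector profiling; they
trade angular/spatial sampling for runtime and are stated here as the
package's own choices.  Because the count total (2e5) is held fixed by
calibration, the desk-scale Fisher information is close to the fine-scale
one; the dominant driver of attainable precision is the count level, not
the grid.

## What the synthetic studies do and do not show

Everything here is matched-model: the same simplified projector generates
the data and drives estimation.  Passing tests therefore demonstrate the
statistical behaviour of the estimators (unbiasedness, efficiency against
the CRLB, crosstalk separation, robustness trends) under a faithful
physics *surrogate* — not the absolute accuracy of the physics itself.
Real acquisitions add septal penetration, characteristic X-rays, detector
backscatter, dead time and anatomical variability that the parametric
torso does not carry.  Known limitations: small lesions (diameter below
roughly 20 mm) of the low-abundance isotope carry intrinsically poor
information at the 2e5-count calibration — their CRLB-derived NSD can
exceed 50% — so population summaries that average signed errors over
few dozen patients remain noisy for that cell; the constant-uptake VOI
model is misspecified under strong intra-regional heterogeneity; and the
method yields no voxel image, so voxel-level dosimetry is out of scope.
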