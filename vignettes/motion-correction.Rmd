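---
title: "Retrospective k-space motion correction with fat navigators: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective k-space motion correction with fat navigators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatnav)
```

This vignette is the package's account of the science it implements:
the signal model, the assumptions baked into each module, the numerical
choices, and the places where the design was genuinely open and a
choice had to be made. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

A multi-shot 3D Cartesian acquisition collects k-space in segments
("shots"): a GRE partition loop, an MP2RAGE inversion cycle with its two
readout trains, a TSE echo train. Head motion is modelled as
piecewise-constant over a shot — one rigid pose per navigator interval,
which matches a navigator cadence of a few seconds against motion that
is dominated by slow drift plus occasional jerks. For a shot acquired
with the head at pose $(R, t)$ (rotation about the volume centre, then
translation, both in scanner coordinates), the Fourier rotation and
shift theorem gives the measured sample at Cartesian frequency $k$ as

$$ s(k) \;=\; e^{-2\pi i\, k \cdot t}\; F(R^{\mathsf T} k), $$

where $F$ is the spectrum of the static coil-weighted object. The
retrospective correction inverts this shot by shot and channel by
channel: multiply by the conjugate phase ramp, reassign the sample to
$k' = R^{\mathsf T} k$, accumulate all shots, and reconstruct each
channel with the adjoint (type-1) non-uniform FFT on the target grid.
Channels are combined by root-sum-of-squares.

Assumptions worth stating explicitly:

* **Coil sensitivities stay in the scanner frame.** The object is
  weighted by each coil map *before* the motion is applied. For small
  motion the error is second order (smooth sensitivities change little
  over a few mm), and the correction itself makes the same
  approximation implicitly. Large rotations would violate it.
* **No density compensation.** Small rotations leave the rotated
  Cartesian coordinates close to uniformly dense; gaps and overlaps in
  k-space are accepted as a known limitation of the approach, and
  reconstruction quality degrades gracefully with angle (a property the
  test suite checks at 0°, 0.5° and 2°).
* **No intra-shot motion,** no spin-history or eddy-current effects, no
  B0/B1 modelling: the piecewise-constant rigid model *is* the physics
  here.

## Conventions

Voxel coordinates are centred on the volume centre (index
$\lfloor n/2\rfloor$ in 0-based terms), so rotation about the image
centre is phase-free in k-space. Frequencies are carried in cycles per
sample ($\xi = k/n$, Nyquist box $|\xi| \le 1/2$); because image
support lies on the integer grid, frequencies are 1-periodic, which is
why rotated coordinates slightly outside the box may be wrapped without
approximation. Rotations are right-handed intrinsic x–y–z about the
volume centre, in degrees; translations in mm. The convention of the
registration tooling this emulates is not publicly specified, so the
package fixes its own and states it; only the 6-DOF rigid model itself
is load-bearing.

## The gridding NUFFT

No NUFFT implementation exists in the R ecosystem this package can
depend on, so the type-2/type-1 pair is implemented here: Kaiser–Bessel
gridding with 2× oversampling, kernel width chosen from the requested
tolerance (about one decimal digit per unit of width at this
oversampling; width 10 for the default `tol = 1e-7`), and the standard
minimum-aliasing shape parameter
$\beta = \pi\sqrt{w^2 \cdot 0.5625 - 0.8}$. Deapodization uses the
kernel's analytic Fourier transform
$w\,\sinh(\sqrt{\beta^2-(\pi w\nu)^2})/\sqrt{\beta^2-(\pi w\nu)^2}$.
Kernel values come from a dense lookup table of exact Bessel evaluations
(32768 nodes, linear interpolation), whose interpolation error sits well
below the kernel's own aliasing error. The type-1 transform is built as
the exact adjoint of the type-2 (same kernel weights, opposite FFT
sign), so the inner-product identity holds to rounding; the exported
`nufftAdjoint()` carries a $1/N$ scale so that full Cartesian sampling
reproduces the inverse FFT. Accuracy against the brute-force DFT sum is
checked in the tests at $10^{-6}$ relative with margin.

## The phantom and what it does not emulate

`makePhantom()` paints nested ellipsoidal compartments (GM, WM, a
ventricle) with 7T-like fixture relaxation times (WM T1 1200 ms, GM
2000 ms, CSF 4000 ms — fixture values, not claims), plus a scalp-fat
shell outside a one-voxel skull gap. Two generator choices matter:

* **The fat shell is irregular on purpose.** Its thickness
  (2.5 ± 1.5 voxels) and intensity carry a smooth seeded modulation. A
  uniform ellipsoidal shell is so close to rotationally symmetric that
  head rotations are nearly invisible at navigator resolution — the
  registration cost is flat along the symmetry directions and estimates
  become arbitrary. Real scalp fat is irregular, and that irregularity
  is precisely what makes FatNav rotation tracking work; the phantom
  has to reproduce it.
* **Navigator realism is opt-in.** `simulateFatNavs()` by default
  returns ideal band-limited fat images (clamped at zero — a magnitude
  image cannot be negative, and letting ringing of a strictly real
  zero-phase object fold through zero would be an artefact the complex
  phase of real data prevents). With `kspacePath = TRUE` it simulates
  the undersampled multi-channel acquisition (4×4-capable GRAPPA with a
  reference-pose calibration prescan, zero-filled 3/4 partial Fourier,
  RSS combination, and a smooth object phase standing in for B0). The
  residual GRAPPA aliasing of that path is locked to the *scanner*
  frame while the object moves, and measurably limits rotation recovery
  to roughly a quarter of a degree under 3 mm / 3° motion — a genuine
  property of image-based navigators, reported here rather than hidden.

What the phantom does not model: anatomy beyond nested ellipsoids,
susceptibility, chemical-shift displacement of fat, RF excitation
physics (the binomial fat excitation is modelled as "only fat produces
signal"), receive-field bias beyond what `makeCoils()`'s smooth
Gaussian-lobe sensitivities produce. Tests passing on this phantom show
the *machinery* is right — the exactness of the translation correction,
the adjointness of the transforms, the convergence of the registration —
not that in-vivo tissue would behave as well.

## Motion estimation

`estimateMotion()` registers every navigator to the reference volume
(the first, by default) by multi-resolution (3-level, 2× box-average
pyramid) Levenberg–Marquardt minimisation of the mean-squared intensity
difference under the 6-DOF rigid model with trilinear interpolation.
The metric is MSE rather than mutual information because the series is
same-modality by construction. The Jacobian is analytic (chain rule
through the resampled image gradient), iterations cap at 100 per level
and stop when the parameter update falls below $10^{-3}$ mm/degree;
translations are initialised from the centre-of-mass offset.

Two preprocessing steps proved essential and are defaults:

* **Gaussian smoothing (FWHM 1.5 navigator voxels).** The fat layer is
  one–two navigator voxels thin; unsmoothed, the metric is dominated by
  near-Nyquist content that trilinear interpolation cannot represent.
* **2× sinc upsampling before registration.** Navigator volumes are
  band-limited by their acquisition, so Fourier zero-padding is exact
  for them, and trilinear interpolation on the oversampled grid is far
  more accurate. Without this step, rotation estimates are biased low
  by tens of percent; with it, recovery on the ideal path reaches a few
  hundredths of a degree (the suite asserts the 0.2 mm / 0.2° median
  bound with a wide margin).

Degenerate registrations (empty or non-overlapping volumes) are flagged
as `NA` poses, and the corrector either borrows the nearest-in-time
pose (default) or drops the shot.

## GRAPPA

Calibration fits, for every missing-line offset of the
$R_y \times R_z$ cell, complex weights predicting each channel's target
sample from 2 acquired source positions per undersampled dimension × 3
readout positions across all channels, over every valid position of a
fully sampled central block, with Tikhonov regularisation
$\lambda = 10^{-4}\,\overline{\mathrm{diag}(A^{\mathsf H}A)}$. Kernel
geometry and regularisation are package choices (the published
protocols do not specify them). Reconstruction preserves acquired
samples bit-exactly and synthesises the rest; on noiseless 8-coil
phantom data at $R = 2$ the whole-volume NRMSE is under 2%, single-coil
data reconstruct much worse (parallel imaging needs coil diversity),
and error shrinks as the calibration block grows — all asserted in the
tests.

## MP2RAGE

The two-train cycle — inversion with efficiency $\eta$, relaxation,
$n$ pulses of $\alpha_1$ with echo-spacing relaxation, a gap, $n$
pulses of $\alpha_2$, relaxation to the next inversion — is affine in
$M_z$, so the periodic steady state is the exact fixed point of the
affine cycle map; fixed-point iteration is kept as a cross-check
(agreement to $10^{-9}$ is a test). Signals are read at the central
echo of each train (the k-space centre of a linearly ordered train; the
reference echo is a package choice). The defaults are TI 800/2700 ms,
flip angles 5°/7°, echo spacing 7.8 ms, 166 echoes per train (which is
what a 442-line PE dimension gives at 3/4 partial Fourier with 2×
GRAPPA), 6000 ms cycle, $\eta = 0.96$ — the inversion efficiency of the
actual adiabatic pulse is unknowable from published protocol tables, so
it is a parameter, not a constant.

The UNI combination
$\mathrm{Re}(S_1^{*}S_2)/(|S_1|^2+|S_2|^2) \in [-0.5, 0.5]$ is
invariant to any global complex scaling — the bias-free property — and
maps strictly monotonically to T1 over the physiological range with
these parameters (the lookup table is restricted to its largest strictly
monotonic branch, with a warning when the requested grid extends past
it, as it does below ~160 ms). `t1Map()` interpolates linearly and
counts clamped out-of-range voxels.

## Bias-field correction

`biasCorrect()` fits a smooth field to the voxels above a user-chosen
threshold — penalized least squares on the 3D cosine basis (a
diffusion-type smoother: spectral filter $1/(1+s\lambda^2)$ over the
DCT Laplacian eigenvalues), in the log domain since the field is
multiplicative, with Garcia-style bisquare reweighting so tissue
structure the field should not follow is downweighted — and divides the
volume by it, preserving the foreground mean. The smoothing parameter
$s$ comes from generalized cross-validation, *bounded below* so the
fitted field cannot vary on scales finer than `fieldScale` × FOV
(default: one FOV): unconstrained GCV happily models the anatomy
itself, whereas receive-coil bias varies on the scale of the coil
geometry. The bound trades a little shrinkage of genuine field
structure near the cutoff (which is why a second application can still
change a multi-tissue volume by a percent or two) against anatomy
leakage; on data the model describes well — a near-uniform foreground —
the operation is idempotent to well under 1%, and on a multi-tissue
phantom under a ±30% low-order field it cuts the within-tissue
coefficient of variation more than five-fold (both asserted in tests).

## PSF, effective resolution and scan economics

`psfProfile()` builds the centred 1D window of $n$ lines with the
asymmetric partial-Fourier mask (the unacquired lines are the extreme
negative frequencies; the centre is always acquired), zero-fills,
evaluates the complex PSF on a ≥64× zero-padded grid (FWHM convergence
under padding refinement is a test), and measures the FWHM of the
magnitude by linear interpolation of the half-maximum crossings.

One measurement deserves an honest flag. For a contiguous window of
$f\!\cdot\!n$ lines the transform is a phase ramp times a Dirichlet
kernel of width $f n$, so *every* magnitude-based width measure scales
by exactly $1/f$: at $f = 3/4$ the measured magnitude-PSF FWHM
broadening is exactly $4/3$ (+33%), and the real-part PSF (the edge
response of a real object on a background) broadens by ~19%. The figure
of ~15% often quoted for zero-filled 3/4 partial Fourier corresponds to
$1/\sqrt{f} = 1.1547$, which is not the FWHM of the zero-filled PSF
under any definition we could construct. This package reports the
measured quantity; `effectiveResolution()` multiplies the nominal
resolution by the measured broadening factor and rounds to 10 µm.

`voxelEconomics()` encodes the SNR arithmetic: voxel-volume ratio
$(a/b)^3$, and with SNR ∝ voxel volume × √(scan time), an SNR-matched
time ratio equal to its square — going from 500 µm to 350 µm costs ~2.9×
in voxel volume and ~8.5× in scan time.

Scan-time accounting mirrors the protocols: GRE host time is acquired
lines × TR and *pays* for its navigators (42 min with, 36 min without,
one navigator every 7.6 s); MP2RAGE (312 inversion cycles × 6 s ≈ 31
min) and TSE hide the navigator in sequence dead time, so it is free.
The navigator's own duration (1152 ms) and its 2.3 s calibration
prescan are stored constants of the navigator protocol — the duration
is not derivable from the navigator matrix and acceleration by any
simple composition, so the package does not pretend to derive it.

## Problem sizes and determinism

The test and demonstration problem sizes are chosen as the smallest
grids on which every mechanism is still exercised honestly: a 64³
phantom at 1 mm (a miniature head whose navigators then have the
method's native 2 mm voxels) for motion recovery and the
16-shot/8-coil correction experiment, 32³ grids for the k-space
round-trip and GRAPPA accuracy checks. Every stochastic input — phantom
texture, coil jitter, motion traces, noise — is a pure function of an
explicit integer seed, and the demonstration pipeline is bit-reproducible
from its configuration.

## Known limitations

* Rotation correction leaves uncompensated k-space gaps/overlaps (no
  density compensation, no sensitivity-informed reconstruction); error
  grows smoothly with angle and the small-motion regime (≤3°) is the
  validated envelope.
* The GRAPPA-path navigators carry scanner-frame-locked residual
  aliasing that limits rotational tracking precision (~0.25° median at
  the simulated artifact level); the ideal-path navigators do not.
* The bias-field smoother cannot separate anatomy from field at spatial
  scales where they overlap; `fieldScale` makes that prior explicit.
* TSE signal evolution along the train is available only as an optional
  amplitude weighting of the PSF window (`psfProfile(weights = ...)`),
  not as a Bloch simulation — tissue-dependent train blurring is
  acknowledged, unmodelled.
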