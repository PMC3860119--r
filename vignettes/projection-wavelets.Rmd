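---
title: "Projection-domain realization of 3D continuous wavelet transforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-domain realization of 3D continuous wavelet transforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomowave)
```

## The model

A mother wavelet in $n$ dimensions is a square-integrable $\psi$ whose
Fourier transform satisfies the admissibility condition
$\int |\hat\psi(\omega)|^2 |\omega|^{-n}\,d\omega < \infty$, which for
integrable $\psi$ forces zero mean. The continuous wavelet transform at a
single scale is the convolution $Wf = f \ast\ast\ast\, \psi_a$ with the
$L^2$-normalized family member $\psi_a(x) = a^{-n/2}\psi(x/a)$.

For parallel-beam geometry rotating about the $z$ axis, the X-ray
transform $P_\theta$ integrates along rays in direction
$\mathbf{w} = (-\sin\theta, \cos\theta, 0)$, recording detector
coordinates $(u, v)$ along $\mathbf{u} = (\cos\theta, \sin\theta, 0)$ and
$\mathbf{v} = (0,0,1)$. Two classical facts connect the domains:

* **Fourier slice theorem.** $F_2 P_\theta f(\omega_u, \omega_v) =
  F_3 f(\omega_u \mathbf{u} + \omega_v \mathbf{v})$: the 2D transform of
  a projection is a central plane of the 3D transform.
* **Projection–convolution identity.** $P_\theta(f \ast\ast\ast\, h) =
  P_\theta f \ast\ast\, P_\theta h$, an immediate corollary of the slice
  theorem.

Taking $h = \psi$ gives the method this package implements: the 3D
wavelet transform of a volume can be computed by 2D-convolving each
projection with the *projected wavelet at that projection's own angle*
and inverting the filtered stack with filtered backprojection (FBP). For
noisy CT data this order of operations is attractive because the wavelet
filtering happens before reconstruction can correlate the noise, and
because per-angle 2D convolutions are much cheaper than one 3D
convolution (see *Operation counting* below).

The workhorse wavelets are the first derivatives of the isotropic
Gaussian $g = e^{-|x|^2/2\sigma^2}$: $\psi_1 = \partial_x g$,
$\psi_2 = \partial_y g$ (and $\psi_3 = \partial_z g$ for volume-domain
use). Their projections have closed forms
$P_\theta\psi_1 = -\kappa\,(u/\sigma^2) e^{-(u^2+v^2)/2\sigma^2}
\cos\theta$ (with $\sin\theta$ for $\psi_2$), making the pair an
angle-matched 2D gradient filter. The 3D Mexican hat $-\Delta g$ projects
to the 2D Mexican hat times $\kappa$, with no direction factor.

**Exact constants.** The line integral of a unit Gaussian contributes
$\kappa = \sigma\sqrt{2\pi}$. Constant-free treatments drop this factor
(and the $2\pi$ factors between spatial and Fourier forms); we keep every
constant exact so that numeric and analytic projections agree to
interpolation error, and expose `kappa` as a constructor argument so the
constant-free normalization is available for cross-checking closed-form
certificate values (e.g. `projected_psi1(1, kappa = 1/(2*pi))` makes the
2D Fourier form exactly $j\omega_u e^{-\rho^2/2}\cos\theta$, whose
admissibility integral is $(\pi/2)\cos^2\theta$ and whose uniform bound
attains $\sqrt{\pi}e^{-1} \approx 0.652$; our certificates reproduce both
from quadrature, and we trust these oracle values over any printed
constants we could not reproduce by direct integration).

**Fourier convention.** Non-unitary with angular frequency,
$\hat f(\omega) = \int f(x) e^{-j\omega\cdot x}dx$, throughout. Under it
Parseval reads $\|f\|_2 = (2\pi)^{-n/2}\|\hat f\|_2$, which
`parseval_check()` verifies to float precision on rasters.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `sigma` | wavelet width, world units | 1 (wavelets); 2 voxels (edge detectors) | smallest width whose raster is well resolved; two voxels matches the detectors' single-voxel localization goal |
| `a` | wavelet scale | 1 | single-scale transform; multi-scale = loop over `a` |
| `trunc_mult` | kernel truncation radius in units of `sigma * a` | 4 | $e^{-8} \approx 3\times10^{-4}$ of peak; kernels stay odd-sized with the center tap on the grid |
| `angles` | projection angles | caller-chosen | FBP quality grows with angle count; the method itself does not fix it, so it is a parameter and reported with results |
| `quantile` | edge threshold on the modulus | 0.90 | relative thresholds make edge maps invariant to positive rescaling of the input |
| noise `variance` | projection-noise level | 0.1 | the study condition for the noise experiment (phantom densities are O(1)) |

## What the phantoms emulate

`make_shepp_logan_3d()` rasterizes the standard 10-ellipsoid head phantom
(the widely published 3D extension with the high-contrast densities;
rotations restricted to the z axis, consistent with the package's
rotation-about-z geometry) on a centered grid in $[-1,1]^3$. Every
ellipsoid also has an exact analytic projection (chord length × density),
so the numeric projector can be validated against closed forms at any
angle. Gaussian blobs provide a second family whose projections *and*
wavelet transforms are closed-form, exercising the whole pipeline
analytically.

What they do not emulate: anatomy, beam physics (polychromaticity,
scatter), detector blur, and non-Gaussian noise. Passing tests therefore
demonstrate the correctness of the transform/projection machinery and the
ordering claims about noise handling under ideal Gaussian projection
noise — not clinical performance.

Noise is added to projections (the processing-order experiment is about
projection-domain filtering); `add_gaussian_noise()` also accepts volumes
for the comparison arm. All noise is seeded and bit-reproducible.

## Numerical choices

* **Projector.** The volume is resampled into the rotated frame
  slice-by-slice (the detector $v$ axis coincides with $z$, so each $v$
  row is a 2D Radon projection of a z-slice) and summed along the ray
  with step equal to the voxel spacing. In-plane resampling uses Keys
  cubic-convolution interpolation by default: with bilinear resampling
  the numeric projection of a rasterized wavelet differs from its closed
  form by $\sim1.5\times10^{-3}$ of peak at oblique angles on a $129^3$
  grid, while the cubic scheme reaches $\sim7\times10^{-6}$ — the
  closed-form agreement this package treats as its primary correctness
  oracle. `interp = "linear"` remains available. Outside the grid the
  volume is zero (all phantoms vanish at the boundary by construction).
* **FBP.** Ram-Lak ramp filter in the frequency domain (DC term zero,
  optional Hann window), per-slice backprojection with linear
  interpolation, angles assumed approximately uniform over $[0,\pi)$ or
  $[0,2\pi)$. On smooth phantoms the projector/FBP round trip is accurate
  to $\approx 4\%$ relative $L^2$ at $64^3$/120 angles; on the
  discontinuous head phantom the round-trip error is Gibbs-limited
  ($\approx 0.27$ at $64^3$, matching reference implementations at the
  same resolution) and decreases with grid refinement.
* **Slice-theorem verifier.** Both sides are computed with a
  phase-corrected, $\Delta^d$-scaled DFT (a consistent approximation of
  the continuous transform on centered grids; even-length axes need the
  query points recentered because the DFT frequency axis carries an
  unpaired negative Nyquist bin). The volume's spectrum is interpolated
  onto the slice plane bicubically after $2\times$ centered zero-padding:
  padding refines the frequency grid, which dominates the error for
  slowly decaying spectra.
* **Convolutions.** Zero-padded FFT products cropped to "same" size —
  true convolution (the FFT product is the flipped-kernel sum), which
  matters for odd kernels like $\psi_1$ that correlation would negate.
  2D/3D results are multiplied by the detector-cell area / voxel volume
  so the continuous identities hold without hidden constants. Kernels are
  odd-sized with the center tap at the origin; convolving two whole
  volumes on an even centered grid lands half a sample off-grid and is
  brought back by a band-limited Fourier half-sample shift.
* **Scale normalization across routes.** The projection of the 3D family
  member $a^{-3/2}\psi(x/a)$ scales as $a^{-1/2}P\psi((u,v)/a)$, not as
  the intrinsic 2D family's $a^{-1}$; `rasterize_projected2d()` exposes
  both (`norm = "xray"` vs `"family"`), and the projection route uses
  `"xray"` so both routes target the same continuous object
  $f \ast\ast\ast\, \psi_a$.
* **Certificates.** "Finite" for improper integrals is operationalized as
  quadrature convergence: the estimate at doubled radial resolution and
  doubled domain radius must agree within 1% (log-divergent integrands
  such as the plain Gaussian's fail this gate, as they must). The
  supremum in the uniform bound is taken over a $360 \times 201$
  $(\theta, \omega_u)$ grid and documented as an approximation of the
  max. Symmetry-forced zeros are tested at $10^{-8}$ relative; zero-mean
  quadratures integrate over $1.5\times$ the nominal support so
  truncation tails of polynomially weighted Gaussians stay below that
  tolerance.
* **Edge detection.** Modulus $\sqrt{W_1^2 + W_2^2}$ of the in-plane
  derivative pair, direction-quantized 8-neighbor non-maximum suppression
  (strict inequality against both neighbors; ties suppressed), quantile
  threshold. A border of one kernel half-width is excluded: there the
  zero-padded convolution is not valid and even a constant input would
  respond. A modulus floor of $10^{-8}\times\max|f|$ keeps pure
  floating-point noise from surviving the relative threshold on
  degenerate (constant) inputs. The wavelet pair spans only the in-plane
  derivatives: the rotation-about-$z$ geometry transports exactly these
  two through the projection identity, so using the same pair in the
  volume route keeps the two routes comparable; an optional
  $\partial_z g$ channel exists for the direct route and is off by
  default.

## Operation counting

The direct 3D route costs $O(S N^2 M^3)$ multiply–adds ($S$ slices of an
$N\times N$ image, kernel size $M$) versus $O(N^2 M(M+1))$ per angle for
the 2D route. The package evaluates convolutions by FFT for speed, and
the counters attached to `cwt3d()`/`cwt2d()` record the tap count of the
direct sliding-window scheme (output size × kernel taps), which is the
cost model under which the two routes are compared;
`complexity_report()` checks the measured ratio against
$S M^3 / (M(M+1))$. Across $M \in \{5, 9, 13\}$ the recorded counts scale
with log-log slopes 3 and 2 exactly.

## Problem sizes

The validation suite uses $129^3$ rasters (extent $\pm 6\sigma$) for the
closed-form projection oracle, $64^3$ phantoms with 180 angles for the
route-agreement and edge-map comparisons, $64^3$ with 90 angles and 10
seeded replicates for the noise experiment, and $32^3$–$48^3$ grids for
unit-level properties. These sizes were chosen so the full suite runs on
a laptop-class single core in a few minutes while keeping every tolerance
meaningfully tight; all scale parameters are arguments, so larger studies
are one call away.

## Known limitations

* Rotation about $z$ only; no cone-beam or helical geometry, no
  iterative reconstruction.
* No inverse wavelet transform (reconstruction of $f$ from its transform
  coefficients); the package computes single-scale forward transforms,
  multi-scale being a loop over scales.
* The projection route's accuracy is FBP-limited: with few angles the
  realized transform degrades gracefully but measurably; angle count is
  therefore always an explicit parameter.
* TIFF output stores normalized 32-bit samples with the affine rescale
  recorded in the JSON sidecar; use the raw float32 format where bitwise
  exactness matters.
* The per-slice 2D baseline detector is a plain derivative-of-Gaussian
  modulus-maxima scheme — a reference point, not a tuned competitor.
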