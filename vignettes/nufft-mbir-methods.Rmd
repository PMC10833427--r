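---
title: "NUFFT-based model-based iterative reconstruction: models, parameters, and design notes"
author: "nufftTomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NUFFT-based MBIR: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nufftTomo)
```

## The reconstruction problem

Parallel-beam tomography measures line integrals of a sample's attenuation
density $f$: for beam direction $\theta$ and signed detector coordinate $t$,

$$ (Rf)(\theta, t) \;=\; \int f\big(t\cos\theta - s\sin\theta,\;
   t\sin\theta + s\cos\theta\big)\, \mathrm{d}s . $$

The central slice theorem identifies the 1-D Fourier transform of a
projection with a radial line of the 2-D Fourier transform of $f$. Both the
forward operator $R$ and its adjoint $R^\dagger$ (unfiltered
back-projection) therefore reduce to resampling between a Cartesian grid
and a polar grid in frequency space. This package performs that resampling
with a non-uniform FFT (NUFFT): per slice,

* **forward**: deapodize, zero-pad to a 2x oversampled fine grid, 2-D FFT,
  kernel-weighted interpolation at the polar frequencies, then a 1-D
  inverse FFT along each radial line (with the rotation-center phase ramp);
* **adjoint**: exactly the transposes of those steps in reverse order.

Because the adjoint is built as the literal transpose of the forward
factorization, the dot-product identity
$\langle Rf, g\rangle = \langle f, R^\dagger g\rangle$ holds to machine
precision, independent of the kernel accuracy — the kernel accuracy only
controls how well both operators approximate the ideal Radon pair.

### Spreading kernel and accuracy

The gridding kernel is the exponential-of-semicircle profile
$\phi(s) = \exp\!\big(\beta(\sqrt{1-(2s/w)^2}-1)\big)$ with shape
$\beta = 2.3\,w$ at 2x oversampling. The per-dimension support $w$ follows
the accuracy rule `kernelWidth(eps)` $= \lceil \log_{10}(1/\varepsilon)
\rceil + 1$; measured end-to-end errors against a direct $O(NM)$ DFT sum
track the requested tolerance ($1.2\times10^{-6}$ at
$\varepsilon = 10^{-6}$; $2\times10^{-12}$ at $\varepsilon = 10^{-12}$ on
$32^2$ grids). The deapodization profile is the kernel's continuous
Fourier transform evaluated by Gauss–Legendre quadrature after the
substitution $s = (w/2)\sin u$, which removes the square-root endpoint
behavior and is exact to machine precision at 80 nodes. Configuration
exposes the tolerance $\varepsilon$, not $w$: the accuracy contract is
normative, the kernel identity is not.

Conventions, chosen once and used consistently by both operators so the
adjoint identity closes:

* angles in radians; degree conversion happens only at the I/O boundary;
* 0-based pixel coordinates with the image origin and detector midpoint at
  $(n-1)/2$; the fractional half-pixel of even grids is carried by a phase
  factor on the polar samples, while the integer part of the centering is
  an index shift on the fine grid (keeping the deapodization profile
  well-conditioned);
* the rotation-center offset enters as a linear phase ramp on each radial
  line (Fourier shift), both in the operators and in `centerCorrect`;
* one radial DFT bin per detector column by default (`radialCount =
  numColumns`); no circular mask inside the operators.

### Filtered back-projection

`fbpReconstruct` applies an apodized $|k|$ density weighting on each
radial line and back-projects through the NUFFT adjoint, scaled by the
angular density factor $\pi/n_\mathrm{angles}$ so dense-angle
reconstructions recover absolute density. Detector rows are zero-padded to
twice the detector width before the radial FFT: without padding, the
implicit circular convolution of the discretely sampled ramp produces the
classic low-frequency "cupping" deficit (measured: a dense-angle Gaussian
phantom reconstructs at 97% of its true amplitude unpadded versus 99.3%
with 2x padding; the padding factor is exposed). Filters: Ram-Lak $|k|$,
Shepp-Logan $|k|\,\mathrm{sinc}(k)$, Butterworth
$|k|/(1+(k/k_c)^{2m})$, or none.

## The MBIR objective

Reconstruction solves

$$ \min_f \; \tfrac12 \lVert Rf - b\rVert_2^2 \;+\;
   \sum_m \sum_{n \in N(m)} w_{mn}\, \rho(f_m - f_n), \qquad
   \rho(\Delta) = \frac{|\Delta/\sigma|^2}{c + |\Delta/\sigma|^{2-p}} , $$

a q-generalized Gaussian Markov random field (qGGMRF) penalty over the
26-neighbor 1-hop 3-D neighborhood with partition-of-unity weights
$w_{mn} \propto 1/\lVert m - n\rVert$ (face weight
$1/(6 + 12/\sqrt2 + 8/\sqrt3) \approx 0.05234$). The potential is
quadratic (amplified by $1/c$) for differences far below the transition
scale and grows like $|\Delta/\sigma|^p$ above it, which preserves edges.

Parameter guidance (units of $\sigma$ are voxel-value units, i.e. the
same units as the reconstructed density):

* $p = 1.2$ and $c = 10^{-4}$ are robust defaults across datasets and are
  not usually worth re-tuning;
* $\sigma$ sets the regularization strength: smaller $\sigma$ smooths
  more. `sweepSigma` reconstructs a small slice subset over a grid of
  $\sigma$ values, mirroring the usual survey practice. For synthetic
  studies the package selects the $\sigma$ minimizing affine-matched rRMSE
  against the known phantom; on real data the choice is the user's (the
  reference workflow relies on expert inspection). The default sweep grid
  spans material density $\times\ \{0.25, 0.5, 1, 2, 4\}$ — on the foam
  benchmark the selection lands at the top of this grid (4x density),
  which is a known limitation of a fixed grid; extend the grid when the
  selected value is a boundary point.
* the penalty is differentiated exactly (no surrogate); boundary voxels
  simply skip out-of-range neighbors without weight renormalization, so a
  single-slice volume degrades to the 8-neighbor 2-D prior.

### Solver

The objective is minimized by a Nesterov-accelerated gradient method with
function-value restart and a monotone safeguard:

* gradient $R^\dagger(Ry - b) + \nabla h(y)$ at the extrapolated point;
* if the accelerated candidate raises the objective, it is discarded and
  the momentum reset (restart);
* if a plain gradient step from the current iterate overshoots, the step
  is halved on the same gradient until the objective decreases
  (backtracking inside the iteration).

The default step is $0.9/\hat L$ with $\hat L$ a 20-iteration seeded power
estimate of $\lVert R^\dagger R\rVert$ (Rayleigh quotient; within 5% of a
dense-SVD reference on small instances). This deliberately ignores the
prior's curvature, which near-constant regions amplify by $1/c$: the
backtracking absorbs the mismatch and, empirically, the step settles at
what the local curvature permits. An earlier variant that re-grew the step
after sustained accepts was rejected — it repeatedly re-entered the
overshoot regime and slowed convergence. The objective trace is
non-increasing by construction when `monotone = TRUE`; traces of the total
objective and of the data term are both recorded, since "error versus
iterations" is ambiguous between the two.

Initialization defaults to the zero volume (an FBP initialization is
available); the stop tolerance defaults to 0, i.e. a fixed iteration
budget, matching the usual fixed-100-iteration evaluation protocol. No
non-negativity constraint is applied by default.

## Hierarchical (coarse-to-fine) mode

`hierarchicalReconstruct` solves a detector-downsampled problem first
(block-averaged columns; the rotation center scales with the factor),
upsamples the solution bilinearly (center-aligned, with linear edge
extrapolation so affine profiles are reproduced exactly), and warm-starts
the next level; the default schedule is 60 iterations at quarter
resolution, 30 at half, 15 at full. Two details make levels consistent:

* coarse attenuation data are divided by the downsampling factor so every
  level reconstructs the same physical density (line integrals are
  measured in pixel units, and a coarse pixel is `factor` fine pixels
  long);
* with block-averaged columns the detector midpoint maps exactly onto the
  coarse midpoint, so no inter-level half-pixel shift arises (verified
  algebraically and by the single-level-identity test).

$\sigma$ is kept constant across levels by default (per-level multipliers
are available); the per-level $\sigma$ actually used is echoed in the
result. On the 64-wide foam benchmark below, the schedule reaches a final
total objective within about 4% of a 100-iteration full-resolution run
while spending only 15 full-resolution iterations; the residual gap is
highest-octave detail that coarse levels cannot represent, and it grows
when regularization is weakened (the sweep-selected $\sigma$ is the
operating point).

## Synthetic data

`makeFoam` emulates foam-like specimens: a cylinder of radius
$0.45\times$ grid side, density `materialDensity`, carved by
non-overlapping spherical voids placed by seeded rejection sampling
(uniform centers in the cylinder, log-uniform radii, at most $10^4$
attempts per void; fewer voids than requested is allowed and reported).
Defaults target the dense polydisperse bubble texture of real foams:
about `gridSide^2/400` voids with radii between 0.4% and 4% of the grid
side, saturating near 34% porosity. `simulateAcquisition` forward-projects
the phantom, applies the rotation-center offset as a sub-pixel Fourier
shift, and converts to transmitted intensity $I = I_0 e^{-b}$ with
optional Poisson counting noise (normal approximation above $10^8$
expected counts, where integer Poisson sampling overflows).

What the generator does *not* emulate: beam hardening, ring artifacts,
detector point-spread, partial-volume edges (voids are carved binarily),
scatter, or the reference foam generator's exact random stream. Passing
tests on this generator therefore validate the operators, objective,
solver and metrics — not robustness to those physical effects.

### The reference benchmark (`foamStudy`)

The packaged evaluation protocol fixes, once:

* detector width 512 (a desk-scale stand-in for 2048), 4 slices;
* 16:1 column-to-view undersampling (32 views over $\pi$ at width 512;
  128 views at width 2048), the sparse-view regime the comparison probes;
* attenuation per voxel $6/\mathrm{gridSide}$, making the peak optical
  depth $\approx 3$–4 — a transmission of a few percent, typical of
  synchrotron micro-CT;
* flux $10^4$ photons per detector pixel, Poisson noise, 3 seeds;
* FBP with Butterworth order 2, cutoff 0.25; MBIR with $p = 1.2$,
  $c = 10^{-4}$, 100 iterations, $\sigma$ from a 60-iteration
  single-slice sweep on the first seed;
* scoring by affine-matched relative RMSE
  ($\lVert sB + \Delta - A\rVert_2 / \lVert A\rVert_2$, least-squares
  $s, \Delta$) inside the inscribed circle.

Typical output at these conditions: FBP $\approx 0.53$, MBIR
$\approx 0.49$, with MBIR strictly better on every seed. Two caveats are
documented rather than hidden. First, the rRMSE normalizer
($\lVert A\rVert_2$ over the masked region) is one of several defensible
conventions; it is fixed here so all reported numbers are mutually
consistent. Second, a width-512 phantom cannot carry bubble detail that
is sub-pixel at this scale, so the FBP error is structurally lower than
the same experiment at width 2048; the MBIR-versus-FBP ordering and the
MBIR error level are the scale-stable quantities.

## Numerical choices and degenerate inputs

* NUFFT tolerance default $10^{-6}$ (width-7 kernel), oversampling 2.
* Even-size grids: frequency bins $m' \in [-M_t/2, M_t/2)$; the unpaired
  Nyquist bin is self-consistent under the real-part projection, and a
  fractional Fourier shift attenuates it by $\cos(\pi\delta)$ (the
  standard real-valued fractional delay).
* `radonOracle` (dense-ray bilinear quadrature, step 0.25 px) and
  `dftOracle` (direct $O(NM)$ sum) are deliberately slow, guarded
  reference implementations used by the test suite; they share no code
  with the NUFFT path.
* Degenerate inputs: constructing any object with violated invariants
  errors before computation; a constant candidate image makes the affine
  match (and rRMSE) undefined and errors; zero-norm references error;
  non-finite objectives abort the solver with the iteration index.
* All randomness (phantom, noise, power iteration) flows through explicit
  seeds with save/restore of the global RNG state; identical calls are
  bit-identical.

## Problem sizes used by the packaged checks

The test suite exercises operators at grid sides 12–64 against the
brute-force oracles, the solver at 16–64, and the full benchmark at
width 512 with 3 seeds (the acceptance script repeats the width-512
benchmark from scratch). These sizes were chosen so the whole suite is a
matter of minutes on a single core while every contract is still
exercised at a nontrivial scale.

## Known limitations

* The operators assume parallel-beam geometry; cone/fan beam and
  laminography tilt are out of scope, as are GPU execution paths.
* The sweep grid for $\sigma$ is fixed and coarse; boundary selections
  should prompt a wider grid.
* `writeVolume`'s TIFF path stores samples normalized to $[0,1]$ (32-bit
  fixed point) with the affine restore parameters in a JSON sidecar —
  standard viewers see a correctly scaled image, but round-tripping the
  absolute scale requires the sidecar.
* HDF5 I/O shells out to the system Python's `h5py`; without a Python
  interpreter on the PATH only the TIFF path is available.
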