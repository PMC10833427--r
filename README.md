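# nufftTomo

Model-based iterative reconstruction (MBIR) for parallel-beam X-ray
tomography, built on non-uniform FFT (NUFFT) Radon operators — in R.

Sparse-angle and low-dose synchrotron micro-CT data defeat filtered
back-projection (FBP): with far fewer views than detector columns the
reconstructions are dominated by streaks and noise. MBIR instead solves

    minimize over f:   1/2 || R f - b ||^2  +  sum_{m,n} w_mn rho(f_m - f_n)

where `R` is the Radon transform of the density volume `f`, `b` the
measured attenuation sinogram (`b = -ln(I/I0)`, Beer–Lambert), and `rho`
the edge-preserving qGGMRF potential
`rho(D) = |D/sigma|^2 / (c + |D/sigma|^(2-p))` over the 26-neighbor 3-D
neighborhood (weights proportional to 1/distance, summing to 1). Both `R`
and its adjoint are evaluated through the central slice theorem with a
gridding NUFFT (exponential-of-semicircle kernel, 2x oversampled FFT,
deapodization), so each application costs FFT time rather than `O(N M)`.
The objective is minimized by a monotone Nesterov-accelerated gradient
method with restart and backtracking; a coarse-to-fine hierarchical mode
warm-starts full resolution from downsampled solves. The package also
provides FBP baselines (Ram-Lak / Shepp-Logan / Butterworth filters),
rotation-center correction by Fourier shift, a synthetic foam-phantom and
noisy-acquisition simulator, affine-matched relative-RMSE metrics,
TIFF/data-exchange-HDF5 I/O and a command-line front-end.

Audience: beamline scientists and imaging methodologists who want an
inspectable, single-machine reference implementation of NUFFT-based MBIR,
plus a reproducible synthetic benchmark comparing it against FBP.

## Worked example

Simulate a sparse-view noisy acquisition of a foam specimen and compare
FBP with MBIR:

```r
library(nufftTomo)

n <- 256L
spec <- foamSpec(n, numSlices = 1L, materialDensity = 6 / n, seed = 7L)
vol  <- makeFoam(spec)                       # cylinder with spherical voids

acq <- acquisitionSpec(numAngles = 16L, flux = 1e4, seed = 8L)
sim <- simulateAcquisition(vol, acq)         # I, I0 and the clean sinogram
b   <- beerLambert(sim$intensity, sim$flat, geom = geometry(sim$clean))

fbp  <- fbpReconstruct(b, filter = filterSpec("butterworth", 2, 0.25))
plan <- operatorPlan(geometry(b))
mbir <- solveMBIR(b, plan, qggmrfParams(sigma = 4 * 6 / n),
                  solverConfig(maxIterations = 100L, seed = 1L))

mask <- circularMask(n)
cat(sprintf("FBP  rRMSE: %.3f\n", relativeRmse(vol, fbp, mask)))
cat(sprintf("MBIR rRMSE: %.3f\n", relativeRmse(vol, reconVolume(mbir), mask)))
```

This prints

```
FBP  rRMSE: 0.450
MBIR rRMSE: 0.346
```

the affine-matched relative root-mean-square error of each reconstruction
against the ground-truth phantom inside the inscribed circle (after
least-squares intensity matching, so only structure — not absolute scale —
is compared). With only 16 views over 180 degrees and Poisson noise at
10^4 photons/pixel, the Butterworth-filtered FBP is dominated by streaks
and noise, while the qGGMRF prior suppresses both; `objectiveTrace(mbir)`
holds the (non-increasing) objective per iteration.

The same pipeline is scriptable from a shell:

```sh
inst/cli/tomo phantom --grid 256 --voids 160 --angles 16 --seed 7 \
    -o foam.h5 --truth truth.tiff
inst/cli/tomo mbir --in foam.h5 --sigma 0.094 --iterations 100 -o rec.tiff
inst/cli/tomo compare --ref truth.tiff --in rec.tiff
```

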