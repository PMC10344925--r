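# aoclass

Label-free adaptive-optics SMLM, end to end and fully simulated.

Deep-tissue single-molecule localization microscopy (SMLM) fails primarily
because tissue-induced pupil aberrations blur each molecule's point spread
function below the detection threshold: the localization *number* collapses
(by an order of magnitude or more), and the precision of what survives
degrades. `aoclass` implements the computational core of a label-free fix:
measure the aberration from coherent *reflectance* of the tissue itself —
no fluorophore photons spent, no guide star — and apply the opposite phase
in the emission path.

The package is aimed at microscopy-methods developers who want a testable,
instrument-free implementation of the full chain:

* **CLASS** (closed-loop accumulation of single scattering): given a
  reflection matrix `R(k_out, k_in)` built from fields recorded under many
  tilted illuminations, the single-scattering model factors each column as
  `R(k_o, j) = O(k_o − k_i,j) · exp(iφ_in(k_i,j)) · exp(iφ_out(k_o))`.
  Re-indexing to the difference frequency `Δk = k_o − k_i` and accumulating
  columns coherently, the iteration alternates closed-form phase updates
  (per-angle, then per-output-pixel, each the argument of an inner product
  against the accumulated spectrum `O_est`) that maximize
  `Σ|O_est(Δk)|²`. Recovered phases are reported modulo the piston/tip/tilt
  gauge, which trades against object position.
* A **scalar Fourier-optics** forward model: pupil-phase PSFs, Strehl
  ratios, tilted-illumination reflectance fields, off-axis interferogram
  synthesis/demodulation, Zernike analysis (Noll indexing, unit-RMS modes).
* A **dual-channel SMLM simulator**: blinking kinetics (two-state Markov,
  per-burst exponential brightness), EMCCD noise chain (Poisson → gamma EM
  gain → read noise), matched AO-off/AO-on channels from one ground truth.
* A **ThunderSTORM-dialect localizer** (DoG detection, Levenberg–Marquardt
  Gaussian fits, bit-exact CSV header compatibility).
* The **quantitative metrics** used to score correction: nearest-neighbor
  precision via the two-term displacement model
  `p(d) = A₁·d/(2σ²)·exp(−d²/4σ²) + A₂·(2πω²)^(−1/2)·exp(−(d−d_C)²/2ω²)`
  (σ is THE localization precision), Fourier ring correlation (odd/even
  split, 1/7 threshold), ensemble-PSF FWHM, localization-number ratios and
  the 2-D Nyquist scaling `resolution ∝ density^(−1/2)`.

## Worked example

Recover a strong, high-order aberration from a synthetic angle scan and
check the correction it implies:

```r
library(aoclass)

grid  <- makePupilGrid(128, 130, 678, 1.2)      # 1.2 NA, 678 nm, 130 nm px
truth <- randomAberration(2.5, grid, modeRange = 5:100, seed = 11)
rmsWavefront(truth$phase)
#> [1] 2.5

ks     <- spiralAngles(grid, 200)               # golden-spiral angle scan
obj    <- pointScatterPhantom(grid, 50, seed = 4)
fields <- simulateAngleScan(obj, ks, truth$phase, truth$phase)
res    <- classIterate(buildReflectionMatrix(fields, ks, grid))
res
#> ClassResult: 4 iterations, converged: TRUE
#>   intensity gain 2.73e+03 -> 1.81e+05

phaseResidualRms(phaseOut(res), truth$phase)    # rad, after gauge removal
#> [1] 0.0002779
```

The recovered map cancels a 2.5 rad RMS aberration — about 2.5× beyond the
~1 rad ceiling of image-metric AO — to a residual of ~3×10⁻⁴ rad.
`correctionMap(res)` is its negative, exportable as float TIFF/PNG.

The full pipeline (reflection scan → CLASS → correction → dual-channel
blinking movie → localization → metrics) is one call:

```r
rep <- fullDemo(defaultConfig(masterSeed = 1))
rep$localizationNumber$ratio   # corrected / uncorrected accepted fits
#> [1] 65.52087
c(rep$sigmaOffNm, rep$sigmaOnNm)   # NN-fit localization precision, nm
#> [1] 28.046617  6.323726
c(rep$fwhmOffNm, rep$fwhmOnNm)     # ensemble-PSF FWHM, nm
#> [1] 443.9336 320.7699
c(rep$frcOffNm, rep$frcOnNm)       # FRC resolution, nm
#> [1] 163.71436  17.49428
```

Correction multiplies the accepted-localization count (here ~66×, i.e. a
√66 ≈ 8.1-fold Nyquist-resolution gain), tightens the precision ~4.4×, and
improves the FRC resolution ~9×; exact values vary with the master seed.

A thin CLI over the same functions lives at `inst/scripts/aosmlm.R`
(`simulate-reflection`, `run-class`, `full-demo`, `localize`, `analyze`).

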