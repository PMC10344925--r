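---
title: "Reflection-matrix adaptive optics for SMLM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reflection-matrix adaptive optics for SMLM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoclass)
```

# The problem

Single-molecule localization microscopy (SMLM) reconstructs super-resolved
images from the fitted centroids of stochastically blinking fluorophores.
Deep inside tissue, refractive-index inhomogeneities impose a pupil-plane
phase aberration $\varphi(\mathbf{k})$ on the emission path. The blurred
point spread function (PSF) spreads each molecule's photons over many camera
pixels, so most emission events drop below the detection threshold: the
dominant failure mode is a collapse of the *localization number*, with a
secondary degradation of the localization precision of whatever survives.

Correcting the aberration requires measuring it first, and doing so without
spending the fluorophores' photon budget. The approach implemented here is
label-free: a coherent reflection-mode measurement of the same tissue at a
wavelength near the emission band yields the aberration, whose opposite
phase is then applied in the emission path (in hardware, by a spatial light
modulator; in this package, by adding the correction to the simulated
pupil).

# The reflection matrix and CLASS

The aberration solver operates on the *reflection matrix*
$R(\mathbf{k}_o, \mathbf{k}_i)$: complex reflected fields (rows: output
spatial-frequency pixels inside the objective aperture) recorded under many
tilted plane-wave illuminations (columns). Under the single-scattering
model, each column factors as

$$R(\mathbf{k}_o, j) =
  O(\mathbf{k}_o - \mathbf{k}_{i,j})\,
  e^{i\varphi_{\mathrm{in}}(\mathbf{k}_{i,j})}\,
  e^{i\varphi_{\mathrm{out}}(\mathbf{k}_o)},$$

where $O$ is the object's scattering spectrum. Re-indexing every column to
the difference frequency $\Delta\mathbf{k} = \mathbf{k}_o - \mathbf{k}_i$
makes the object term identical across columns; summing columns coherently
(*closed-loop accumulation of single scattering*, CLASS) amplifies the
single-scattered signal only insofar as the two phase factors are
compensated. The iteration alternates closed-form updates that each
maximize the accumulated intensity $\sum_{\Delta\mathbf{k}}|O_{\rm est}|^2$:

* **input step** — for each angle $j$, rotate the column by
  $-\arg\langle C_j, O_{\rm est}\rangle$ (the column's global phase
  misalignment against the current accumulation);
* **output step** — for each output pixel $\mathbf{k}_o$, rotate the row
  entries by $-\arg\langle C(\mathbf{k}_o,\cdot), O_{\rm est}\rangle$
  evaluated at the matching difference frequencies.

Both updates are unit-modulus phase rotations; amplitudes are never
modified. The inner products are amplitude-weighted by default (strong
spectral components dominate the estimate, which is what makes the solver
robust to noise); `weighting = "equal"` switches to pure phasor
correlation, and `leaveOneOut = TRUE` excludes the updated column from its
own reference. On the package's phantoms all variants converge to the same
fixed point; include-self amplitude weighting is the default because it is
the fastest and most noise-robust.

Convergence is declared when the relative intensity gain drops below
`relTol` ($10^{-4}$ by default) with a `maxIter` cap of 30; fixtures
converge in 4–7 iterations. Non-convergence flags the result instead of
raising.

**Gauge freedom.** Piston, tip and tilt of either pupil phase trade against
a global phase and a lateral shift of $O$: they are unobservable. All
recovered phases are therefore reported with piston/tip/tilt removed, and
`phaseResidualRms()` compares phases modulo these gauges *and* modulo
$2\pi$ (the residual is computed on $e^{i\Delta\varphi}$, so strong
aberrations whose unwrapped estimate carries $2\pi$ ambiguities compare
correctly).

Only $\varphi_{\mathrm{out}}$ feeds the correction map
(`correctionMap()` returns $-\hat\varphi_{\mathrm{out}}$, optionally
combined with a pre-measured system aberration): the instrument corrects
the emission path only, and the input phase is sampled just at the discrete
illumination angles (it is reported via nearest-angle interpolation, for
inspection only).

## Angle sampling and grids

Illumination angles follow a Vogel (golden-angle) spiral covering 90% of
the aperture radius — uniform disk coverage at any angle count. The desk
default is 200 angles on a 128-pixel grid (130 nm pitch, NA 1.2, 678 nm),
for which one recovery takes about a second; the instrument-scale 4000
angles is a configuration flag away but not the default. The
difference-frequency grid must span twice the aperture diameter, which
bounds the usable aperture at a quarter of the grid; the constructors
enforce this.

## Isoplanatic patches

`subareaClass()` recovers spatially varying aberrations patch by patch:
fields are windowed with a Tukey (taper 0.2) apodization, re-sampled onto
the patch's own coarser frequency grid (fractional illumination
wavevectors are demodulated to the nearest integer first), and iterated
independently. The flat-topped window matters: the window kernel convolves
the output-pupil phase factor, and a wide kernel (full Hann) visibly
biases the recovered phase. Residuals of ~0.1 rad per patch are typical at
desk scale for moderate (≈1 rad, ≤20-mode) per-patch aberrations; stronger
or higher-order per-patch aberrations degrade gracefully toward ~0.3 rad.

# Wave-optics model

The forward model is scalar Fourier optics on a zero-centered frequency
grid (even size, $k=0$ at index $n/2+1$; unitary FFTs, so Parseval holds to
machine precision). The aperture is the disk $|\mathbf{k}| \le
\mathrm{NA}/\lambda$. This is a deliberate simplification at NA 1.2: the
analyses the package supports (Zernike phase, Strehl, FWHM) are themselves
scalar-pupil concepts, and vectorial/apodization effects are out of scope.
One wavelength (678 nm) serves both the reflection and emission paths;
the chromatic offset to the real emission spectrum is ignored.

Zernike modes use Noll single-indexing and unit-RMS normalization over the
disk, so a coefficient *is* its RMS contribution in radians and orthogonal
modes add in quadrature. `rmsWavefront()` removes piston/tip/tilt *and
defocus* by default before taking the RMS — displayed aberration maps
conventionally drop tilt and defocus, and whether printed RMS values also
exclude defocus is ambiguous in practice, so the exclusion set is an
explicit argument.

`randomAberration()` draws modes 5–100 with amplitude decay
$j^{-0.5}$ and rescales exactly to the target RMS. This emulates the
strong, high-order tissue aberrations of the deep-imaging regime
(RMS 2–3 rad needing ~100 modes), which is beyond the ~1 rad reach of
image-metric AO.

Off-axis holography: the interferogram is $|S + A e^{-i\mathbf{k}_c\cdot
\mathbf{r}}|^2$ with the carrier at 3/4 Nyquist along x by default and
$A$ set to the field's RMS amplitude. The sign convention puts the direct
image at $+\mathbf{k}_c$; demodulation crops the aperture disk there,
recenters, inverse-transforms and divides by $A$. Separability requires
$|\mathbf{k}_c| \ge 3 r_{\rm aperture}$ (the baseband autocorrelation is
twice the aperture wide) and $|\mathbf{k}_c| + r$ inside the band; with
those satisfied the round trip is exact to numerical precision, which the
tests assert at $10^{-6}$.

# The SMLM simulator

`structureFixture()` supplies labeled-point ground truth: a 170 nm line
pair (two-filament geometry), a filament mesh, the side-view cross-section
of a 180 nm hollow cylinder (arcsine-peaked bimodal transverse profile),
or uniform points; label jitter defaults to 5 nm.

Blinking is a two-state Markov chain per emitter (`pOn` activation per
frame, geometric on-times of mean `meanOnFrames`), started from its
stationary distribution. Brightness has two models: `"constant"` (every
on-frame emits the nominal photon rate — the right fixture for photon
accounting contracts) and `"per_burst_exponential"` (each switching event
draws an exponential rate factor of mean 1, held for the burst). The
second is what the demo uses: real dye photon-per-event histograms are
broad and right-skewed, and that brightness spread is what lets a strongly
aberrated channel retain its bright tail — with constant brightness every
aberrated PSF sits at the same marginal SNR and the localization-number
comparison becomes a knife-edge.

Rendering splats each on emitter through the pupil-phase PSF on a grid
oversampled 4× relative to the 130 nm camera pixel (bilinear sub-pixel
placement, so positions are not quantized), bins to camera pixels, adds
background (20 photons/px/frame by default), and applies the EMCCD chain:
Poisson photoelectrons (QE 0.9), gamma-distributed EM amplification
(gain 100), Gaussian read noise (1 e⁻), baseline 100, integer counts.
Photon budget defaults to 3000 expected photons per on-frame. The
dual-channel renderer shares one blink/brightness matrix and splits the
budget 50/50, mirroring the beam-splitter scheme that acquires AO-off and
AO-on movies simultaneously and makes the comparison fair; channel B's
pupil is `aberration + correction`.

What the generator does **not** emulate: axial (z) structure and PSF
defocus, dye dark states beyond two, drift, autofluorescence gradients,
and field-dependent (space-variant) PSFs within one render. Passing tests
therefore demonstrate correctness of the algorithms under the stated
model, not instrument calibration on real data.

# Localization

Detection mimics the standard SMLM pipeline: counts are calibrated to
photons using the camera metadata (dividing by EM gain and QE; the EM
excess-noise factor is knowingly ignored, a documented ~√2 underestimate of
photon-count noise, not of the photon values), a difference-of-Gaussians
band-pass (σ 1 and 2.5 px) is thresholded at `thresholdFactor` (default 3)
times a robust noise level, with 8-neighbor maxima and non-maximum
suppression inside the fit window. The noise level is the MAD-based SD of
the *raw* frame's high-frequency residual (frame minus its 1 px smooth),
matching the reference implementation's default of thresholding its
detection image against the first wavelet level of the raw frame —
estimating noise on the already-smoothed detection image instead would
roughly halve the effective threshold.

Fitting is Levenberg–Marquardt least squares of a symmetric 2-D Gaussian
plus offset in a 7×7 px window, with one window-recentering pass when the
centroid lands off-center. Fits are rejected (reason enumerated, never
raised) for non-convergence, border or out-of-window centroids, and widths
outside 0.5–3× the nominal PSF σ (1.1 px at this geometry). Photons are
reported as $2\pi A \sigma^2$; the per-row `uncertainty_nm` is the
Thompson-style estimate and is an annotation only — localization
*precision* in this package always means the nearest-neighbor fit σ.
Tables export bit-exactly to the ThunderSTORM CSV header dialect and the
reader tolerates reordered/renamed export variants.

# Quality metrics

**Nearest-neighbor precision.** Displacements pair each localization in
frame $t$ with its nearest neighbor in frame $t+1$ (strictly consecutive;
ties by distance then row). Their histogram (5 nm bins to 300 nm) is fitted
by bounded Levenberg–Marquardt to

$$p(d)=A_1\frac{d}{2\sigma^2}\exp\!\Big[-\frac{d^2}{4\sigma^2}\Big]
 + A_2\frac{1}{\sqrt{2\pi\omega^2}}
   \exp\!\Big[-\frac{(d-d_C)^2}{2\omega^2}\Big],$$

whose first term is the Rayleigh density of the distance between two
independent estimates of one molecule with per-axis precision σ (scale
$\sigma\sqrt2$, mean $\sigma\sqrt\pi$), and whose Gaussian term (center
$d_C$, width ω) absorbs pairs formed by *different* molecules in
proximity. σ is the localization precision. Initialization: σ₀ from the
histogram mode ($\mathrm{mode}/\sqrt2$), $d_{C,0}$ from the upper-tail
mode; unweighted least squares by default with Poisson weights available.
Displacement sets whose 95th percentile collapses below one bin bypass the
fit (degenerate flag). Fewer than 100 displacements refuse to fit.

**FRC.** Odd/even-frame halves are rendered as 5 nm 2-D histograms,
correlated per integer frequency ring, smoothed by a 3-ring running mean,
and the resolution is the interpolated first crossing of the fixed 1/7
threshold; never crossing flags the curve unresolved.

**Ensemble PSF.** Crops around accepted localizations (first 400 frames in
the demo), bilinearly aligned at the fitted sub-pixel centroid, averaged,
unit-peak normalized, measured by `fwhm2d` (profile-through-peak with
linear interpolation at the half level). For a strongly aberrated channel
the accepted localizations sit on speckle lobes, so this measures the
dominant-lobe envelope — wider than the corrected PSF, much narrower than
the full scattered halo.

**Nyquist scaling.** Over a fixed 2-D area the density-limited resolution
scales as density$^{-1/2}$, so a localization-number ratio $N$ maps to a
$\sqrt N$ Nyquist-resolution enhancement; the 37.4 → 6.12 relation is the
package's fixed-point check of that convention.

# The demo pipeline and its scale

`fullDemo()` chains everything: a 2.5 rad RMS, 100-mode ground-truth
aberration on the reflection grid; a 200-angle scan of a 50-scatterer
phantom; CLASS recovery (residual ≈ $10^{-4}$ rad noiseless); transfer of
the aberration (exact, via its generating modes) and of the correction
(complex-domain bilinear resampling by physical frequency) onto the SMLM
render grid; a 1500-frame, 250-emitter dual-channel movie at 64×64 camera
pixels; localization of both channels; and the metric suite. The
acquisition length is chosen so the *uncorrected* channel — which keeps
only the bright tail of the burst-brightness distribution, about 1% of
emitter-frames — still accumulates the ≥100 consecutive-frame pairs the
precision fit requires; the ensemble PSF uses the first 400 frames. The
whole pipeline runs in well under two minutes on one core; all stage seeds
derive deterministically from one master seed and a fixed configuration
reproduces its stored report byte-for-byte.

Numerical conventions worth knowing: even grids put $k=0$ at $n/2+1$;
degenerate NN-displacement sets bypass the model fit; FRC curves that never
cross 1/7 are flagged rather than extrapolated; `fwhm2d` errors on border
peaks and warns below two-pixel widths; CLASS non-convergence flags the
result. Serialization uses float TIFF with affine scales and full metadata
in JSON sidecars (phase maps, field stacks, frame stacks) — a deliberately
text-auditable format pairing.

# Known limitations

* Scalar single-wavelength optics at NA 1.2; no vectorial PSF, no
  chromatic offset between reflection and emission paths.
* Single-scattering reflection model; no multiple scattering or coherence
  gating, so the simulator cannot probe CLASS's depth limits.
* The localizer fits isolated symmetric Gaussians: overlapping emitters
  and astigmatic/3-D PSFs are out of scope, and under strong aberration
  each speckle lobe can be accepted as a separate localization — real
  analysis software behaves the same way, but counts should be read as
  *accepted fits*, not molecules.
* Patch-wise CLASS assumes the windowed patch still obeys the
  shift-invariant model; window spectral leakage biases recovery for
  high-order per-patch aberrations.
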