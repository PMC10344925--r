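#' @import methods
NULL

#' Pupil-plane sampling geometry
#'
#' A \code{PupilGrid} describes the discrete spatial-frequency plane shared by
#' all pupil-phase and field objects: an \code{nPx} x \code{nPx} grid whose
#' frequency step per axis is \code{1/(nPx * pitchNm)} (units 1/nm), with the
#' zero frequency at index \code{nPx/2 + 1} (even-grid FFT convention). The
#' objective aperture is the disk of radius \code{na/wavelengthNm} in spatial
#' frequency.
#'
#' @slot nPx integer, grid side (even, >= 16).
#' @slot pitchNm image-plane pixel pitch in nm.
#' @slot wavelengthNm wavelength in nm.
#' @slot na numerical aperture.
#' @slot mask logical matrix, TRUE inside the aperture disk.
#'
#' @export
setClass("PupilGrid",
  representation(
    nPx = "integer",
    pitchNm = "numeric",
    wavelengthNm = "numeric",
    na = "numeric",
    mask = "matrix"
  )
)

setValidity("PupilGrid", function(object) {
  msg <- character()
  if (length(object@nPx) != 1L || object@nPx < 16L)
    msg <- c(msg, "nPx must be a single integer >= 16")
  if (object@nPx %% 2L != 0L)
    msg <- c(msg, "nPx must be even (zero frequency sits at nPx/2 + 1)")
  if (object@pitchNm <= 0 || object@wavelengthNm <= 0 || object@na <= 0)
    msg <- c(msg, "pitchNm, wavelengthNm and na must be positive")
  # aperture must fit strictly inside the representable frequency band
  if (object@na * object@pitchNm / object@wavelengthNm >= 0.5)
    msg <- c(msg, "aperture exceeds the Nyquist frequency band: need na*pitch/wavelength < 0.5")
  if (!identical(dim(object@mask), c(object@nPx, object@nPx)))
    msg <- c(msg, "mask dimensions must equal nPx x nPx")
  if (length(msg)) msg else TRUE
})

#' Pupil-plane phase map
#'
#' A phase aberration (radians) defined on the aperture pixels of a
#' \code{PupilGrid}; values outside the aperture mask carry no meaning and are
#' stored as 0.
#'
#' @slot grid a \code{PupilGrid}.
#' @slot phase numeric matrix of phases in radians.
#'
#' @export
setClass("PhaseMap",
  representation(grid = "PupilGrid", phase = "matrix")
)

setValidity("PhaseMap", function(object) {
  msg <- character()
  if (!identical(dim(object@phase), dim(object@grid@mask)))
    msg <- c(msg, "phase dimensions must match the grid")
  if (any(!is.finite(object@phase[object@grid@mask])))
    msg <- c(msg, "phase must be finite on the aperture")
  if (length(msg)) msg else TRUE
})

#' Zernike mode coefficients
#'
#' Coefficients of unit-RMS-normalized Zernike modes in Noll single-index
#' ordering (j = 1 piston, 2/3 tip/tilt, 4 defocus, ...). With this
#' normalization each coefficient is directly the RMS contribution of its mode
#' in radians, so orthogonal modes add in quadrature.
#'
#' @slot values numeric coefficients, mode j = position j.
#' @slot ordering ordering tag, currently only \code{"noll"}.
#'
#' @export
setClass("ZernikeCoefficients",
  representation(values = "numeric", ordering = "character"),
  prototype(ordering = "noll")
)

setValidity("ZernikeCoefficients", function(object) {
  msg <- character()
  if (length(object@values) < 1L) msg <- c(msg, "need at least one coefficient")
  if (any(!is.finite(object@values))) msg <- c(msg, "coefficients must be finite")
  if (!object@ordering %in% c("noll")) msg <- c(msg, "unsupported ordering tag")
  if (length(msg)) msg else TRUE
})

#' Complex field in the camera plane
#'
#' @slot grid the shared \code{PupilGrid} sampling.
#' @slot amplitude complex matrix, the field sampled at the camera pixels.
#'
#' @export
setClass("ComplexField",
  representation(grid = "PupilGrid", amplitude = "matrix")
)

setValidity("ComplexField", function(object) {
  msg <- character()
  if (!identical(dim(object@amplitude), dim(object@grid@mask)))
    msg <- c(msg, "amplitude dimensions must match the grid")
  if (any(!is.finite(Re(object@amplitude))) || any(!is.finite(Im(object@amplitude))))
    msg <- c(msg, "field must be finite")
  if (length(msg)) msg else TRUE
})

#' Off-axis interferogram
#'
#' Intensity image of the coherent sum of the sample field and a tilted
#' reference plane wave, \code{|S + A exp(i k_c . r)|^2}.
#'
#' @slot image non-negative real matrix.
#' @slot carrier integer length-2 carrier wavevector in grid pixel units.
#' @slot refAmplitude reference-beam amplitude A.
#' @slot grid the \code{PupilGrid}.
#' @slot illumK integer length-2 illumination wavevector index (bookkeeping).
#'
#' @export
setClass("Interferogram",
  representation(image = "matrix", carrier = "integer",
                 refAmplitude = "numeric", grid = "PupilGrid",
                 illumK = "integer")
)

setValidity("Interferogram", function(object) {
  msg <- character()
  if (any(object@image < 0)) msg <- c(msg, "interferogram must be non-negative")
  if (length(object@carrier) != 2L) msg <- c(msg, "carrier must be length 2")
  if (length(msg)) msg else TRUE
})

#' Reflection matrix R(k_out, k_in)
#'
#' Complex matrix of reflected fields in the spatial-frequency basis: rows are
#' the aperture pixels of the output pupil (flattened via \code{rowIndex}),
#' columns are illumination angles.
#'
#' @slot entries complex matrix (aperture pixels x angles).
#' @slot illumKs integer matrix (angles x 2) of input wavevectors as pixel
#'   offsets from the grid center.
#' @slot rowIndex integer vector of linear grid indices for the rows.
#' @slot grid the \code{PupilGrid}.
#'
#' @export
setClass("ReflectionMatrix",
  representation(entries = "matrix", illumKs = "matrix",
                 rowIndex = "integer", grid = "PupilGrid")
)

setValidity("ReflectionMatrix", function(object) {
  msg <- character()
  if (nrow(object@entries) != length(object@rowIndex))
    msg <- c(msg, "rowIndex length must equal the number of rows")
  if (ncol(object@entries) != nrow(object@illumKs))
    msg <- c(msg, "illumKs must have one row per column of entries")
  if (anyDuplicated(object@rowIndex))
    msg <- c(msg, "rowIndex must be a bijection onto aperture pixels")
  r <- apertureRadiusPx(object@grid)
  if (any(sqrt(rowSums(object@illumKs^2)) > r + 1e-9))
    msg <- c(msg, "all illumination wavevectors must lie inside the aperture")
  if (length(msg)) msg else TRUE
})

#' Result of the CLASS aberration search
#'
#' @slot phaseIn input-path aberration as a \code{PhaseMap} (known only at the
#'   illumination angles; nearest-angle interpolation onto the aperture).
#' @slot phaseOut output-path aberration \code{PhaseMap}.
#' @slot phiInAngles accumulated input phase per illumination angle (radians).
#' @slot objectSpectrum accumulated single-scattering object spectrum on the
#'   difference-frequency grid.
#' @slot intensityTrace total single-scattering intensity per iteration.
#' @slot iterations number of iterations run.
#' @slot converged logical convergence flag.
#'
#' @export
setClass("ClassResult",
  representation(phaseIn = "PhaseMap", phaseOut = "PhaseMap",
                 phiInAngles = "numeric", objectSpectrum = "matrix",
                 intensityTrace = "numeric", iterations = "integer",
                 converged = "logical")
)

#' Ground-truth emitters for an SMLM simulation
#'
#' @slot positions numeric matrix (n x 2) of (x, y) in nm, origin at the
#'   field-of-view corner.
#' @slot photonRate expected photons emitted per on-frame (recycled).
#' @slot structureTag fixture name.
#' @slot fovNm field-of-view side in nm.
#'
#' @export
setClass("EmitterSet",
  representation(positions = "matrix", photonRate = "numeric",
                 structureTag = "character", fovNm = "numeric")
)

setValidity("EmitterSet", function(object) {
  msg <- character()
  if (nrow(object@positions) > 0) {
    if (ncol(object@positions) != 2L) msg <- c(msg, "positions must be n x 2")
    if (any(object@positions < 0) || any(object@positions > object@fovNm))
      msg <- c(msg, "positions must lie inside the field of view")
  }
  if (any(object@photonRate <= 0)) msg <- c(msg, "photonRate must be positive")
  if (length(msg)) msg else TRUE
})

#' Photoswitching on/off states
#'
#' Two-state Markov chain per emitter: off -> on with probability \code{pOn}
#' per frame, on -> off with probability \code{1/meanOnFrames}; stationary
#' on-fraction \code{pOn / (pOn + 1/meanOnFrames)}.
#'
#' @slot states logical matrix (emitters x frames).
#' @slot brightness numeric matrix (emitters x frames) of emission-rate
#'   factors (mean 1 over on-states; 0 when off). Under the
#'   \code{"per_burst_exponential"} model each switching event draws one
#'   exponential factor held constant for the burst.
#' @slot pOn per-frame activation probability.
#' @slot meanOnFrames mean on-state duration in frames.
#' @slot seed integer seed used for the draw.
#'
#' @export
setClass("BlinkMatrix",
  representation(states = "matrix", brightness = "matrix", pOn = "numeric",
                 meanOnFrames = "numeric", seed = "integer")
)

#' Simulated camera frame stack
#'
#' @slot frames numeric array (H x W x nFrames) of integer counts.
#' @slot channel "uncorrected", "corrected" or "single".
#' @slot camera named list: emGain, readNoiseE, baseline, qe, pixelNm.
#' @slot psfPhase the pupil \code{PhaseMap} used to render the PSF.
#'
#' @export
setClass("FrameStack",
  representation(frames = "array", channel = "character",
                 camera = "list", psfPhase = "PhaseMap")
)

setValidity("FrameStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L) msg <- c(msg, "frames must be H x W x nFrames")
  if (any(object@frames < 0)) msg <- c(msg, "counts must be non-negative")
  need <- c("emGain", "readNoiseE", "baseline", "qe", "pixelNm")
  if (!all(need %in% names(object@camera)))
    msg <- c(msg, paste("camera metadata must include:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Nearest-neighbor localization-precision fit
#'
#' Parameters of the two-term pairwise-displacement model
#' \deqn{p(d) = A_1 \frac{d}{2\sigma^2} e^{-d^2/(4\sigma^2)} +
#'       A_2 \frac{1}{\sqrt{2\pi\omega^2}} e^{-(d-d_C)^2/(2\omega^2)}}
#' where \eqn{\sigma} is the localization precision and the Gaussian term
#' absorbs nearest neighbors that are different molecules in proximity.
#'
#' @slot sigmaNm localization precision (nm).
#' @slot omegaNm correction-term width (nm).
#' @slot dCNm correction-term center (nm).
#' @slot a1,a2 component amplitudes (mixture weights of the density).
#' @slot binEdges,histogram the fitted histogram (density scale).
#' @slot fitResidual root-mean-square residual of the fit.
#' @slot nDisplacements number of displacements used.
#' @slot degenerate TRUE when the displacements collapse below one bin and the
#'   model fit was bypassed.
#'
#' @export
setClass("NNPrecisionFit",
  representation(sigmaNm = "numeric", omegaNm = "numeric", dCNm = "numeric",
                 a1 = "numeric", a2 = "numeric", binEdges = "numeric",
                 histogram = "numeric", fitResidual = "numeric",
                 nDisplacements = "integer", degenerate = "logical")
)

setValidity("NNPrecisionFit", function(object) {
  msg <- character()
  if (object@sigmaNm < 0) msg <- c(msg, "sigma must be non-negative")
  if (!object@degenerate && object@omegaNm <= 0) msg <- c(msg, "omega must be positive")
  if (length(msg)) msg else TRUE
})

#' Fourier ring correlation curve
#'
#' @slot ringFreqs spatial frequencies (1/nm) of the ring centers.
#' @slot correlation FRC values in [-1, 1].
#' @slot resolutionNm resolution at the threshold crossing; \code{NA} when the
#'   curve never crosses (see \code{resolved}).
#' @slot resolved FALSE when the threshold was never crossed.
#' @slot splitMode how localizations were split into half-images.
#' @slot threshold the fixed FRC threshold used.
#'
#' @export
setClass("FrcCurve",
  representation(ringFreqs = "numeric", correlation = "numeric",
                 resolutionNm = "numeric", resolved = "logical",
                 splitMode = "character", threshold = "numeric")
)

# ---- show methods ----------------------------------------------------------

setMethod("show", "PupilGrid", function(object) {
  cat(sprintf("PupilGrid: %d x %d px, pitch %.1f nm, lambda %.1f nm, NA %.2f\n",
              object@nPx, object@nPx, object@pitchNm, object@wavelengthNm, object@na))
  cat(sprintf("  aperture radius %.3f um^-1 (%.1f px), %d aperture pixels\n",
              1000 * object@na / object@wavelengthNm, apertureRadiusPx(object),
              sum(object@mask)))
})

setMethod("show", "PhaseMap", function(object) {
  v <- object@phase[object@grid@mask]
  cat(sprintf("PhaseMap on %d px grid: rms %.3f rad (piston removed), range [%.2f, %.2f]\n",
              object@grid@nPx, stats::sd(v) * sqrt((length(v) - 1) / length(v)),
              min(v), max(v)))
})

setMethod("show", "ReflectionMatrix", function(object) {
  cat(sprintf("ReflectionMatrix: %d aperture pixels x %d illumination angles\n",
              nrow(object@entries), ncol(object@entries)))
})

setMethod("show", "ClassResult", function(object) {
  cat(sprintf("ClassResult: %d iterations, converged: %s\n",
              object@iterations, object@converged))
  cat(sprintf("  intensity gain %.3g -> %.3g\n",
              object@intensityTrace[1], utils::tail(object@intensityTrace, 1)))
})

setMethod("show", "EmitterSet", function(object) {
  cat(sprintf("EmitterSet '%s': %d emitters in %.1f x %.1f um FOV\n",
              object@structureTag, nrow(object@positions),
              object@fovNm / 1000, object@fovNm / 1000))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack (%s): %d frames of %d x %d px (%.0f nm pixel)\n",
              object@channel, d[3], d[1], d[2], object@camera$pixelNm))
})

setMethod("show", "NNPrecisionFit", function(object) {
  cat(sprintf("NNPrecisionFit: sigma = %.1f nm, omega = %.1f nm, d_C = %.1f nm (n = %d)\n",
              object@sigmaNm, object@omegaNm, object@dCNm, object@nDisplacements))
})

setMethod("show", "FrcCurve", function(object) {
  if (object@resolved)
    cat(sprintf("FrcCurve (%s split): resolution %.1f nm at threshold %.3f\n",
                object@splitMode, object@resolutionNm, object@threshold))
  else
    cat(sprintf("FrcCurve (%s split): threshold %.3f never crossed\n",
                object@splitMode, object@threshold))
})
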