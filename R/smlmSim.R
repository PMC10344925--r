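# Dual-channel SMLM blinking-movie simulator: ground-truth structures,
# two-state photoswitching, and EMCCD frame rendering with an arbitrary
# pupil-phase PSF.

#' Ground-truth structure fixtures
#'
#' Generates labeled-point positions along parametric structures that emulate
#' commonly imaged specimens: a pair of parallel filaments at a fixed
#' separation (microtubule-pair geometry), a sparse filament mesh, the
#' side-view cross-section of a hollow membrane cylinder (bimodal transverse
#' profile whose modes sit one wall spacing apart), or uniform random points.
#'
#' @param kind one of \code{"line_pair"}, \code{"filament_mesh"},
#'   \code{"hollow_cylinder_cross_section"}, \code{"random_points"}.
#' @param fovNm field-of-view side in nm.
#' @param nEmitters number of labeled points.
#' @param params named list of structure parameters: \code{separationNm}
#'   (line pair, default 170), \code{spacingNm} (cylinder wall spacing,
#'   default 180), \code{nFilaments} (mesh, default 4), \code{jitterNm}
#'   (label jitter standard deviation, default 5).
#' @param photonRate expected photons per on-frame (default 3000).
#' @param seed integer seed.
#' @return an \code{\linkS4class{EmitterSet}}.
#' @export
structureFixture <- function(kind, fovNm, nEmitters,
                             params = list(), photonRate = 3000, seed = 1L) {
  kind <- match.arg(kind, c("line_pair", "filament_mesh",
                            "hollow_cylinder_cross_section", "random_points"))
  p <- utils::modifyList(list(separationNm = 170, spacingNm = 180,
                              nFilaments = 4L, jitterNm = 5), params)
  pos <- withSeed(seed, {
    if (nEmitters == 0L) {
      matrix(numeric(0), 0, 2)
    } else switch(kind,
      line_pair = {
        t <- stats::runif(nEmitters, 0.15 * fovNm, 0.85 * fovNm)
        side <- sample(c(-0.5, 0.5), nEmitters, replace = TRUE)
        cbind(t, fovNm / 2 + side * p$separationNm +
                    stats::rnorm(nEmitters, 0, p$jitterNm))
      },
      filament_mesh = {
        nf <- p$nFilaments
        a <- stats::runif(nf, 0, pi)
        o <- stats::runif(nf, 0.3, 0.7) * fovNm
        which <- sample(nf, nEmitters, replace = TRUE)
        t <- stats::runif(nEmitters, -0.6, 0.6) * fovNm
        cbind(fovNm / 2 + t * cos(a[which]) +
                stats::rnorm(nEmitters, 0, p$jitterNm),
              o[which] + t * sin(a[which]) +
                stats::rnorm(nEmitters, 0, p$jitterNm))
      },
      hollow_cylinder_cross_section = {
        t <- stats::runif(nEmitters, 0.15 * fovNm, 0.85 * fovNm)
        phi <- stats::runif(nEmitters, 0, 2 * pi)
        cbind(t, fovNm / 2 + (p$spacingNm / 2) * sin(phi) +
                    stats::rnorm(nEmitters, 0, p$jitterNm))
      },
      random_points = {
        cbind(stats::runif(nEmitters, 0, fovNm),
              stats::runif(nEmitters, 0, fovNm))
      }
    )
  })
  if (nrow(pos)) pos <- pmin(pmax(pos, 0), fovNm)
  colnames(pos) <- c("x", "y")
  new("EmitterSet", positions = pos, photonRate = photonRate,
      structureTag = kind, fovNm = fovNm)
}

#' @rdname structureFixture
#' @param x an \code{EmitterSet}.
#' @export
emitterPositions <- function(x) x@positions

#' Simulate photoswitching
#'
#' Independent two-state Markov chain per emitter: an off emitter switches on
#' with probability \code{pOn} per frame; an on emitter stays on with
#' probability \code{1 - 1/meanOnFrames} (geometric on-times with the given
#' mean). Initial states are drawn from the stationary distribution, whose
#' on-fraction is \code{pOn / (pOn + 1/meanOnFrames)}.
#'
#' @param emitters an \code{\linkS4class{EmitterSet}}.
#' @param nFrames number of frames.
#' @param pOn per-frame activation probability in (0, 1); 0 is allowed and
#'   yields an all-off matrix.
#' @param meanOnFrames mean on-state duration in frames (>= 1).
#' @param seed integer seed; same seed, same matrix.
#' @param brightnessModel \code{"constant"} (every on-frame emits exactly the
#'   emitter's photon rate) or \code{"per_burst_exponential"} (each switching
#'   event draws an exponential emission-rate factor of mean 1, held constant
#'   for the burst — the broad per-event brightness spread seen in real dye
#'   photon histograms).
#' @return a \code{\linkS4class{BlinkMatrix}}.
#' @export
simulateBlinking <- function(emitters, nFrames, pOn = 0.02,
                             meanOnFrames = 3, seed = 1L,
                             brightnessModel = c("constant",
                                                 "per_burst_exponential")) {
  stopifnot(pOn >= 0, pOn < 1, meanOnFrames >= 1)
  brightnessModel <- match.arg(brightnessModel)
  nE <- nrow(emitters@positions)
  pOff <- 1 / meanOnFrames
  states <- matrix(FALSE, nE, nFrames)
  bright <- matrix(0, nE, nFrames)
  if (nE > 0 && pOn > 0) {
    withSeed(seed, {
      pStat <- pOn / (pOn + pOff)
      s <- stats::runif(nE) < pStat
      b <- if (brightnessModel == "constant") rep(1, nE)
           else stats::rexp(nE)
      for (f in seq_len(nFrames)) {
        u <- stats::runif(nE)
        sNew <- ifelse(s, u >= pOff, u < pOn)
        if (brightnessModel == "per_burst_exponential") {
          started <- sNew & !s
          if (any(started)) b[started] <- stats::rexp(sum(started))
        }
        states[, f] <- sNew
        bright[, f] <- ifelse(sNew, b, 0)
        s <- sNew
      }
    })
  }
  new("BlinkMatrix", states = states, brightness = bright, pOn = pOn,
      meanOnFrames = meanOnFrames, seed = as.integer(seed))
}

#' @rdname simulateBlinking
#' @param x a \code{BlinkMatrix}.
#' @export
blinkStates <- function(x) x@states

#' Default EMCCD camera model
#'
#' @param emGain electron-multiplying gain (gamma-distributed amplification).
#' @param readNoiseE Gaussian read noise sigma in electrons.
#' @param baseline constant camera offset in counts.
#' @param qe quantum efficiency.
#' @param pixelNm camera pixel size in nm.
#' @return named list of camera parameters.
#' @export
cameraModel <- function(emGain = 100, readNoiseE = 1, baseline = 100,
                        qe = 0.9, pixelNm = 130) {
  list(emGain = emGain, readNoiseE = readNoiseE, baseline = baseline,
       qe = qe, pixelNm = pixelNm)
}

#' Pupil grid for rendering a camera field of view
#'
#' Convenience constructor for the oversampled render grid used by
#' \code{\link{renderFrames}}: \code{fovPx * oversample} pixels at pitch
#' \code{camera$pixelNm / oversample}.
#'
#' @param fovPx camera field of view side in pixels.
#' @param camera camera model list.
#' @param wavelengthNm wavelength in nm.
#' @param na numerical aperture.
#' @param oversample oversampling factor.
#' @return a \code{PupilGrid}.
#' @export
renderGrid <- function(fovPx, camera, wavelengthNm, na, oversample = 4L) {
  makePupilGrid(as.integer(fovPx * oversample), camera$pixelNm / oversample,
                wavelengthNm, na)
}

#' Render an SMLM blinking movie
#'
#' For each frame, every on-state emitter deposits its photon budget through
#' the (aberrated or corrected) PSF rendered from the pupil phase on a grid
#' oversampled by \code{oversample} relative to the camera pixels; the
#' oversampled photon image is binned to camera pixels, background is added,
#' and the EMCCD chain is applied: Poisson shot noise on detected
#' photoelectrons, gamma-distributed EM amplification, Gaussian read noise,
#' constant baseline, integer quantization.
#'
#' @param emitters an \code{\linkS4class{EmitterSet}}.
#' @param blink a \code{\linkS4class{BlinkMatrix}} for those emitters.
#' @param psfPhase pupil \code{PhaseMap} on the render grid (its \code{nPx}
#'   must be \code{fovPx * oversample} and its pitch
#'   \code{camera$pixelNm / oversample}; see \code{\link{renderGrid}}).
#' @param camera camera model list from \code{\link{cameraModel}}.
#' @param backgroundPhotons background photons per camera pixel per frame.
#' @param seed integer seed.
#' @param oversample PSF splat oversampling factor (default 4).
#' @param photonScale multiplier on each emitter's photon rate (used by the
#'   dual-channel beam-splitter model).
#' @param shotNoise,emNoise,readNoise logical switches for the stochastic
#'   stages; turning them all off yields a deterministic expected-value render
#'   (plus baseline).
#' @param channel channel tag stored on the stack.
#' @return a \code{\linkS4class{FrameStack}}.
#' @export
renderFrames <- function(emitters, blink, psfPhase, camera = cameraModel(),
                         backgroundPhotons = 20, seed = 1L, oversample = 4L,
                         photonScale = 1, shotNoise = TRUE, emNoise = TRUE,
                         readNoise = TRUE, channel = "single") {
  oversample <- as.integer(oversample)
  nBig <- psfPhase@grid@nPx
  fovPx <- nBig %/% oversample
  if (fovPx * oversample != nBig)
    stop("psfPhase grid side must be a multiple of the oversampling factor")
  nFrames <- ncol(blink@states)
  nE <- nrow(emitters@positions)
  psf <- psfFromPupil(psfPhase, oversample = 1L)
  psf <- psf / sum(psf)
  c0 <- gridCenter(psfPhase@grid)
  pitchBig <- psfPhase@grid@pitchNm
  # bilinear sub-pixel splat: each emitter maps to 4 neighboring oversampled
  # pixels with bilinear weights, so positions are not quantized to the
  # oversampled grid
  if (nE) {
    pr <- emitters@positions[, 1] / pitchBig + 0.5
    pc <- emitters@positions[, 2] / pitchBig + 0.5
    fr0 <- pmin(pmax(floor(pr), 1L), nBig - 1L)
    fc0 <- pmin(pmax(floor(pc), 1L), nBig - 1L)
    wr <- pr - fr0
    wc <- pc - fc0
    splat <- lapply(seq_len(nE), function(e) {
      list(rows = c(fr0[e], fr0[e] + 1L, fr0[e], fr0[e] + 1L),
           cols = c(fc0[e], fc0[e], fc0[e] + 1L, fc0[e] + 1L),
           w = c((1 - wr[e]) * (1 - wc[e]), wr[e] * (1 - wc[e]),
                 (1 - wr[e]) * wc[e], wr[e] * wc[e]))
    })
  } else splat <- list()
  photons <- rep_len(emitters@photonRate, max(nE, 1L)) * photonScale
  frames <- array(0, dim = c(fovPx, fovPx, nFrames))
  binIdx <- rep(seq_len(fovPx), each = oversample)
  withSeed(seed, {
    for (f in seq_len(nFrames)) {
      canvas <- matrix(0, nBig, nBig)
      on <- which(blink@states[, f])
      for (e in on) {
        sp <- splat[[e]]
        amp <- photons[e] * blink@brightness[e, f]
        for (q in 1:4) {
          if (sp$w[q] == 0) next
          d <- c(sp$rows[q] - c0, sp$cols[q] - c0)
          s <- shiftOverlap(nBig, d)
          canvas[s$dst1:s$dst2, s$dst3:s$dst4] <-
            canvas[s$dst1:s$dst2, s$dst3:s$dst4] +
            amp * sp$w[q] * psf[s$src1:s$src2, s$src3:s$src4]
        }
      }
      # bin oversample x oversample blocks to camera pixels
      img <- rowsum(canvas, binIdx)
      img <- t(rowsum(t(img), binIdx))
      lambda <- (img + backgroundPhotons) * camera$qe
      pe <- if (shotNoise) matrix(stats::rpois(length(lambda), lambda),
                                  fovPx, fovPx) else lambda
      if (emNoise && camera$emGain != 1) {
        amp <- matrix(0, fovPx, fovPx)
        nz <- pe > 0
        amp[nz] <- stats::rgamma(sum(nz), shape = pe[nz], scale = camera$emGain)
        pe <- amp
      } else pe <- pe * camera$emGain
      if (readNoise && camera$readNoiseE > 0)
        pe <- pe + matrix(stats::rnorm(length(pe), 0, camera$readNoiseE),
                          fovPx, fovPx)
      # expected-value renders (all noise off) stay continuous; stochastic
      # renders are quantized to integer counts like a real readout
      frames[, , f] <- if (!shotNoise && !emNoise && !readNoise)
        pmax(pe + camera$baseline, 0)
      else pmax(round(pe + camera$baseline), 0)
    }
  })
  new("FrameStack", frames = frames, channel = channel, camera = camera,
      psfPhase = psfPhase)
}

#' @rdname renderFrames
#' @param x a \code{FrameStack}.
#' @export
stackFrames <- function(x) x@frames

#' @rdname renderFrames
#' @export
stackCamera <- function(x) x@camera

#' Render matched AO-off / AO-on channels
#'
#' Emulates the beam-splitter scheme that records aberration-uncorrected and
#' corrected blinking movies simultaneously: both channels share the same
#' blink matrix and ground-truth emitters; the photon budget is split between
#' them; channel A sees \code{aberration}, channel B sees
#' \code{aberration + correction} (a perfect correction cancels to a flat
#' pupil).
#'
#' @param emitters,blink as in \code{\link{renderFrames}}.
#' @param aberration sample aberration \code{PhaseMap} on the render grid.
#' @param correction correction \code{PhaseMap} (same grid); use
#'   \code{zernikePhase(-coefs, grid)} of a recovered aberration.
#' @param camera,backgroundPhotons,seed,oversample as in
#'   \code{\link{renderFrames}}.
#' @param split fraction of photons sent to the uncorrected channel.
#' @return list with elements \code{uncorrected} and \code{corrected}, both
#'   \code{\linkS4class{FrameStack}}s.
#' @export
renderDualChannel <- function(emitters, blink, aberration, correction,
                              camera = cameraModel(), backgroundPhotons = 20,
                              seed = 1L, oversample = 4L, split = 0.5) {
  grid <- aberration@grid
  corrected <- phaseMap(grid, aberration@phase + correction@phase)
  list(
    uncorrected = renderFrames(emitters, blink, aberration, camera,
                               backgroundPhotons, seed = deriveSeed(seed, "chA"),
                               oversample = oversample, photonScale = split,
                               channel = "uncorrected"),
    corrected = renderFrames(emitters, blink, corrected, camera,
                             backgroundPhotons, seed = deriveSeed(seed, "chB"),
                             oversample = oversample, photonScale = 1 - split,
                             channel = "corrected")
  )
}
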