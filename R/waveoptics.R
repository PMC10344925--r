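# Scalar Fourier-optics forward model. All transforms are unitary and
# zero-centered: fft2c/ifft2c put k = 0 at grid index nPx/2 + 1, so Parseval
# holds exactly (sum |x|^2 == sum |X|^2).

# half-grid swap; for even grids fftshift == ifftshift
fftshift2 <- function(m) {
  n <- nrow(m)
  h <- n %/% 2L
  m[c((h + 1L):n, 1L:h), c((h + 1L):n, 1L:h)]
}

fft2c <- function(x) fftshift2(stats::fft(fftshift2(x))) / sqrt(length(x))

ifft2c <- function(x) fftshift2(stats::fft(fftshift2(x), inverse = TRUE)) / sqrt(length(x))

#' Complex field constructor
#'
#' @param grid a \code{PupilGrid}.
#' @param amplitude complex matrix on the camera-plane pixels.
#' @return a \code{\linkS4class{ComplexField}}.
#' @export
complexField <- function(grid, amplitude) {
  new("ComplexField", grid = grid, amplitude = amplitude)
}

#' @rdname complexField
#' @param x a \code{ComplexField}.
#' @export
fieldAmplitude <- function(x) x@amplitude

# complex pupil function aperture * exp(i phase)
pupilFunction <- function(phase) {
  p <- phase@grid@mask * exp(1i * phase@phase)
  p[!phase@grid@mask] <- 0
  p
}

#' Incoherent PSF from a pupil phase
#'
#' Computes \code{|IFFT(aperture * exp(i phase))|^2} on a grid oversampled by
#' \code{oversample} (the pupil is zero-padded, so the image-plane sampling is
#' \code{pitchNm/oversample}). The image is normalized so the flat-phase PSF
#' on the same grid peaks at 1; the peak of an aberrated PSF is therefore its
#' Strehl ratio.
#'
#' @param phase a \code{PhaseMap}.
#' @param oversample integer >= 1 image-plane oversampling factor.
#' @return numeric matrix with attributes \code{pitchNm} (sampling) and
#'   \code{flatPeak} (the flat-phase normalization peak, pre-division).
#' @export
psfFromPupil <- function(phase, oversample = 1L) {
  oversample <- as.integer(oversample)
  stopifnot(oversample >= 1L)
  grid <- phase@grid
  n <- grid@nPx
  nBig <- n * oversample
  embed <- function(p) {
    big <- matrix(0 + 0i, nBig, nBig)
    o <- (nBig - n) %/% 2L
    big[(o + 1L):(o + n), (o + 1L):(o + n)] <- p
    big
  }
  psfOf <- function(p) abs(ifft2c(embed(p)))^2
  psf <- psfOf(pupilFunction(phase))
  flatPeak <- sum(grid@mask)^2 / nBig^2   # peak of |ifft2c(mask)|^2, analytic
  out <- psf / flatPeak
  attr(out, "pitchNm") <- grid@pitchNm / oversample
  attr(out, "flatPeak") <- flatPeak
  out
}

#' Strehl ratio of a pupil phase
#'
#' Peak intensity of the aberrated PSF divided by the peak of the ideal
#' (flat-phase) PSF on the same grid; always in (0, 1], equal to 1 only for
#' piston/tip/tilt phases.
#'
#' @param phase a \code{PhaseMap}.
#' @return the ratio.
#' @export
strehlRatio <- function(phase) {
  max(psfFromPupil(phase, oversample = 1L))
}

#' Full width at half maximum of a peaked 2-D image
#'
#' Takes the row and column profiles through the brightest pixel, finds the
#' half-maximum crossings on each side by linear interpolation, and returns
#' the mean of the x and y widths scaled to nm.
#'
#' @param image numeric matrix with a single dominant peak.
#' @param pitchNm sampling of the image in nm (defaults to the
#'   \code{pitchNm} attribute if present).
#' @return FWHM in nm.
#' @export
fwhm2d <- function(image, pitchNm = attr(image, "pitchNm")) {
  if (is.null(pitchNm)) stop("pitchNm must be supplied")
  pk <- which(image == max(image), arr.ind = TRUE)[1, ]
  n <- dim(image)
  if (any(pk <= 1L) || pk[1] >= n[1] || pk[2] >= n[2])
    stop("peak lies on the image border; cannot measure FWHM")
  half <- max(image) / 2
  crossing <- function(prof, ip) {
    # walk out from the peak to the first dip below half, interpolate
    right <- NA_real_
    for (i in (ip + 1L):length(prof)) {
      if (prof[i] <= half) {
        right <- (i - 1) + (prof[i - 1] - half) / (prof[i - 1] - prof[i])
        break
      }
    }
    left <- NA_real_
    for (i in (ip - 1L):1L) {
      if (prof[i] <= half) {
        left <- (i + 1) - (prof[i + 1] - half) / (prof[i + 1] - prof[i])
        break
      }
    }
    if (is.na(left) || is.na(right))
      stop("half-maximum level not reached inside the image")
    right - left
  }
  wx <- crossing(image[, pk[2]], pk[1])
  wy <- crossing(image[pk[1], ], pk[2])
  if (wx < 2 || wy < 2)
    warning("peak is close to single-pixel width; FWHM is not resolved by the sampling")
  mean(c(wx, wy)) * pitchNm
}

#' Coherent reflectance field under tilted illumination
#'
#' Single-scattering forward model for one angle of the angle scan: a plane
#' wave at \code{illumK} picks up the input-pupil phase at that one frequency,
#' reflects off the object (spectrum shift by \code{illumK}), and the returning
#' field is filtered by the output pupil \code{aperture * exp(i phaseOut)}
#' before propagating to the camera plane.
#'
#' @param objectMap complex or numeric matrix of object reflectance on the
#'   camera-plane pixels.
#' @param illumK integer length-2 illumination wavevector (pixel offsets from
#'   the grid center); must lie inside the aperture.
#' @param phaseIn input-path aberration \code{PhaseMap}.
#' @param phaseOut output-path aberration \code{PhaseMap}.
#' @return a \code{\linkS4class{ComplexField}}.
#' @export
reflectanceField <- function(objectMap, illumK, phaseIn, phaseOut) {
  grid <- phaseOut@grid
  n <- grid@nPx
  c0 <- gridCenter(grid)
  illumK <- as.integer(round(illumK))
  r <- apertureRadiusPx(grid)
  if (sum(illumK^2) > r^2)
    stop("illumination wavevector lies outside the aperture")
  O <- fft2c(objectMap)
  # non-circular spectrum shift by illumK (zeros wrap in)
  S <- matrix(0 + 0i, n, n)
  src <- shiftOverlap(n, illumK)
  S[src$dst1:src$dst2, src$dst3:src$dst4] <- O[src$src1:src$src2, src$src3:src$src4]
  phiIn <- phaseIn@phase[c0 + illumK[1], c0 + illumK[2]]
  S <- S * exp(1i * phiIn) * pupilFunction(phaseOut)
  complexField(grid, ifft2c(S))
}

# index bookkeeping for a non-circular 2-D shift by (dx, dy)
shiftOverlap <- function(n, d) {
  dx <- d[1]; dy <- d[2]
  list(
    dst1 = max(1L, 1L + dx), dst2 = min(n, n + dx),
    dst3 = max(1L, 1L + dy), dst4 = min(n, n + dy),
    src1 = max(1L, 1L - dx), src2 = min(n, n - dx),
    src3 = max(1L, 1L - dy), src4 = min(n, n - dy)
  )
}

# minimum carrier modulus for clean sideband separation: the baseband
# autocorrelation term has radius 2r, each sideband radius r
minCarrier <- function(grid) 3 * apertureRadiusPx(grid)

#' Synthesize an off-axis interferogram
#'
#' Camera intensity \code{|S + A exp(-i k_c . r)|^2} of the sample field plus
#' a tilted reference plane wave. The reference tilt is chosen so the direct
#' (non-conjugate) image of the field sits at \code{+carrier} in the spectrum;
#' the conjugate sideband at \code{-carrier} holds the flipped conjugate
#' field.
#'
#' @param field a \code{ComplexField}.
#' @param carrier integer length-2 carrier wavevector in grid pixel units;
#'   default (3/4 Nyquist, 0) along x. Its modulus must exceed 3x the aperture
#'   radius (so the sideband clears the baseband autocorrelation) and fit
#'   inside the band.
#' @param refAmplitude reference amplitude A; defaults to the RMS amplitude of
#'   the field.
#' @return an \code{\linkS4class{Interferogram}}.
#' @export
synthesizeInterferogram <- function(field, carrier = NULL, refAmplitude = NULL) {
  grid <- field@grid
  n <- grid@nPx
  if (is.null(carrier)) carrier <- c(as.integer(round(0.375 * n)), 0L)
  carrier <- as.integer(round(carrier))
  r <- apertureRadiusPx(grid)
  kc <- sqrt(sum(carrier^2))
  if (kc < minCarrier(grid))
    stop("sidebands overlap: |carrier| must be at least 3x the aperture radius")
  if (kc + r >= n / 2 - 1)
    stop("sideband exceeds the frequency band; reduce the carrier or the aperture")
  if (is.null(refAmplitude))
    refAmplitude <- sqrt(mean(abs(field@amplitude)^2))
  x <- seq_len(n) - gridCenter(grid)
  ref <- refAmplitude * exp(-2i * pi * (outer(x * carrier[1], x * carrier[2], "+")) / n)
  img <- abs(field@amplitude + ref)^2
  new("Interferogram", image = img, carrier = carrier,
      refAmplitude = refAmplitude, grid = grid, illumK = c(0L, 0L))
}

#' Demodulate an off-axis interferogram
#'
#' Recovers the complex sample field from a single off-axis intensity image:
#' FFT, crop the aperture-radius disk around \code{+carrier}, recenter it at
#' zero frequency, inverse FFT, divide by the reference amplitude. Exact (to
#' numerical precision) whenever the sidebands are separable.
#'
#' @param ig an \code{\linkS4class{Interferogram}}.
#' @return a \code{\linkS4class{ComplexField}}.
#' @export
demodulateOffaxis <- function(ig) {
  grid <- ig@grid
  n <- grid@nPx
  kc <- sqrt(sum(ig@carrier^2))
  if (kc < minCarrier(grid))
    stop("carrier too close to DC: sidebands are not separable")
  F <- fft2c(ig@image)
  c0 <- gridCenter(grid)
  k <- kOffsets(n)
  disk <- outer(k, k, function(kx, ky) kx^2 + ky^2 <= apertureRadiusPx(grid)^2)
  S <- matrix(0 + 0i, n, n)
  idx <- which(disk, arr.ind = TRUE)
  srcR <- idx[, 1] + ig@carrier[1]
  srcC <- idx[, 2] + ig@carrier[2]
  ok <- srcR >= 1 & srcR <= n & srcC >= 1 & srcC <= n
  S[idx[ok, , drop = FALSE]] <- F[cbind(srcR[ok], srcC[ok])]
  complexField(grid, ifft2c(S) / ig@refAmplitude)
}
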