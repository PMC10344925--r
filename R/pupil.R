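#' Build a pupil-plane sampling grid
#'
#' Constructs the shared frequency-plane geometry for all field and phase
#' objects. The grid is zero-centered with the even-size FFT convention
#' (k = 0 at index \code{nPx/2 + 1}); the frequency step per axis is
#' \code{1/(nPx * pitchNm)} and the aperture is the disk
#' \code{|k| <= na/wavelengthNm}, the physical cutoff of the objective.
#'
#' @param nPx grid side in pixels (even, >= 16).
#' @param pitchNm image-plane pixel pitch in nm.
#' @param wavelengthNm wavelength in nm.
#' @param na numerical aperture; must satisfy
#'   \code{na * pitchNm / wavelengthNm < 0.5} so the aperture fits inside the
#'   representable band.
#' @return a \code{\linkS4class{PupilGrid}}.
#' @examples
#' g <- makePupilGrid(256, 130, 678, 1.2)
#' cutoffFreq(g) * 1000   # aperture radius, um^-1
#' @export
makePupilGrid <- function(nPx, pitchNm, wavelengthNm, na) {
  nPx <- as.integer(nPx)
  if (length(nPx) != 1L || is.na(nPx) || nPx < 16L)
    stop("nPx must be a single integer >= 16")
  if (nPx %% 2L != 0L) stop("nPx must be even")
  if (na * pitchNm / wavelengthNm >= 0.5)
    stop("invalid sampling: aperture radius na/wavelength exceeds the Nyquist ",
         "band for pitch ", pitchNm, " nm")
  r <- na * nPx * pitchNm / wavelengthNm      # cutoff radius in frequency px
  k <- kOffsets(nPx)
  mask <- outer(k, k, function(kx, ky) kx^2 + ky^2 <= r^2)
  new("PupilGrid", nPx = nPx, pitchNm = pitchNm,
      wavelengthNm = wavelengthNm, na = na, mask = mask)
}

# signed frequency-pixel offsets for a zero-centered even grid
kOffsets <- function(nPx) seq_len(nPx) - (nPx %/% 2L + 1L)

#' @rdname makePupilGrid
#' @param grid a \code{PupilGrid}.
#' @export
freqStep <- function(grid) 1 / (grid@nPx * grid@pitchNm)

#' @rdname makePupilGrid
#' @export
cutoffFreq <- function(grid) grid@na / grid@wavelengthNm

#' @rdname makePupilGrid
#' @export
apertureRadiusPx <- function(grid) cutoffFreq(grid) / freqStep(grid)

#' @rdname makePupilGrid
#' @export
apertureMask <- function(grid) grid@mask

#' @rdname makePupilGrid
#' @export
gridCenter <- function(grid) grid@nPx %/% 2L + 1L

# normalized radial/angular pupil coordinates: rho in [0,1] at the cutoff
pupilPolar <- function(grid) {
  k <- kOffsets(grid@nPx)
  kx <- matrix(k, grid@nPx, grid@nPx)
  ky <- matrix(k, grid@nPx, grid@nPx, byrow = TRUE)
  r <- apertureRadiusPx(grid)
  list(rho = sqrt(kx^2 + ky^2) / r, theta = atan2(ky, kx))
}

#' Construct a phase map
#'
#' Wraps a raw matrix of radians as a \code{\linkS4class{PhaseMap}} on a grid;
#' values outside the aperture are zeroed.
#'
#' @param grid a \code{PupilGrid}.
#' @param phase numeric matrix of radians (defaults to flat zero phase).
#' @return a \code{PhaseMap}.
#' @export
phaseMap <- function(grid, phase = NULL) {
  if (is.null(phase)) phase <- matrix(0, grid@nPx, grid@nPx)
  phase[!grid@mask] <- 0
  new("PhaseMap", grid = grid, phase = phase)
}

#' @rdname phaseMap
#' @param x a \code{PhaseMap}.
#' @export
phaseValues <- function(x) x@phase

#' @rdname phaseMap
#' @export
pupilGrid <- function(x) x@grid

# ---- Zernike basis (Noll ordering, unit RMS over the disk) -----------------

# Noll single index -> (n, m); j = 1 is piston, 2/3 tip/tilt, 4 defocus
nollToNM <- function(j) {
  stopifnot(j >= 1)
  n <- floor((sqrt(8 * (j - 1) + 1) - 1) / 2)
  p <- j - n * (n + 1) / 2                 # 1 .. n+1 within the order block
  mAbs <- if (n %% 2 == 0) 2 * floor(p / 2) else 2 * floor((p - 1) / 2) + 1
  m <- if (j %% 2 == 0) mAbs else -mAbs    # even j cosine, odd j sine
  c(n = n, m = m)
}

# radial polynomial R_n^{|m|}(rho)
zernikeRadial <- function(n, mAbs, rho) {
  out <- 0
  for (k in 0:((n - mAbs) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + mAbs) / 2 - k) * factorial((n - mAbs) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

# one unit-RMS Noll mode evaluated on the full grid (0 outside the aperture)
zernikeModeMatrix <- function(j, grid, polar = NULL) {
  if (is.null(polar)) polar <- pupilPolar(grid)
  nm <- nollToNM(j)
  n <- nm[["n"]]; m <- nm[["m"]]; mAbs <- abs(m)
  norm <- if (mAbs == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  z <- norm * zernikeRadial(n, mAbs, polar$rho)
  if (m > 0) z <- z * cos(mAbs * polar$theta)
  if (m < 0) z <- z * sin(mAbs * polar$theta)
  z[!grid@mask] <- 0
  z
}

# design matrix of modes 1..nModes restricted to aperture pixels
zernikeDesign <- function(grid, nModes) {
  polar <- pupilPolar(grid)
  idx <- which(grid@mask)
  Z <- matrix(0, length(idx), nModes)
  for (j in seq_len(nModes)) Z[, j] <- zernikeModeMatrix(j, grid, polar)[idx]
  Z
}

#' Zernike coefficient container
#'
#' @param values numeric coefficients (radians RMS per mode), Noll ordering.
#' @return a \code{\linkS4class{ZernikeCoefficients}}.
#' @export
zernikeCoefficients <- function(values) {
  new("ZernikeCoefficients", values = as.numeric(values), ordering = "noll")
}

#' @rdname zernikeCoefficients
#' @param x a \code{ZernikeCoefficients}.
#' @export
coefValues <- function(x) x@values

#' Phase map from Zernike coefficients
#'
#' Linear superposition of unit-RMS Noll modes over the unit disk mapped onto
#' the aperture of \code{grid}. With unit-RMS normalization the aperture RMS
#' of mode j with coefficient a is a (up to disk-discretization error), and
#' orthogonal modes add in quadrature.
#'
#' @param coeffs a \code{ZernikeCoefficients} (or bare numeric vector).
#' @param grid a \code{PupilGrid}.
#' @return a \code{\linkS4class{PhaseMap}}.
#' @export
zernikePhase <- function(coeffs, grid) {
  if (is.numeric(coeffs)) coeffs <- zernikeCoefficients(coeffs)
  validObject(coeffs)
  v <- coeffs@values
  polar <- pupilPolar(grid)
  phase <- matrix(0, grid@nPx, grid@nPx)
  for (j in seq_along(v)) {
    if (v[j] != 0) phase <- phase + v[j] * zernikeModeMatrix(j, grid, polar)
  }
  phaseMap(grid, phase)
}

#' Least-squares Zernike decomposition
#'
#' Projects a phase map onto the first \code{nModes} Noll modes by least
#' squares over the aperture pixels (QR; the discrete Gram matrix is used, so
#' \code{decomposeZernike(zernikePhase(c))} round-trips exactly for in-span
#' inputs regardless of grid discretization).
#'
#' @param phase a \code{PhaseMap}.
#' @param nModes number of modes to fit.
#' @return a \code{\linkS4class{ZernikeCoefficients}} of length \code{nModes}.
#' @export
decomposeZernike <- function(phase, nModes) {
  grid <- phase@grid
  nPix <- sum(grid@mask)
  if (nModes > nPix)
    stop("conditioning error: ", nModes, " modes cannot be resolved on ",
         nPix, " aperture pixels")
  Z <- zernikeDesign(grid, nModes)
  qrz <- qr(Z)
  if (qrz$rank < nModes)
    stop("conditioning error: Zernike design matrix is rank deficient on this grid")
  coef <- qr.coef(qrz, phase@phase[grid@mask])
  zernikeCoefficients(coef)
}

#' RMS wavefront distortion
#'
#' Standard deviation of the pupil phase (radians) over the aperture after
#' subtracting the least-squares fit of the excluded low-order modes. The
#' default exclusion set is piston, tip, tilt and defocus: tip/tilt and
#' defocus trade against lateral/axial position of the imaged plane and are
#' not treated as aberration.
#'
#' @param phase a \code{PhaseMap}.
#' @param excludedModes character subset of
#'   \code{c("piston","tip","tilt","defocus")} (Noll j = 1,2,3,4).
#' @return RMS in radians.
#' @export
rmsWavefront <- function(phase,
                         excludedModes = c("piston", "tip", "tilt", "defocus")) {
  modeIdx <- c(piston = 1L, tip = 2L, tilt = 3L, defocus = 4L)
  excludedModes <- match.arg(excludedModes, names(modeIdx), several.ok = TRUE)
  grid <- phase@grid
  idx <- which(grid@mask)
  if (length(idx) == 0L) stop("empty aperture mask")
  v <- phase@phase[idx]
  js <- sort(unique(c(1L, modeIdx[excludedModes])))  # piston always removed
  Z <- zernikeDesign(grid, max(js))[, js, drop = FALSE]
  resid <- v - Z %*% qr.coef(qr(Z), v)
  sqrt(mean(resid^2))
}

#' Seeded random high-order aberration
#'
#' Draws Noll-mode coefficients over \code{modeRange} with a power-law
#' amplitude decay \code{j^-spectrumDecay} and rescales them exactly so that
#' \code{rmsWavefront} (with the default low-order exclusions) equals
#' \code{rmsTarget}. Emulates the strong, high-order tissue aberrations that
#' need on the order of 100 Zernike modes to describe.
#'
#' @param rmsTarget target RMS wavefront distortion in radians (>= 0).
#' @param modeRange integer range of Noll modes carrying power (default 5:100,
#'   i.e. everything above defocus up to mode 100).
#' @param spectrumDecay power-law exponent of the mode-amplitude decay.
#' @param seed integer seed; same seed, same map.
#' @param grid a \code{PupilGrid}.
#' @return a list with \code{phase} (the \code{PhaseMap}) and \code{coeffs}
#'   (the generating \code{ZernikeCoefficients}).
#' @export
randomAberration <- function(rmsTarget, grid, modeRange = 5:100,
                             spectrumDecay = 0.5, seed = 1L) {
  stopifnot(rmsTarget >= 0)
  v <- numeric(max(modeRange))
  if (rmsTarget > 0) {
    withSeed(seed, {
      v[modeRange] <- stats::rnorm(length(modeRange)) * modeRange^(-spectrumDecay)
    })
    pm <- zernikePhase(v, grid)
    measured <- rmsWavefront(pm)
    v <- v * rmsTarget / measured
  }
  list(phase = zernikePhase(v, grid), coeffs = zernikeCoefficients(v))
}

# evaluate a block with a local RNG state, restoring the caller's state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# deterministic sub-seed fan-out from a master seed and a stage tag
deriveSeed <- function(master, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647)
}
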