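# Closed-loop accumulation of single scattering (CLASS).
#
# The reflection matrix R(k_out, k_in) of a single-scattering sample factors,
# column by column, as R(k_o, j) = O(k_o - k_in_j) e^{i phi_in(k_in_j)}
# e^{i phi_out(k_o)}: the same object spectrum O appears in every column,
# shifted by the illumination wavevector and wrapped in the two pupil-phase
# factors. Re-indexing each column to the difference frequency dk = k_o - k_in
# and summing over angles accumulates O coherently only when the phase factors
# are compensated; the CLASS iteration alternates closed-form phase updates
# that maximize the accumulated single-scattering intensity sum |O_est|^2.

#' Build a reflection matrix from angle-scanned fields
#'
#' Each camera-plane field is Fourier transformed and restricted to the
#' aperture pixels; column j of the result is the output spectrum recorded
#' under illumination angle j.
#'
#' @param fields list of \code{\linkS4class{ComplexField}} sharing one grid.
#' @param illumKs integer matrix (nAngles x 2) of illumination wavevectors in
#'   grid pixel offsets from the center.
#' @param grid the common \code{PupilGrid}.
#' @return a \code{\linkS4class{ReflectionMatrix}}.
#' @export
buildReflectionMatrix <- function(fields, illumKs, grid) {
  if (length(fields) < 2L) stop("need at least two illumination angles")
  if (length(fields) != nrow(illumKs))
    stop("one illumination wavevector per field is required")
  idx <- which(grid@mask)
  entries <- matrix(0 + 0i, length(idx), length(fields))
  for (j in seq_along(fields)) {
    f <- fields[[j]]
    if (!identical(dim(f@amplitude), dim(grid@mask)))
      stop("field ", j, " does not share the grid sampling")
    entries[, j] <- fft2c(f@amplitude)[idx]
  }
  new("ReflectionMatrix", entries = entries,
      illumKs = matrix(as.integer(round(illumKs)), ncol = 2L),
      rowIndex = idx, grid = grid)
}

#' @rdname buildReflectionMatrix
#' @param R a \code{ReflectionMatrix}.
#' @export
reflectionEntries <- function(R) R@entries

#' @rdname buildReflectionMatrix
#' @export
illumWavevectors <- function(R) R@illumKs

# per-column linear indices into the difference-frequency (dk) plane
diffIndexMatrix <- function(R) {
  grid <- R@grid
  n <- grid@nPx
  ar <- arrayInd(R@rowIndex, dim(grid@mask))
  nAng <- nrow(R@illumKs)
  idx <- matrix(0L, nrow(R@entries), nAng)
  for (j in seq_len(nAng)) {
    rr <- ar[, 1] - R@illumKs[j, 1]
    cc <- ar[, 2] - R@illumKs[j, 2]
    if (any(rr < 1L | rr > n | cc < 1L | cc > n))
      stop("difference-frequency grid overflows: the grid must span at least ",
           "2x the aperture diameter (use a larger nPx or smaller na*pitch)")
    idx[, j] <- (cc - 1L) * n + rr
  }
  idx
}

# coherent accumulation of corrected columns onto the dk plane
accumulateColumns <- function(C, idxMat, n) {
  O <- rep(0 + 0i, n * n)
  for (j in seq_len(ncol(C))) {
    ij <- idxMat[, j]
    O[ij] <- O[ij] + C[, j]
  }
  O
}

#' Accumulate single-scattering intensity
#'
#' Applies per-angle input and per-pixel output phase corrections to the
#' reflection matrix, re-indexes every column to the difference frequency
#' dk = k_out - k_in, and sums coherently over angles. Corrections are added
#' to the recorded phase, so to cancel an aberration phi pass -phi.
#'
#' @param R a \code{\linkS4class{ReflectionMatrix}}.
#' @param phiInCorr numeric per-angle input correction (radians), length =
#'   number of angles (default 0).
#' @param phiOutCorr output correction: a \code{PhaseMap} or a numeric vector
#'   over aperture pixels in \code{rowIndex} order (default 0).
#' @return list with \code{spectrum} (complex nPx x nPx matrix on the dk
#'   plane), \code{totalIntensity} (sum |O_est|^2) and \code{coverage}
#'   (integer matrix of contributing angles per dk pixel).
#' @export
accumulateSingleScattering <- function(R, phiInCorr = NULL, phiOutCorr = NULL) {
  n <- R@grid@nPx
  nAng <- ncol(R@entries)
  if (is.null(phiInCorr)) phiInCorr <- numeric(nAng)
  if (is.null(phiOutCorr)) {
    phiOut <- numeric(nrow(R@entries))
  } else if (is(phiOutCorr, "PhaseMap")) {
    phiOut <- phiOutCorr@phase[R@rowIndex]
  } else phiOut <- phiOutCorr
  C <- R@entries * exp(1i * phiOut)
  C <- sweep(C, 2L, exp(1i * phiInCorr), `*`)
  idxMat <- diffIndexMatrix(R)
  O <- accumulateColumns(C, idxMat, n)
  cov <- integer(n * n)
  for (j in seq_len(nAng)) cov[idxMat[, j]] <- cov[idxMat[, j]] + 1L
  list(spectrum = matrix(O, n, n),
       totalIntensity = sum(abs(O)^2),
       coverage = matrix(cov, n, n))
}

#' Run the CLASS aberration-recovery iteration
#'
#' Alternating closed-form phase updates that maximize the accumulated
#' single-scattering intensity. Input step: for each angle j the update is
#' the argument of the inner product between column j (in the dk frame) and
#' the current accumulated spectrum; output step: the same per output-pupil
#' pixel across the row. Updates are pure phase rotations (unit modulus); the
#' inner products are amplitude-weighted by default. Iteration stops when the
#' relative intensity gain drops below \code{relTol} or after \code{maxIter}
#' iterations; non-convergence is flagged on the result, never raised.
#'
#' @param R a \code{\linkS4class{ReflectionMatrix}}.
#' @param maxIter maximum iterations.
#' @param relTol relative intensity-gain convergence tolerance.
#' @param leaveOneOut exclude column j from the accumulated spectrum when
#'   updating angle j (default FALSE: include-self accumulation).
#' @param weighting \code{"amplitude"} (inner products over raw complex
#'   entries) or \code{"equal"} (unit-modulus phasors only).
#' @return a \code{\linkS4class{ClassResult}}; recovered phases are reported
#'   modulo 2 pi with piston and tip/tilt removed (those trade against object
#'   position and carry no aberration information).
#' @export
classIterate <- function(R, maxIter = 30L, relTol = 1e-4,
                         leaveOneOut = FALSE,
                         weighting = c("amplitude", "equal")) {
  weighting <- match.arg(weighting)
  grid <- R@grid
  n <- grid@nPx
  nAng <- ncol(R@entries)
  C <- R@entries
  idxMat <- diffIndexMatrix(R)
  phiIn <- numeric(nAng)
  phiOut <- numeric(nrow(C))
  unit <- function(x) {
    out <- x / abs(x)
    out[!is.finite(Re(out))] <- 0 + 0i
    out
  }
  wOf <- function(M) if (weighting == "amplitude") M else unit(M)
  O <- accumulateColumns(C, idxMat, n)
  trace <- sum(abs(O)^2)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxIter)) {
    iter <- it
    # input step: align each column's global phase with the accumulated spectrum
    Oval <- matrix(O[idxMat], nrow(C), nAng)
    g <- colSums(wOf(C) * Conj(wOf(Oval)))
    if (leaveOneOut) g <- g - colSums(wOf(C) * Conj(wOf(C)))
    alpha <- Arg(g)
    alpha[Mod(g) == 0] <- 0
    C <- sweep(C, 2L, exp(-1i * alpha), `*`)
    phiIn <- phiIn - alpha
    O <- accumulateColumns(C, idxMat, n)
    # output step: align each output-pupil pixel across angles
    Oval <- matrix(O[idxMat], nrow(C), nAng)
    h <- rowSums(wOf(C) * Conj(wOf(Oval)))
    if (leaveOneOut) h <- h - rowSums(wOf(C) * Conj(wOf(C)))
    beta <- Arg(h)
    beta[Mod(h) == 0] <- 0
    C <- C * exp(-1i * beta)
    phiOut <- phiOut - beta
    O <- accumulateColumns(C, idxMat, n)
    inew <- sum(abs(O)^2)
    trace <- c(trace, inew)
    gain <- (inew - trace[length(trace) - 1L]) / trace[length(trace) - 1L]
    if (abs(gain) < relTol) {
      converged <- TRUE
      break
    }
  }
  # the accumulated update cancels the aberration, so the aberration estimate
  # is the negative of the applied correction
  outMat <- matrix(0, n, n)
  outMat[R@rowIndex] <- -phiOut
  outMat <- reducePhaseGauge(outMat, grid@mask)
  inEst <- -phiIn
  inMat <- nearestAngleMap(inEst, R@illumKs, grid)
  inMat <- reducePhaseGauge(inMat, grid@mask)
  new("ClassResult",
      phaseIn = phaseMap(grid, inMat),
      phaseOut = phaseMap(grid, outMat),
      phiInAngles = inEst,
      objectSpectrum = matrix(O, n, n),
      intensityTrace = trace,
      iterations = iter,
      converged = converged)
}

#' @rdname classIterate
#' @param result a \code{ClassResult}.
#' @export
intensityTrace <- function(result) result@intensityTrace

#' @rdname classIterate
#' @export
phaseOut <- function(result) result@phaseOut

#' @rdname classIterate
#' @export
phaseIn <- function(result) result@phaseIn

#' @rdname classIterate
#' @export
objectSpectrum <- function(result) result@objectSpectrum

# spread per-angle phase samples onto the aperture by nearest-angle lookup
nearestAngleMap <- function(values, illumKs, grid) {
  idx <- which(grid@mask, arr.ind = TRUE)
  c0 <- gridCenter(grid)
  px <- idx[, 1] - c0
  py <- idx[, 2] - c0
  d2 <- outer(px^2, rep(1, nrow(illumKs))) -
    2 * outer(px, illumKs[, 1]) + outer(rep(1, length(px)), illumKs[, 1]^2) +
    outer(py^2, rep(1, nrow(illumKs))) -
    2 * outer(py, illumKs[, 2]) + outer(rep(1, length(py)), illumKs[, 2]^2)
  nn <- max.col(-d2, ties.method = "first")
  out <- matrix(0, grid@nPx, grid@nPx)
  out[grid@mask] <- values[nn]
  out
}

# remove piston and tip/tilt on the wrapped-phase (complex) representation:
# integer tilt from the spectral peak of exp(i phi), sub-pixel tilt from the
# mean wrapped phase gradient, piston from the circular mean; returns the
# reduced phase wrapped to (-pi, pi]
reducePhaseGauge <- function(phi, mask) {
  n <- nrow(phi)
  c0 <- n %/% 2L + 1L
  u <- matrix(0 + 0i, n, n)
  u[mask] <- exp(1i * phi[mask])
  F <- fft2c(u)
  pk <- which(abs(F) == max(abs(F)), arr.ind = TRUE)[1, ]
  tilt <- pk - c0
  x <- kOffsets(n)
  lin <- 2 * pi * (outer(x * tilt[1], x * tilt[2], "+")) / n
  u2 <- u * exp(-1i * lin)
  # sub-pixel tilt: mean wrapped gradient along each axis over the mask
  gx <- Arg(sum(u2[-1, ] * Conj(u2[-n, ]) * (mask[-1, ] & mask[-n, ])))
  gy <- Arg(sum(u2[, -1] * Conj(u2[, -n]) * (mask[, -1] & mask[, -n])))
  sub <- outer(x * gx, x * gy, "+")
  u2 <- u2 * exp(-1i * sub)
  piston <- Arg(sum(u2[mask]))
  out <- matrix(0, n, n)
  out[mask] <- Arg(u2[mask] * exp(-1i * piston))
  out
}

#' RMS of the wrapped phase residual after gauge removal
#'
#' Compares a recovered pupil phase with a reference modulo the recovery
#' degeneracies: the difference is wrapped to (-pi, pi], piston and tip/tilt
#' are removed (they trade against object position), and the aperture RMS of
#' what remains is returned.
#'
#' @param est,truth \code{PhaseMap}s on the same grid (or bare matrices with
#'   \code{mask} supplied).
#' @param mask optional logical aperture mask for matrix input.
#' @return residual RMS in radians.
#' @export
phaseResidualRms <- function(est, truth, mask = NULL) {
  if (is(est, "PhaseMap")) {
    mask <- est@grid@mask
    est <- est@phase
  }
  if (is(truth, "PhaseMap")) truth <- truth@phase
  d <- reducePhaseGauge(est - truth, mask)
  sqrt(mean(d[mask]^2))
}

#' Correction map from a CLASS result
#'
#' The correction displayed on the wavefront modulator is the opposite phase
#' of the recovered output-path aberration, optionally combined with a
#' pre-measured system aberration; piston and tip/tilt are removed and the
#' result is wrapped to (-pi, pi].
#'
#' @param result a \code{\linkS4class{ClassResult}}.
#' @param systemPhase optional \code{PhaseMap} of the static setup aberration.
#' @return a \code{PhaseMap}.
#' @export
correctionMap <- function(result, systemPhase = NULL) {
  grid <- result@phaseOut@grid
  corr <- -result@phaseOut@phase
  if (!is.null(systemPhase)) corr <- corr - systemPhase@phase
  phaseMap(grid, reducePhaseGauge(corr, grid@mask))
}

#' Per-patch CLASS over a segmented field of view
#'
#' Aberrations that vary across the field are recovered patch by patch: each
#' camera-plane field is windowed to a patch with a smooth Tukey (tapered
#' cosine, taper fraction 0.2) apodization, re-sampled onto the patch's own
#' frequency grid, and a reflection matrix is rebuilt and iterated per patch.
#' The flat-topped window keeps the spectral smoothing kernel narrow (the
#' window convolves the output-pupil phase factor, which biases the recovered
#' phase when the kernel is wide). Fractional illumination wavevectors on the
#' coarser patch grid are demodulated to the nearest integer frequency before
#' the transform.
#'
#' @param fields list of \code{\linkS4class{ComplexField}} (full FOV).
#' @param illumKs integer matrix of illumination wavevectors on the full grid.
#' @param patchPx patch side in pixels (>= 32).
#' @param overlapPx overlap between neighboring patches in pixels.
#' @param ... passed to \code{\link{classIterate}}.
#' @return list of per-patch results; each element has \code{region}
#'   (\code{c(row0, col0, patchPx)}, 1-based corner) and \code{result}
#'   (a \code{ClassResult} on the patch grid).
#' @export
subareaClass <- function(fields, illumKs, patchPx, overlapPx = 0L, ...) {
  grid <- fields[[1]]@grid
  n <- grid@nPx
  patchPx <- as.integer(patchPx)
  if (patchPx < 32L) stop("patch must be at least 32 px")
  if (patchPx > n) stop("patch larger than the field of view")
  step <- patchPx - as.integer(overlapPx)
  if (step < 1L) stop("overlap must be smaller than the patch")
  starts <- unique(pmin(seq(1L, n, by = step), n - patchPx + 1L))
  starts <- starts[starts >= 1L]
  pgrid <- makePupilGrid(patchPx, grid@pitchNm, grid@wavelengthNm, grid@na)
  # a patch covering the full FOV needs no apodization and reproduces the
  # whole-FOV iteration exactly
  win <- if (patchPx == n) matrix(1, n, n) else {
    w1 <- tukeyWindow(patchPx, 0.2)
    outer(w1, w1)
  }
  xloc <- seq_len(patchPx) - gridCenter(pgrid)
  out <- list()
  for (r0 in starts) for (c0 in starts) {
    pk <- illumKs * patchPx / n
    pkInt <- round(pk)
    pfields <- vector("list", length(fields))
    for (j in seq_along(fields)) {
      crop <- fields[[j]]@amplitude[r0:(r0 + patchPx - 1L),
                                    c0:(c0 + patchPx - 1L)] * win
      frac <- pk[j, ] - pkInt[j, ]
      demod <- exp(-2i * pi * (outer(xloc * frac[1], xloc * frac[2], "+")) / patchPx)
      pfields[[j]] <- complexField(pgrid, crop * demod)
    }
    res <- classIterate(buildReflectionMatrix(pfields, pkInt, pgrid), ...)
    out[[length(out) + 1L]] <- list(region = c(row0 = r0, col0 = c0,
                                               patchPx = patchPx),
                                    result = res)
  }
  out
}

# tapered-cosine window: flat over 1 - alpha of the support
tukeyWindow <- function(n, alpha = 0.2) {
  t <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Point-scatterer phantom and angle-scan fixtures
#'
#' \code{pointScatterPhantom} draws a sparse complex reflectance map of point
#' scatterers with random amplitude and phase; \code{spiralAngles} samples the
#' aperture disk uniformly with a Vogel (golden-angle) spiral rounded to grid
#' pixels; \code{simulateAngleScan} renders the full set of reflectance fields
#' for one aberration pair.
#'
#' @param grid a \code{PupilGrid}.
#' @param nScatter number of point scatterers.
#' @param seed integer seed.
#' @param amplitudeRange scatterer amplitude range.
#' @return \code{pointScatterPhantom}: complex matrix;
#'   \code{spiralAngles}: integer matrix (n x 2) of wavevector offsets;
#'   \code{simulateAngleScan}: list of \code{ComplexField}.
#' @export
pointScatterPhantom <- function(grid, nScatter, seed = 1L,
                                amplitudeRange = c(0.5, 1.5)) {
  n <- grid@nPx
  obj <- matrix(0 + 0i, n, n)
  withSeed(seed, {
    pos <- cbind(sample(n, nScatter, replace = TRUE),
                 sample(n, nScatter, replace = TRUE))
    amp <- stats::runif(nScatter, amplitudeRange[1], amplitudeRange[2])
    ph <- stats::runif(nScatter, 0, 2 * pi)
    obj[pos] <- obj[pos] + amp * exp(1i * ph)
  })
  obj
}

#' @rdname pointScatterPhantom
#' @param nAngles number of illumination angles.
#' @param fillFraction fraction of the aperture radius covered by the scan.
#' @export
spiralAngles <- function(grid, nAngles, fillFraction = 0.9) {
  r <- apertureRadiusPx(grid) * fillFraction
  i <- seq_len(nAngles)
  rho <- r * sqrt(i / nAngles)
  th <- i * 2.39996322972865332
  ks <- unique(cbind(as.integer(round(rho * cos(th))),
                     as.integer(round(rho * sin(th)))))
  ks
}

#' @rdname pointScatterPhantom
#' @param objectMap complex reflectance map.
#' @param illumKs integer matrix of illumination wavevectors.
#' @param phaseIn,phaseOut input/output aberration \code{PhaseMap}s.
#' @export
simulateAngleScan <- function(objectMap, illumKs, phaseIn, phaseOut) {
  lapply(seq_len(nrow(illumKs)), function(j) {
    reflectanceField(objectMap, illumKs[j, ], phaseIn, phaseOut)
  })
}

#' Additive complex Gaussian noise on a reflection matrix
#'
#' @param R a \code{ReflectionMatrix}.
#' @param snrDb signal-to-noise ratio in dB (mean entry power over noise
#'   power).
#' @param seed integer seed.
#' @return a noisy \code{ReflectionMatrix}.
#' @export
addReflectionNoise <- function(R, snrDb, seed = 1L) {
  p <- mean(abs(R@entries)^2)
  nv <- p / 10^(snrDb / 10)
  e <- R@entries
  withSeed(seed, {
    e <- e + sqrt(nv / 2) * (matrix(stats::rnorm(length(e)), nrow(e)) +
                               1i * matrix(stats::rnorm(length(e)), nrow(e)))
  })
  initialize(R, entries = e)
}
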