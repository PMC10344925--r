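# Quantitative SMLM analyses: nearest-neighbor precision, Fourier ring
# correlation, ensemble PSF width, localization-number and Nyquist scaling,
# and photon statistics.

#' Consecutive-frame nearest-neighbor displacements
#'
#' For every localization in frame t, the Euclidean distance to its nearest
#' neighbor among the localizations of frame t+1 (strictly consecutive
#' frames; frames with an empty successor contribute nothing). Ties are
#' broken by smallest distance, then lowest row index. Repeated localization
#' of the same molecule makes these displacements Rayleigh-distributed with
#' scale sigma*sqrt(2), which is what the precision fit exploits.
#'
#' @param table localization \code{data.frame} (\code{frame, x_nm, y_nm}).
#' @param minPairs below this pair count a warning is attached.
#' @return numeric vector of displacements (nm), possibly empty, with
#'   attribute \code{lowCount} when fewer than \code{minPairs}.
#' @export
nnPairwiseDisplacements <- function(table, minPairs = 100L) {
  if (nrow(table) == 0L) return(numeric(0))
  frames <- sort(unique(table$frame))
  byFrame <- split(seq_len(nrow(table)), table$frame)
  d <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    nxt <- as.character(frames[i] + 1L)
    cur <- as.character(frames[i])
    if (is.null(byFrame[[nxt]])) next
    a <- table[byFrame[[cur]], c("x_nm", "y_nm"), drop = FALSE]
    b <- table[byFrame[[nxt]], c("x_nm", "y_nm"), drop = FALSE]
    dd <- sqrt(outer(a$x_nm, b$x_nm, "-")^2 + outer(a$y_nm, b$y_nm, "-")^2)
    d[[i]] <- apply(dd, 1L, min)
  }
  out <- unlist(d)
  if (is.null(out)) out <- numeric(0)
  if (length(out) < minPairs) {
    warning("only ", length(out), " nearest-neighbor pairs (minimum ",
            minPairs, " recommended)")
    attr(out, "lowCount") <- TRUE
  }
  out
}

# two-term displacement density: Rayleigh term (precision) + Gaussian
# correction term for nearest neighbors that are different molecules
nnModel <- function(d, a1, sigma, a2, omega, dC) {
  a1 * d / (2 * sigma^2) * exp(-d^2 / (4 * sigma^2)) +
    a2 / sqrt(2 * pi * omega^2) * exp(-(d - dC)^2 / (2 * omega^2))
}

#' Fit the nearest-neighbor localization-precision model
#'
#' Histograms the pairwise displacements and fits the envelope by nonlinear
#' least squares to the two-term model
#' \deqn{p(d) = A_1 \frac{d}{2\sigma^2} e^{-d^2/(4\sigma^2)} +
#'       A_2 (2\pi\omega^2)^{-1/2} e^{-(d-d_C)^2/(2\omega^2)}}
#' whose first term is the Rayleigh density of the distance between two
#' independent position estimates with per-axis precision \eqn{\sigma};
#' \eqn{\sigma} is reported as THE localization precision. The Gaussian term
#' (center \eqn{d_C}, width \eqn{\omega}) absorbs pairs formed by different
#' molecules in proximity.
#'
#' @param displacements numeric vector of displacements in nm.
#' @param binWidthNm histogram bin width (default 5 nm).
#' @param dMaxNm histogram upper limit (default 300 nm).
#' @param weighted use Poisson-weighted least squares on the bin counts
#'   (default FALSE, plain least squares).
#' @return an \code{\linkS4class{NNPrecisionFit}}.
#' @export
fitNNPrecision <- function(displacements, binWidthNm = 5, dMaxNm = 300,
                           weighted = FALSE) {
  displacements <- displacements[is.finite(displacements)]
  if (length(displacements) < 100L)
    stop("need at least 100 displacements for a stable fit")
  # degenerate limit: essentially identical positions
  if (stats::quantile(displacements, 0.95) < binWidthNm) {
    s <- stats::sd(displacements) / sqrt(2)
    return(new("NNPrecisionFit", sigmaNm = min(s, binWidthNm / 2),
               omegaNm = binWidthNm, dCNm = 0, a1 = 1, a2 = 0,
               binEdges = c(0, binWidthNm), histogram = 1 / binWidthNm,
               fitResidual = 0, nDisplacements = length(displacements),
               degenerate = TRUE))
  }
  edges <- seq(0, dMaxNm, by = binWidthNm)
  keep <- displacements < dMaxNm
  h <- graphics::hist(displacements[keep], breaks = edges, plot = FALSE)
  dens <- h$counts / (length(displacements) * binWidthNm)
  mids <- h$mids
  # initial guesses: Rayleigh mode at sigma*sqrt(2); second-population
  # center from the upper-tail mode
  modeBin <- mids[which.max(dens)]
  s0 <- max(modeBin / sqrt(2), binWidthNm / 2)
  tail <- mids > 2.5 * modeBin
  dC0 <- if (any(tail) && max(dens[tail]) > 0)
    mids[tail][which.max(dens[tail])] else min(2.5 * modeBin, dMaxNm * 0.7)
  w <- if (weighted) 1 / sqrt(pmax(h$counts, 1)) else rep(1, length(mids))
  residFun <- function(p) {
    w * (nnModel(mids, p[1], p[2], p[3], p[4], p[5]) - dens)
  }
  start <- c(a1 = 0.8, sigma = s0, a2 = 0.2, omega = 4 * binWidthNm,
             dC = max(dC0, 2.5 * modeBin))
  # the correction term models *different-molecule* pairs, which lie beyond
  # the same-molecule Rayleigh bulk: keeping d_C off the main peak stops the
  # Gaussian from eating the Rayleigh flank on single-population data
  fit <- minpack.lm::nls.lm(
    par = start, fn = residFun,
    lower = c(0, binWidthNm / 10, 0, binWidthNm / 2, 2.5 * modeBin),
    upper = c(2, dMaxNm, 2, dMaxNm, dMaxNm),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info < 1 || fit$info > 4 || any(!is.finite(fit$par)))
    stop("nearest-neighbor precision fit did not converge (status ",
         fit$info, ", n = ", length(displacements),
         ", mode at ", modeBin, " nm)")
  p <- fit$par
  new("NNPrecisionFit", sigmaNm = p[["sigma"]], omegaNm = p[["omega"]],
      dCNm = p[["dC"]], a1 = p[["a1"]], a2 = p[["a2"]],
      binEdges = edges, histogram = dens,
      fitResidual = sqrt(mean((nnModel(mids, p[1], p[2], p[3], p[4], p[5]) -
                                 dens)^2)),
      nDisplacements = length(displacements), degenerate = FALSE)
}

#' @rdname fitNNPrecision
#' @param x an \code{NNPrecisionFit}.
#' @export
precisionSigma <- function(x) x@sigmaNm

#' Fourier ring correlation resolution
#'
#' Splits the localizations into two half-datasets (odd/even frames by
#' default, or a random half split), renders each as a 2-D position
#' histogram, and correlates the two Fourier transforms ring by ring. The
#' curve is lightly smoothed (running mean over 3 rings) and the resolution
#' is the inverse frequency of the first downward crossing of the fixed 1/7
#' threshold.
#'
#' @param table localization \code{data.frame}.
#' @param renderPxNm rendering pixel for the half-images (default 5 nm).
#' @param splitMode \code{"odd_even"} or \code{"random"}.
#' @param threshold FRC threshold (default 1/7).
#' @param fovNm optional field-of-view side; defaults to the data extent.
#' @param seed seed for the random split.
#' @return an \code{\linkS4class{FrcCurve}}.
#' @export
frcResolution <- function(table, renderPxNm = 5, splitMode = c("odd_even", "random"),
                          threshold = 1 / 7, fovNm = NULL, seed = 1L) {
  splitMode <- match.arg(splitMode)
  if (nrow(table) < 10L) stop("too few localizations for an FRC estimate")
  sel <- if (splitMode == "odd_even") table$frame %% 2L == 1L
         else withSeed(seed, stats::runif(nrow(table)) < 0.5)
  if (is.null(fovNm)) fovNm <- max(table$x_nm, table$y_nm)
  n <- 2L^ceiling(log2(max(64, fovNm / renderPxNm)))
  render <- function(sub) {
    img <- matrix(0, n, n)
    ix <- pmin(pmax(floor(sub$x_nm / renderPxNm) + 1L, 1L), n)
    iy <- pmin(pmax(floor(sub$y_nm / renderPxNm) + 1L, 1L), n)
    for (k in seq_along(ix)) img[ix[k], iy[k]] <- img[ix[k], iy[k]] + 1
    img
  }
  f1 <- fft2c(render(table[sel, , drop = FALSE]))
  f2 <- fft2c(render(table[!sel, , drop = FALSE]))
  k <- kOffsets(n)
  ring <- round(sqrt(outer(k^2, k^2, "+")))
  maxRing <- n %/% 2L - 1L
  num <- Re(tapply(f1 * Conj(f2), ring, sum))
  p1 <- tapply(abs(f1)^2, ring, sum)
  p2 <- tapply(abs(f2)^2, ring, sum)
  rings <- as.integer(names(num))
  keep <- rings >= 1L & rings <= maxRing
  frc <- num[keep] / sqrt(p1[keep] * p2[keep])
  frc[!is.finite(frc)] <- 0
  frc <- pmax(pmin(frc, 1), -1)
  # running-mean smoothing over 3 rings
  sm <- stats::filter(frc, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- frc[is.na(sm)]
  freqs <- rings[keep] / (n * renderPxNm)   # cycles per nm
  below <- which(sm < threshold)
  if (length(below) == 0L || below[1] == 1L) {
    resolved <- length(below) > 0L
    resNm <- if (resolved) 1 / freqs[below[1]] else NA_real_
  } else {
    i <- below[1]
    f0 <- freqs[i - 1] + (sm[i - 1] - threshold) / (sm[i - 1] - sm[i]) *
      (freqs[i] - freqs[i - 1])
    resNm <- 1 / f0
    resolved <- TRUE
  }
  new("FrcCurve", ringFreqs = freqs, correlation = as.numeric(frc),
      resolutionNm = resNm, resolved = resolved,
      splitMode = splitMode, threshold = threshold)
}

#' @rdname frcResolution
#' @param x an \code{FrcCurve}.
#' @export
frcValue <- function(x) x@resolutionNm

#' Nyquist resolution enhancement from a localization-density ratio
#'
#' In two dimensions the density-limited (Nyquist) resolution scales as
#' density^(-1/2) over a fixed area, so an N-fold localization-number
#' increase improves the Nyquist resolution by sqrt(N).
#'
#' @param localizationRatio localization-number ratio (> 0).
#' @return the resolution enhancement factor, \code{sqrt(localizationRatio)}.
#' @examples
#' nyquistEnhancement(37.4)   # ~6.12
#' @export
nyquistEnhancement <- function(localizationRatio) {
  stopifnot(all(localizationRatio > 0))
  sqrt(localizationRatio)
}

#' Ensemble-averaged PSF and its width
#'
#' Crops a window around every accepted localization within the first
#' \code{firstNFrames} frames, aligns the crops at their sub-pixel centroids
#' (exact Fourier shift, which does not broaden band-limited PSFs the way
#' bilinear resampling would), averages, normalizes to unit peak, and
#' measures the FWHM.
#'
#' @param stack a \code{\linkS4class{FrameStack}}.
#' @param table its localization table.
#' @param firstNFrames frames to include (default all).
#' @param windowPx odd crop window in pixels (default 15).
#' @param align disable to average without sub-pixel alignment.
#' @return list with \code{psf} (matrix, unit peak), \code{fwhmNm} and
#'   \code{nUsed}.
#' @export
ensembleAveragePsf <- function(stack, table, firstNFrames = Inf,
                               windowPx = 15L, align = TRUE) {
  camera <- stack@camera
  px <- camera$pixelNm
  rows <- table[table$frame <= firstNFrames, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no localizations within the requested frames")
  half <- windowPx %/% 2L
  n <- dim(stack@frames)
  acc <- matrix(0, windowPx, windowPx)
  used <- 0L
  for (i in seq_len(nrow(rows))) {
    cx <- rows$x_nm[i] / px + 0.5     # pixel-center coordinates
    cy <- rows$y_nm[i] / px + 0.5
    r0 <- round(cx); c0 <- round(cy)
    if (r0 - half - 1 < 1 || r0 + half + 1 > n[1] ||
        c0 - half - 1 < 1 || c0 + half + 1 > n[2]) next
    img <- countsToPhotons(stack@frames[, , rows$frame[i]], camera)
    crop <- img[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
    if (align) {
      # exact sub-pixel shift by a Fourier phase ramp (wrap-around at the
      # window edge is negligible for a centered, decaying PSF)
      fr <- cx - r0; fc <- cy - c0
      k <- c(0:(half), (-half):(-1)) / windowPx
      ramp <- exp(2i * pi * outer(k * fr, k * fc, "+"))
      crop <- Re(stats::fft(stats::fft(crop) * ramp, inverse = TRUE)) /
        windowPx^2
    }
    acc <- acc + crop - stats::median(crop)
    used <- used + 1L
  }
  if (used == 0L) stop("no localizations far enough from the border")
  psf <- acc / max(acc)
  list(psf = psf, fwhmNm = fwhm2d(psf, pitchNm = px), nUsed = used)
}

#' Localization-number ratio inside a region of interest
#'
#' @param tableOn,tableOff localization tables of the corrected and
#'   uncorrected channels (same field of view).
#' @param roi optional list with \code{xmin, xmax, ymin, ymax} in nm.
#' @return list with \code{ratio} (\code{Inf} flagged when the uncorrected
#'   count is zero), \code{nOn}, \code{nOff}.
#' @export
localizationNumberRatio <- function(tableOn, tableOff, roi = NULL) {
  inRoi <- function(t) {
    if (is.null(roi)) rep(TRUE, nrow(t))
    else t$x_nm >= roi$xmin & t$x_nm <= roi$xmax &
      t$y_nm >= roi$ymin & t$y_nm <= roi$ymax
  }
  nOn <- sum(inRoi(tableOn))
  nOff <- sum(inRoi(tableOff))
  list(ratio = if (nOff == 0L) Inf else nOn / nOff,
       nOn = nOn, nOff = nOff, offEmpty = nOff == 0L)
}

#' Photon-number histogram per emission PSF
#'
#' @param table localization table (non-empty).
#' @param binWidth bin width in photons.
#' @return list with \code{breaks}, \code{counts}, \code{median}, \code{mean}.
#' @export
photonHistogram <- function(table, binWidth = 250) {
  if (nrow(table) == 0L) stop("empty localization table")
  ph <- table$photons
  breaks <- seq(0, max(ph) + binWidth, by = binWidth)
  h <- graphics::hist(ph, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts,
       median = stats::median(ph), mean = mean(ph))
}
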