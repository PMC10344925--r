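# Single-molecule detection and sub-pixel Gaussian fitting. The pipeline
# mirrors the standard SMLM chain: counts-to-photons calibration, band-pass
# (difference-of-Gaussians) filtering, thresholded local-maximum detection
# with non-maximum suppression, and least-squares fitting of a symmetric 2-D
# Gaussian plus constant offset in a small window around each candidate.

# convert raw counts to expected photons using the camera metadata; the EM
# excess-noise factor is deliberately ignored (documented estimator bias)
countsToPhotons <- function(img, camera) {
  (img - camera$baseline) / (camera$emGain * camera$qe)
}

#' Detect single-molecule candidates in one frame
#'
#' The calibrated frame is band-pass filtered with a difference of Gaussians
#' (sigma 1 px and 2.5 px); local maxima of the filtered image above
#' \code{thresholdFactor} times a robust noise estimate are kept, with
#' non-maximum suppression inside the fitting window and a border margin.
#' The noise level is the MAD-based standard deviation of the raw frame's
#' high-frequency residual (frame minus its 1 px Gaussian smooth) — the
#' difference-of-Gaussians analogue of thresholding the wavelet detection
#' image against the first wavelet level's standard deviation, as the
#' reference SMLM software does by default.
#'
#' @param frameImage numeric matrix of raw counts.
#' @param camera camera model list (for counts-to-photons calibration).
#' @param thresholdFactor detection threshold in robust noise units.
#' @param windowPx fitting window (odd); candidates closer than half a window
#'   to the border or to a brighter candidate are dropped.
#' @param sigmaSmall,sigmaLarge DoG filter widths in pixels.
#' @return integer matrix (n x 2) of candidate pixel coordinates (row, col);
#'   zero rows when nothing is found.
#' @export
detectCandidates <- function(frameImage, camera = cameraModel(),
                             thresholdFactor = 3, windowPx = 7L,
                             sigmaSmall = 1, sigmaLarge = 2.5) {
  ph <- countsToPhotons(frameImage, camera)
  smooth1 <- EBImage::gblur(ph, sigma = sigmaSmall)
  dog <- smooth1 - EBImage::gblur(ph, sigma = sigmaLarge)
  noise <- stats::mad(ph - smooth1)
  thr <- thresholdFactor * noise
  n <- dim(dog)
  # 8-neighborhood local maxima
  pad <- matrix(-Inf, n[1] + 2L, n[2] + 2L)
  pad[2:(n[1] + 1L), 2:(n[2] + 1L)] <- dog
  isMax <- dog >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    isMax <- isMax & dog >= pad[(2:(n[1] + 1L)) + dr, (2:(n[2] + 1L)) + dc]
  }
  cand <- which(isMax, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(cand)
  half <- windowPx %/% 2L
  inb <- cand[, 1] > half & cand[, 1] <= n[1] - half &
    cand[, 2] > half & cand[, 2] <= n[2] - half
  cand <- cand[inb, , drop = FALSE]
  if (nrow(cand) <= 1L) return(cand)
  # greedy non-maximum suppression within the fitting window
  o <- order(dog[cand], decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand) - 1L)) {
    if (!keep[i]) next
    later <- (i + 1L):nrow(cand)
    close <- abs(cand[later, 1] - cand[i, 1]) <= half &
      abs(cand[later, 2] - cand[i, 2]) <= half
    keep[later][close] <- FALSE
  }
  cand[keep, , drop = FALSE]
}

#' Fit one candidate with a symmetric 2-D Gaussian
#'
#' Levenberg-Marquardt least squares of
#' \code{b + A exp(-((x-x0)^2 + (y-y0)^2) / (2 s^2))} on the photon-calibrated
#' window. A fit is rejected (reason returned, never raised) on
#' non-convergence, a centroid outside the window, a width outside
#' \code{sigmaRange} times the nominal PSF width, or a non-positive
#' amplitude. The integrated signal is the ThunderSTORM convention
#' \code{2 pi A s^2}; the per-row uncertainty is the Thompson-style
#' \code{sqrt((s^2 + a^2/12)/N + 8 pi s^4 b/(a^2 N^2))} with the background
#' variance approximated by the fitted offset.
#'
#' @param frameImage numeric matrix of raw counts.
#' @param candidate integer length-2 (row, col) pixel.
#' @param camera camera model list.
#' @param windowPx odd window side in pixels.
#' @param nominalSigmaPx expected PSF Gaussian width in pixels.
#' @param sigmaRange acceptance band on the fitted width, as multiples of
#'   \code{nominalSigmaPx}.
#' @return list with \code{ok}; when \code{ok} is TRUE also \code{xPx, yPx}
#'   (sub-pixel centroid, pixel units), \code{sigmaPx}, \code{photons},
#'   \code{background} (photons/pixel), \code{uncertaintyPx}; otherwise
#'   \code{reason}.
#' @export
fitGaussian <- function(frameImage, candidate, camera = cameraModel(),
                        windowPx = 7L, nominalSigmaPx = 1.1,
                        sigmaRange = c(0.5, 3)) {
  half <- windowPx %/% 2L
  n <- dim(frameImage)
  r0 <- candidate[1]; c0 <- candidate[2]
  if (r0 - half < 1 || r0 + half > n[1] || c0 - half < 1 || c0 + half > n[2])
    return(list(ok = FALSE, reason = "border"))
  win <- countsToPhotons(frameImage[(r0 - half):(r0 + half),
                                    (c0 - half):(c0 + half)], camera)
  if (max(win) - min(win) <= 0)
    return(list(ok = FALSE, reason = "flat"))
  xs <- rep(seq_len(windowPx), times = windowPx)
  ys <- rep(seq_len(windowPx), each = windowPx)
  z <- as.vector(win)
  b0 <- stats::median(z)
  a0 <- max(z) - b0
  w <- pmax(z - b0, 0)
  x0 <- if (sum(w) > 0) sum(xs * w) / sum(w) else half + 1
  y0 <- if (sum(w) > 0) sum(ys * w) / sum(w) else half + 1
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      z ~ b + A * exp(-((xs - mx)^2 + (ys - my)^2) / (2 * s^2)),
      start = list(b = b0, A = a0, mx = x0, my = y0, s = nominalSigmaPx),
      lower = c(b = -Inf, A = 0, mx = 1, my = 1, s = 0.2),
      upper = c(b = Inf, A = Inf, mx = windowPx, my = windowPx, s = windowPx),
      control = minpack.lm::nls.lm.control(maxiter = 60)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(list(ok = FALSE, reason = "no_convergence"))
  p <- stats::coef(fit)
  if (p[["A"]] <= 0) return(list(ok = FALSE, reason = "non_positive_amplitude"))
  if (p[["s"]] < sigmaRange[1] * nominalSigmaPx ||
      p[["s"]] > sigmaRange[2] * nominalSigmaPx)
    return(list(ok = FALSE, reason = "sigma_out_of_range"))
  if (p[["mx"]] < 1.5 || p[["mx"]] > windowPx - 0.5 ||
      p[["my"]] < 1.5 || p[["my"]] > windowPx - 0.5)
    return(list(ok = FALSE, reason = "centroid_outside_window"))
  photons <- 2 * pi * p[["A"]] * p[["s"]]^2
  bgVar <- max(p[["b"]], 0)
  unc <- sqrt((p[["s"]]^2 + 1 / 12) / photons +
                8 * pi * p[["s"]]^4 * bgVar / photons^2)
  list(ok = TRUE,
       xPx = r0 - half - 1 + p[["mx"]],
       yPx = c0 - half - 1 + p[["my"]],
       sigmaPx = p[["s"]],
       photons = photons,
       background = p[["b"]],
       uncertaintyPx = unc)
}

#' Localize a full frame stack
#'
#' Runs detection and Gaussian fitting on every frame. When a fitted centroid
#' lands more than half a pixel from its window center the window is
#' re-centered there and the spot re-fitted once (reduces truncation bias for
#' sub-pixel positions).
#'
#' @param stack a \code{\linkS4class{FrameStack}}.
#' @param thresholdFactor,windowPx,nominalSigmaPx,sigmaRange see
#'   \code{\link{detectCandidates}} and \code{\link{fitGaussian}}.
#' @return a localization table: \code{data.frame} with columns \code{frame}
#'   (1-based), \code{x_nm}, \code{y_nm}, \code{sigma_nm}, \code{photons},
#'   \code{background}, \code{uncertainty_nm}, sorted by frame. The x axis is
#'   the matrix row direction (consistent with \code{EmitterSet} positions).
#' @export
localizeStack <- function(stack, thresholdFactor = 3, windowPx = 7L,
                          nominalSigmaPx = 1.1, sigmaRange = c(0.5, 3)) {
  camera <- stack@camera
  px <- camera$pixelNm
  nF <- dim(stack@frames)[3]
  rows <- vector("list", nF)
  for (f in seq_len(nF)) {
    img <- stack@frames[, , f]
    cand <- detectCandidates(img, camera, thresholdFactor, windowPx)
    if (nrow(cand) == 0L) next
    got <- list()
    for (i in seq_len(nrow(cand))) {
      fit <- fitGaussian(img, cand[i, ], camera, windowPx,
                         nominalSigmaPx, sigmaRange)
      if (fit$ok) {
        # one re-centering pass for off-center windows
        newC <- c(round(fit$xPx), round(fit$yPx))
        if (any(abs(newC - cand[i, ]) >= 1)) {
          fit2 <- fitGaussian(img, newC, camera, windowPx,
                              nominalSigmaPx, sigmaRange)
          if (fit2$ok) fit <- fit2
        }
      }
      if (fit$ok)
        got[[length(got) + 1L]] <- data.frame(
          frame = f,
          x_nm = unname((fit$xPx - 0.5) * px),
          y_nm = unname((fit$yPx - 0.5) * px),
          sigma_nm = unname(fit$sigmaPx * px),
          photons = unname(fit$photons),
          background = unname(fit$background),
          uncertainty_nm = unname(fit$uncertaintyPx * px))
    }
    if (length(got)) rows[[f]] <- do.call(rbind, got)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                      sigma_nm = numeric(), photons = numeric(),
                      background = numeric(), uncertainty_nm = numeric())
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- ThunderSTORM CSV dialect ---------------------------------------------

tsHeader <- c("id", "frame", "x [nm]", "y [nm]", "sigma [nm]",
              "intensity [photon]", "offset [photon]", "uncertainty [nm]")

#' Write / read localization tables in the ThunderSTORM CSV dialect
#'
#' \code{writeLocalizations} writes the quoted header
#' \code{"id","frame","x [nm]","y [nm]","sigma [nm]","intensity [photon]",
#' "offset [photon]","uncertainty [nm]"}. \code{readLocalizations} tolerates
#' column reordering and the common export variants (\code{uncertainty_xy},
#' missing id/offset columns).
#'
#' @param table localization \code{data.frame} from
#'   \code{\link{localizeStack}}.
#' @param path CSV file path.
#' @return \code{readLocalizations} returns a localization \code{data.frame}
#'   in the package's column convention.
#' @export
writeLocalizations <- function(table, path) {
  df <- data.frame(
    id = seq_len(nrow(table)),
    frame = table$frame,
    x = table$x_nm, y = table$y_nm, sigma = table$sigma_nm,
    intensity = table$photons, offset = table$background,
    uncertainty = table$uncertainty_nm)
  names(df) <- tsHeader
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pick <- function(cands, default = NA_real_) {
    hit <- intersect(cands, names(df))
    if (length(hit)) df[[hit[1]]] else rep(default, nrow(df))
  }
  out <- data.frame(
    frame = as.integer(pick(c("frame", "frames"))),
    x_nm = as.numeric(pick(c("x [nm]", "x"))),
    y_nm = as.numeric(pick(c("y [nm]", "y"))),
    sigma_nm = as.numeric(pick(c("sigma [nm]", "sigma1 [nm]", "sigma"))),
    photons = as.numeric(pick(c("intensity [photon]", "intensity"))),
    background = as.numeric(pick(c("offset [photon]", "offset", "bkgstd [photon]"))),
    uncertainty_nm = as.numeric(pick(c("uncertainty [nm]", "uncertainty_xy [nm]",
                                       "uncertainty"))))
  if (anyNA(out$frame) || anyNA(out$x_nm) || anyNA(out$y_nm))
    stop("file does not contain the required frame/x/y columns")
  out[order(out$frame), , drop = FALSE]
}
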