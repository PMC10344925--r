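# Disk formats: float TIFF (values rescaled to [0,1] with the affine scale
# recorded in a JSON sidecar) for phase maps, field stacks and frame stacks,
# plus wrapped-phase PNG for quick visual inspection. Every artifact carries
# its grid/camera metadata and seeds in the sidecar so it can be reproduced.

sidecarPath <- function(path) paste0(path, ".json")

scaleTo01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) hi <- lo + 1
  list(data = (x - lo) / (hi - lo), lo = lo, hi = hi)
}

gridMeta <- function(grid) {
  list(nPx = grid@nPx, pitchNm = grid@pitchNm,
       wavelengthNm = grid@wavelengthNm, na = grid@na)
}

gridFromMeta <- function(m) makePupilGrid(m$nPx, m$pitchNm, m$wavelengthNm, m$na)

#' Phase-map and stack serialization
#'
#' \code{writePhaseMapTiff}/\code{readPhaseMapTiff} store a
#' \code{\linkS4class{PhaseMap}} as a 32-bit TIFF (affinely rescaled to
#' [0, 1]; the scale and the grid parameters travel in a \code{.json}
#' sidecar). \code{writePhasePng} writes an 8-bit display PNG of the phase
#' wrapped to (-pi, pi].
#'
#' @param phase a \code{PhaseMap}.
#' @param path output file path (sidecar written at \code{<path>.json}).
#' @return the path, invisibly; readers return the reconstructed object.
#' @export
writePhaseMapTiff <- function(phase, path) {
  s <- scaleTo01(phase@phase)
  tiff::writeTIFF(s$data, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(type = "PhaseMap", lo = s$lo, hi = s$hi, grid = gridMeta(phase@grid)),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhaseMapTiff
#' @export
readPhaseMapTiff <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  phaseMap(gridFromMeta(meta$grid), m * (meta$hi - meta$lo) + meta$lo)
}

#' @rdname writePhaseMapTiff
#' @export
writePhasePng <- function(phase, path) {
  w <- (Arg(exp(1i * phase@phase)) + pi) / (2 * pi)
  w[!phase@grid@mask] <- 0
  png::writePNG(w, path)
  invisible(path)
}

#' Angle-scan field stacks on disk
#'
#' Complex camera-plane fields are stored as a multi-page 32-bit TIFF with
#' two pages (real, imaginary; rescaled to [0, 1]) per illumination angle;
#' the sidecar records the per-page scales, the illumination wavevectors,
#' the grid, and optionally the ground-truth aberration coefficients.
#'
#' @param fields list of \code{\linkS4class{ComplexField}}.
#' @param illumKs integer matrix of illumination wavevectors.
#' @param path output TIFF path.
#' @param truthCoeffs optional numeric ground-truth Zernike coefficients.
#' @param seed integer seed recorded for provenance.
#' @return the path, invisibly; \code{readFieldStackTiff} returns a list with
#'   \code{fields}, \code{illumKs}, \code{grid}, \code{truthCoeffs}.
#' @export
writeFieldStackTiff <- function(fields, illumKs, path, truthCoeffs = NULL,
                                seed = NA_integer_) {
  pages <- list()
  scales <- matrix(0, 2L * length(fields), 2L)
  for (j in seq_along(fields)) {
    sr <- scaleTo01(Re(fields[[j]]@amplitude))
    si <- scaleTo01(Im(fields[[j]]@amplitude))
    pages[[2L * j - 1L]] <- sr$data
    pages[[2L * j]] <- si$data
    scales[2L * j - 1L, ] <- c(sr$lo, sr$hi)
    scales[2L * j, ] <- c(si$lo, si$hi)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(type = "FieldStack", nAngles = length(fields),
         illumKs = unname(as.matrix(illumKs)), scales = scales,
         grid = gridMeta(fields[[1]]@grid),
         truthCoeffs = truthCoeffs, seed = seed,
         package = as.character(utils::packageVersion("aoclass"))),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFieldStackTiff
#' @export
readFieldStackTiff <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  grid <- gridFromMeta(meta$grid)
  unscale <- function(p, s) p * (s[2] - s[1]) + s[1]
  fields <- lapply(seq_len(meta$nAngles), function(j) {
    re <- unscale(pages[[2L * j - 1L]], meta$scales[2L * j - 1L, ])
    im <- unscale(pages[[2L * j]], meta$scales[2L * j, ])
    complexField(grid, re + 1i * im)
  })
  list(fields = fields, illumKs = matrix(as.integer(meta$illumKs), ncol = 2L),
       grid = grid, truthCoeffs = meta$truthCoeffs, seed = meta$seed)
}

#' Frame stacks as 16-bit multi-page TIFF
#'
#' Counts are stored divided by 65535 (ImageJ-compatible 16-bit range); the
#' sidecar carries the camera metadata and channel tag.
#'
#' @param stack a \code{\linkS4class{FrameStack}}.
#' @param path output TIFF path.
#' @return the path invisibly; the reader returns a \code{FrameStack} (with a
#'   flat placeholder PSF phase, which is not stored).
#' @export
writeFrameStackTiff <- function(stack, path) {
  d <- dim(stack@frames)
  pages <- lapply(seq_len(d[3]), function(f)
    pmin(stack@frames[, , f], 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(type = "FrameStack", channel = stack@channel, nFrames = d[3],
         camera = stack@camera,
         psfGrid = gridMeta(stack@psfPhase@grid)),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFrameStackTiff
#' @export
readFrameStackTiff <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- round(pages[[f]] * 65535)
  g <- gridFromMeta(meta$psfGrid)
  new("FrameStack", frames = frames, channel = meta$channel,
      camera = as.list(meta$camera), psfPhase = phaseMap(g))
}
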