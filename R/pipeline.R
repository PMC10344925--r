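# End-to-end workbench: configuration, deterministic seed fan-out, and the
# demo pipeline simulation -> CLASS -> correction -> dual-channel SMLM ->
# metrics. Every stage seed is derived from one master seed, so a fixed
# configuration reproduces its report exactly.

#' Default run configuration
#'
#' Nested parameter set for the full pipeline. The reflection-side grid is
#' 128 px at 130 nm pitch (1.2 NA, 678 nm), scanned by 200 golden-spiral
#' illumination angles over a 50-scatterer phantom carrying a 100-mode
#' aberration of 2.5 rad RMS; the SMLM side renders a 64 px dual-channel
#' blinking movie of a filament mesh (3000 expected photons per on-frame with
#' per-burst exponential brightness, split 50/50 between channels) over a
#' 20 photon/px background.
#'
#' @param masterSeed integer master seed; all stage seeds derive from it.
#' @param outputDir optional directory for artifacts and the JSON report.
#' @return nested configuration list.
#' @export
defaultConfig <- function(masterSeed = 1L, outputDir = NULL) {
  list(
    masterSeed = as.integer(masterSeed),
    outputDir = outputDir,
    grid = list(nPx = 128L, pitchNm = 130, wavelengthNm = 678, na = 1.2),
    aberration = list(rms = 2.5, modeLo = 5L, modeHi = 100L, decay = 0.5),
    reflection = list(nAngles = 200L, nScatter = 50L, fillFraction = 0.9),
    classOpts = list(maxIter = 30L, relTol = 1e-4),
    smlm = list(fovPx = 64L, nFrames = 1500L, nEmitters = 250L,
                structure = "filament_mesh", structureParams = list(),
                pOn = 0.03, meanOnFrames = 3, photonsPerFrame = 3000,
                brightnessModel = "per_burst_exponential",
                backgroundPhotons = 20, split = 0.5, oversample = 4L),
    camera = list(emGain = 100, readNoiseE = 1, baseline = 100, qe = 0.9,
                  pixelNm = 130),
    localization = list(thresholdFactor = 3, windowPx = 7L,
                        nominalSigmaPx = 1.1),
    metrics = list(nnBinWidthNm = 5, nnDMaxNm = 300, frcRenderPxNm = 5,
                   psfWindowPx = 21L, psfFirstNFrames = 400L)
  )
}

#' Read / write / validate a YAML run configuration
#'
#' Unknown keys are rejected and missing ones filled from
#' \code{\link{defaultConfig}}; validation errors name the offending path.
#'
#' @param path YAML file.
#' @param config configuration list.
#' @return \code{readRunConfig} returns a validated configuration list.
#' @export
readRunConfig <- function(path) {
  validateConfig(yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname readRunConfig
#' @export
validateConfig <- function(config) {
  ref <- defaultConfig()
  bad <- setdiff(names(config), names(ref))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(ref, config)
  with(cfg$grid, {
    if (na * pitchNm / wavelengthNm >= 0.5)
      stop("grid: invalid sampling, na*pitchNm/wavelengthNm must be < 0.5")
  })
  if (cfg$aberration$rms < 0) stop("aberration.rms: must be >= 0")
  if (cfg$reflection$nAngles < 2) stop("reflection.nAngles: need at least 2")
  if (cfg$smlm$pOn < 0 || cfg$smlm$pOn >= 1) stop("smlm.pOn: must be in [0, 1)")
  if (cfg$smlm$split <= 0 || cfg$smlm$split >= 1)
    stop("smlm.split: must be in (0, 1)")
  cfg
}

#' Resample a pupil phase onto another grid
#'
#' Interpolates in the complex domain (bilinear on exp(i phi), then the
#' argument), which is insensitive to 2 pi wraps away from wrap contours;
#' source and target pixels are matched by physical spatial frequency.
#'
#' @param phase a \code{PhaseMap}.
#' @param newGrid target \code{PupilGrid} (same wavelength/NA expected).
#' @return a \code{PhaseMap} on \code{newGrid}.
#' @export
resamplePhaseMap <- function(phase, newGrid) {
  old <- phase@grid
  u <- matrix(0 + 0i, old@nPx, old@nPx)
  u[old@mask] <- exp(1i * phase@phase[old@mask])
  idx <- which(newGrid@mask, arr.ind = TRUE)
  cNew <- gridCenter(newGrid)
  cOld <- gridCenter(old)
  # physical frequency of each target pixel -> source pixel coordinates
  scale <- freqStep(newGrid) / freqStep(old)
  sr <- (idx[, 1] - cNew) * scale + cOld
  sc <- (idx[, 2] - cNew) * scale + cOld
  fr <- pmin(pmax(floor(sr), 1L), old@nPx - 1L)
  fc <- pmin(pmax(floor(sc), 1L), old@nPx - 1L)
  wr <- sr - fr; wc <- sc - fc
  val <- (1 - wr) * (1 - wc) * u[cbind(fr, fc)] +
    wr * (1 - wc) * u[cbind(fr + 1L, fc)] +
    (1 - wr) * wc * u[cbind(fr, fc + 1L)] +
    wr * wc * u[cbind(fr + 1L, fc + 1L)]
  out <- matrix(0, newGrid@nPx, newGrid@nPx)
  out[newGrid@mask] <- Arg(val)
  phaseMap(newGrid, out)
}

#' Simulate and store an angle-scanned reflection acquisition
#'
#' Draws the ground-truth aberration and scatterer phantom from the
#' configuration, renders the reflectance field for every illumination angle
#' (input and output path see the same pupil aberration), and, when
#' \code{dir} is given, writes the stack plus ground truth to disk.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @param dir optional output directory.
#' @return list with \code{fields}, \code{illumKs}, \code{grid},
#'   \code{truth} (aberration draw), \code{paths} (when written).
#' @export
simulateReflectionScan <- function(config, dir = NULL) {
  cfg <- validateConfig(config)
  g <- cfg$grid
  grid <- makePupilGrid(g$nPx, g$pitchNm, g$wavelengthNm, g$na)
  ab <- cfg$aberration
  truth <- randomAberration(ab$rms, grid, modeRange = ab$modeLo:ab$modeHi,
                            spectrumDecay = ab$decay,
                            seed = deriveSeed(cfg$masterSeed, "aberration"))
  illumKs <- spiralAngles(grid, cfg$reflection$nAngles,
                          cfg$reflection$fillFraction)
  phantom <- pointScatterPhantom(grid, cfg$reflection$nScatter,
                                 seed = deriveSeed(cfg$masterSeed, "phantom"))
  fields <- simulateAngleScan(phantom, illumKs, truth$phase, truth$phase)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fp <- file.path(dir, "reflection_fields.tif")
    writeFieldStackTiff(fields, illumKs, fp,
                        truthCoeffs = truth$coeffs@values,
                        seed = cfg$masterSeed)
    tp <- file.path(dir, "true_aberration.tif")
    writePhaseMapTiff(truth$phase, tp)
    paths <- list(fields = fp, truth = tp)
  }
  list(fields = fields, illumKs = illumKs, grid = grid, truth = truth,
       paths = paths)
}

#' Run CLASS on a stored (or in-memory) acquisition
#'
#' Builds the reflection matrix, iterates, and writes the recovered
#' aberration and its correction map (float TIFF + wrapped-phase PNG). When
#' ground truth is present a recovery report (residual RMS after gauge
#' removal) is added.
#'
#' @param scan either a directory containing \code{reflection_fields.tif}
#'   or the list returned by \code{\link{simulateReflectionScan}}.
#' @param dir optional output directory for maps and the recovery report.
#' @param ... passed to \code{\link{classIterate}}.
#' @return list with \code{result} (\code{ClassResult}), \code{correction}
#'   (\code{PhaseMap}) and \code{recoveryRms} (NA without ground truth).
#' @export
runClassScan <- function(scan, dir = NULL, ...) {
  if (is.character(scan)) {
    loaded <- readFieldStackTiff(file.path(scan, "reflection_fields.tif"))
    fields <- loaded$fields; illumKs <- loaded$illumKs; grid <- loaded$grid
    truthCoeffs <- loaded$truthCoeffs
  } else {
    fields <- scan$fields; illumKs <- scan$illumKs; grid <- scan$grid
    truthCoeffs <- scan$truth$coeffs@values
  }
  R <- buildReflectionMatrix(fields, illumKs, grid)
  result <- classIterate(R, ...)
  corr <- correctionMap(result)
  recoveryRms <- NA_real_
  if (!is.null(truthCoeffs))
    recoveryRms <- phaseResidualRms(result@phaseOut,
                                    zernikePhase(truthCoeffs, grid))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writePhaseMapTiff(result@phaseOut, file.path(dir, "recovered_aberration.tif"))
    writePhaseMapTiff(corr, file.path(dir, "correction_map.tif"))
    writePhasePng(corr, file.path(dir, "correction_map.png"))
    jsonlite::write_json(
      list(iterations = result@iterations, converged = result@converged,
           intensityTrace = result@intensityTrace,
           recoveryRms = recoveryRms),
      file.path(dir, "class_report.json"), auto_unbox = TRUE, digits = NA)
  }
  list(result = result, correction = corr, recoveryRms = recoveryRms)
}

#' Full dual-channel demo pipeline
#'
#' Chains every stage: reflection-scan simulation, CLASS aberration recovery,
#' correction-map generation, matched AO-off/AO-on blinking-movie rendering,
#' localization of both channels, and the quantitative comparison
#' (localization-number ratio, nearest-neighbor precision pair, ensemble-PSF
#' FWHM pair, Strehl pair, FRC pair). Metrics whose inputs are insufficient
#' in a channel (e.g. too few uncorrected localizations) are reported as NA
#' with a reason rather than failing the run.
#'
#' @param config configuration list; see \code{\link{defaultConfig}}.
#' @return report list (also written to \code{outputDir/report.json} when an
#'   output directory is configured).
#' @export
fullDemo <- function(config = defaultConfig()) {
  cfg <- validateConfig(config)
  t0 <- Sys.time()
  # --- stage 1-2: reflection scan + CLASS --------------------------------
  scan <- withStage("simulate-reflection", simulateReflectionScan(cfg))
  cls <- withStage("run-class", runClassScan(scan, maxIter = cfg$classOpts$maxIter,
                                             relTol = cfg$classOpts$relTol))
  # --- stage 3: transfer phases to the SMLM render grid ------------------
  sm <- cfg$smlm
  rg <- renderGrid(sm$fovPx, cfg$camera, cfg$grid$wavelengthNm, cfg$grid$na,
                   sm$oversample)
  aberrRender <- zernikePhase(scan$truth$coeffs, rg)
  corrRender <- resamplePhaseMap(cls$correction, rg)
  residual <- phaseMap(rg, aberrRender@phase + corrRender@phase)
  # --- stage 4: dual-channel blinking movie ------------------------------
  emitters <- withStage("simulate-smlm", structureFixture(
    sm$structure, fovNm = sm$fovPx * cfg$camera$pixelNm,
    nEmitters = sm$nEmitters, params = sm$structureParams,
    photonRate = sm$photonsPerFrame,
    seed = deriveSeed(cfg$masterSeed, "structure")))
  blink <- simulateBlinking(emitters, sm$nFrames, sm$pOn, sm$meanOnFrames,
                            seed = deriveSeed(cfg$masterSeed, "blink"),
                            brightnessModel = sm$brightnessModel)
  stacks <- renderDualChannel(emitters, blink, aberrRender, corrRender,
                              camera = cfg$camera,
                              backgroundPhotons = sm$backgroundPhotons,
                              seed = deriveSeed(cfg$masterSeed, "render"),
                              oversample = sm$oversample, split = sm$split)
  # --- stage 5: localization ---------------------------------------------
  lz <- cfg$localization
  locOff <- withStage("localize", localizeStack(
    stacks$uncorrected, lz$thresholdFactor, lz$windowPx, lz$nominalSigmaPx))
  locOn <- localizeStack(stacks$corrected, lz$thresholdFactor, lz$windowPx,
                         lz$nominalSigmaPx)
  # --- stage 6: metrics ---------------------------------------------------
  mt <- cfg$metrics
  tryMetric <- function(expr) tryCatch(suppressWarnings(expr),
                                       error = function(e) NA_real_)
  nnSigma <- function(tab) tryMetric(
    precisionSigma(fitNNPrecision(nnPairwiseDisplacements(tab),
                                  mt$nnBinWidthNm, mt$nnDMaxNm)))
  fwhmOf <- function(stack, tab) tryMetric(
    ensembleAveragePsf(stack, tab, firstNFrames = mt$psfFirstNFrames,
                       windowPx = mt$psfWindowPx)$fwhmNm)
  frcOf <- function(tab) tryMetric(
    frcValue(frcResolution(tab, mt$frcRenderPxNm,
                           fovNm = sm$fovPx * cfg$camera$pixelNm)))
  ratio <- localizationNumberRatio(locOn, locOff)
  report <- list(
    config = cfg[c("masterSeed", "grid", "aberration", "reflection", "smlm")],
    classRecoveryRms = cls$recoveryRms,
    classIterations = cls$result@iterations,
    residualRmsAfterCorrection = phaseResidualRms(residual, phaseMap(rg)),
    strehlUncorrected = strehlRatio(aberrRender),
    strehlCorrected = strehlRatio(residual),
    localizationNumber = list(on = ratio$nOn, off = ratio$nOff,
                              ratio = ratio$ratio),
    nyquistEnhancement = if (is.finite(ratio$ratio) && ratio$ratio > 0)
      nyquistEnhancement(ratio$ratio) else NA_real_,
    sigmaOffNm = nnSigma(locOff),
    sigmaOnNm = nnSigma(locOn),
    fwhmOffNm = fwhmOf(stacks$uncorrected, locOff),
    fwhmOnNm = fwhmOf(stacks$corrected, locOn),
    frcOffNm = frcOf(locOff),
    frcOnNm = frcOf(locOn),
    photonMedianOff = if (nrow(locOff)) stats::median(locOff$photons) else NA_real_,
    photonMedianOn = if (nrow(locOn)) stats::median(locOn$photons) else NA_real_,
    runtimeSec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    writeLocalizations(locOff, file.path(cfg$outputDir, "localizations_off.csv"))
    writeLocalizations(locOn, file.path(cfg$outputDir, "localizations_on.csv"))
    rep2 <- report
    rep2$runtimeSec <- NULL   # keep the stored report byte-reproducible
    jsonlite::write_json(rep2, file.path(cfg$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# tag stage failures with the stage name so pipeline errors are attributable
withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
}
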