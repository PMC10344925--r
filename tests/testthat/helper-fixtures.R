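# Shared fixtures, built in code and memoized per test run.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, builder(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# standard instrument geometry (1.2 NA, 678 nm, 130 nm camera pixel)
stdGrid <- function(nPx = 128L) makePupilGrid(nPx, 130, 678, 1.2)

# small geometry for fast property sweeps
smallGrid <- function(nPx = 64L) makePupilGrid(nPx, 130, 678, 1.2)

# a complete noiseless angle-scan recovery fixture: known 100-mode output
# aberration of the requested RMS seen by both pupils, point phantom
recoveryFixture <- function(seed, rms = 2.5, nAngles = 200L, nScatter = 50L,
                            grid = stdGrid(), modeRange = 5:100) {
  truth <- randomAberration(rms, grid, modeRange = modeRange, seed = seed)
  ks <- spiralAngles(grid, nAngles)
  obj <- pointScatterPhantom(grid, nScatter, seed = seed + 1000L)
  fields <- simulateAngleScan(obj, ks, truth$phase, truth$phase)
  list(truth = truth, illumKs = ks,
       R = buildReflectionMatrix(fields, ks, grid),
       fields = fields, grid = grid)
}

# localization table of one static molecule re-localized every frame with
# isotropic per-axis jitter
jitterTable <- function(sigmaNm, nFrames, seed = 1L, x0 = 1000, y0 = 1000) {
  set.seed(seed)
  data.frame(frame = seq_len(nFrames),
             x_nm = x0 + rnorm(nFrames, 0, sigmaNm),
             y_nm = y0 + rnorm(nFrames, 0, sigmaNm),
             sigma_nm = 120, photons = 3000, background = 20,
             uncertainty_nm = 10)
}

# two molecules a fixed distance apart, each present with dropout, so some
# nearest neighbors pair across molecules
twoMoleculeTable <- function(sigmaNm, sepNm, nFrames, pPresent = 0.7,
                             seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (f in seq_len(nFrames)) {
    if (runif(1) < pPresent)
      rows[[length(rows) + 1L]] <-
        c(f, 1000 + rnorm(1, 0, sigmaNm), 1000 + rnorm(1, 0, sigmaNm))
    if (runif(1) < pPresent)
      rows[[length(rows) + 1L]] <-
        c(f, 1000 + sepNm + rnorm(1, 0, sigmaNm), 1000 + rnorm(1, 0, sigmaNm))
  }
  m <- do.call(rbind, rows)
  data.frame(frame = as.integer(m[, 1]), x_nm = m[, 2], y_nm = m[, 3],
             sigma_nm = 120, photons = 3000, background = 20,
             uncertainty_nm = 10)
}

# render one noise-free Gaussian spot (the localizer's model class) at a
# sub-pixel position on a counts image
gaussianSpotFrame <- function(nPx = 21L, xPx, yPx, sigmaPx, photons,
                              backgroundPhotons = 0, camera = cameraModel(qe = 1)) {
  xs <- matrix(seq_len(nPx), nPx, nPx)
  ys <- t(xs)
  g <- exp(-((xs - xPx)^2 + (ys - yPx)^2) / (2 * sigmaPx^2))
  g <- g / (2 * pi * sigmaPx^2) * photons + backgroundPhotons
  g * camera$emGain * camera$qe + camera$baseline
}

# small dual-channel render used by localizer/metric direction tests
dualChannelFixture <- function(seed = 5L, rms = 2.5, nFrames = 120L,
                               nEmitters = 60L, fovPx = 48L,
                               photons = 3000) {
  memoFixture(sprintf("dual_%d_%g_%d", seed, rms, nFrames), function() {
    cam <- cameraModel()
    rg <- renderGrid(fovPx, cam, 678, 1.2, 4L)
    ab <- randomAberration(rms, rg, seed = seed)
    em <- structureFixture("filament_mesh", fovNm = fovPx * cam$pixelNm,
                           nEmitters = nEmitters, photonRate = photons,
                           seed = seed)
    blink <- simulateBlinking(em, nFrames, pOn = 0.04, meanOnFrames = 3,
                              seed = seed,
                              brightnessModel = "per_burst_exponential")
    stacks <- renderDualChannel(em, blink, ab$phase,
                                zernikePhase(-coefValues(ab$coeffs), rg),
                                camera = cam, backgroundPhotons = 20,
                                seed = seed)
    list(stacks = stacks, emitters = em, blink = blink, grid = rg,
         aberration = ab, camera = cam)
  })
}
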