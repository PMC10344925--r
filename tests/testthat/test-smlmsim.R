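# Ground-truth structures, photoswitching kinetics, EMCCD frame rendering.

test_that("structure fixtures reproduce their nominal geometry", {
  fov <- 8000
  lp <- structureFixture("line_pair", fov, 400, params = list(jitterNm = 2),
                         seed = 1)
  pos <- emitterPositions(lp)
  # two loci at +/- separation/2 around the FOV midline
  side <- pos[, 2] > fov / 2
  expect_equal(mean(pos[side, 2]) - mean(pos[!side, 2]), 170, tolerance = 2)
  hc <- structureFixture("hollow_cylinder_cross_section", fov, 4000,
                         params = list(jitterNm = 2), seed = 2)
  y <- emitterPositions(hc)[, 2] - fov / 2
  h <- hist(y, breaks = seq(-120, 120, by = 10), plot = FALSE)
  upper <- h$mids > 30; lower <- h$mids < -30
  modeSep <- h$mids[upper][which.max(h$counts[upper])] -
    h$mids[lower][which.max(h$counts[lower])]
  expect_equal(modeSep, 180, tolerance = 5)
  expect_equal(nrow(emitterPositions(
    structureFixture("random_points", fov, 0, seed = 1))), 0)
  expect_error(structureFixture("spiral_galaxy", fov, 10, seed = 1))
})

test_that("blinking follows the two-state Markov stationary distribution", {
  em <- structureFixture("random_points", 5000, 200, seed = 3)
  bl <- simulateBlinking(em, 2000, pOn = 0.05, meanOnFrames = 4, seed = 9)
  pStat <- 0.05 / (0.05 + 1 / 4)
  onFrac <- mean(blinkStates(bl))
  se <- sqrt(pStat * (1 - pStat) / (200 * 2000))   # generous: ignores correlation
  expect_lt(abs(onFrac - pStat), 30 * se)
  # mean on-run length
  runs <- rle(as.vector(t(blinkStates(bl)[1:50, ])))
  expect_equal(mean(runs$lengths[runs$values]), 4, tolerance = 0.4)
  # determinism and the all-off limit
  bl2 <- simulateBlinking(em, 2000, pOn = 0.05, meanOnFrames = 4, seed = 9)
  expect_identical(blinkStates(bl), blinkStates(bl2))
  expect_false(any(blinkStates(simulateBlinking(em, 100, pOn = 0, seed = 1))))
})

test_that("per-burst brightness draws have unit mean and stay constant in a burst", {
  em <- structureFixture("random_points", 5000, 300, seed = 4)
  bl <- simulateBlinking(em, 1500, pOn = 0.05, meanOnFrames = 4, seed = 2,
                         brightnessModel = "per_burst_exponential")
  b <- bl@brightness[blinkStates(bl)]
  expect_equal(mean(b), 1, tolerance = 0.1)
  # within one on-run the factor does not change
  s <- blinkStates(bl)[3, ]; br <- bl@brightness[3, ]
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (i in which(runs$values & runs$lengths > 1))
    expect_equal(diff(range(br[starts[i]:ends[i]])), 0)
})

test_that("rendering conserves the photon budget and the camera chain is optional", {
  cam <- cameraModel(qe = 1, emGain = 1, readNoiseE = 0)
  rg <- renderGrid(32, cam, 678, 1.2)
  em <- structureFixture("random_points", 32 * 130, 1, photonRate = 5000,
                         seed = 2)
  em@positions[1, ] <- c(16.2, 15.8) * 130   # central: PSF tails stay in FOV
  bl <- simulateBlinking(em, 2, pOn = 0.9999, meanOnFrames = 1e6, seed = 1)
  # no emitters, no background, no noise: frames are pure baseline
  em0 <- structureFixture("random_points", 32 * 130, 0, seed = 1)
  bl0 <- simulateBlinking(em0, 2, pOn = 0, seed = 1)
  st0 <- renderFrames(em0, bl0, phaseMap(rg), cam, backgroundPhotons = 0,
                      shotNoise = FALSE, emNoise = FALSE, readNoise = FALSE)
  expect_true(all(stackFrames(st0) == cam$baseline))
  # photon conservation on a noise-free render
  st <- renderFrames(em, bl, phaseMap(rg), cam, backgroundPhotons = 0,
                     shotNoise = FALSE, emNoise = FALSE, readNoise = FALSE)
  integrated <- sum(stackFrames(st)[, , 1]) - cam$baseline * 32^2
  expect_equal(integrated, 5000, tolerance = 0.01)
})

test_that("aberration redistributes but does not destroy detected photons", {
  cam <- cameraModel(qe = 1, emGain = 1, readNoiseE = 0)
  rg <- renderGrid(32, cam, 678, 1.2)
  em <- structureFixture("random_points", 32 * 130, 1, photonRate = 5000, seed = 7)
  em@positions[1, ] <- c(16, 16) * 130
  bl <- simulateBlinking(em, 1, pOn = 0.9999, meanOnFrames = 1e6, seed = 1)
  ab <- randomAberration(2.5, rg, seed = 12)$phase
  stF <- renderFrames(em, bl, phaseMap(rg), cam, backgroundPhotons = 0,
                      shotNoise = FALSE, emNoise = FALSE, readNoise = FALSE)
  stA <- renderFrames(em, bl, ab, cam, backgroundPhotons = 0,
                      shotNoise = FALSE, emNoise = FALSE, readNoise = FALSE)
  fF <- stackFrames(stF)[, , 1] - cam$baseline
  fA <- stackFrames(stA)[, , 1] - cam$baseline
  expect_equal(sum(fA), sum(fF), tolerance = 0.02)
  # peak ratio tracks the Strehl ratio of the phase
  expect_equal(max(fA) / max(fF), strehlRatio(ab), tolerance = 0.15)
  expect_lt(max(fA), max(fF))
})

test_that("dual-channel rendering shares truth and splits the photon budget", {
  cam <- cameraModel(qe = 1, emGain = 1, readNoiseE = 0)
  rg <- renderGrid(32, cam, 678, 1.2)
  em <- structureFixture("random_points", 32 * 130, 4, photonRate = 4000, seed = 3)
  bl <- simulateBlinking(em, 6, pOn = 0.5, meanOnFrames = 3, seed = 5)
  ab <- randomAberration(2.5, rg, seed = 6)
  corr <- zernikePhase(-coefValues(ab$coeffs), rg)
  # exact cancellation: corrected-channel PSF equals the flat-phase PSF
  duo <- renderDualChannel(em, bl, ab$phase, corr, camera = cam,
                           backgroundPhotons = 0, seed = 8)
  expect_s4_class(duo$corrected, "FrameStack")
  corrPhase <- phaseMap(rg, phaseValues(ab$phase) + phaseValues(corr))
  expect_lt(max(abs(phaseValues(corrPhase)[apertureMask(rg)])), 1e-8)
  # photon split: noise-free channel sums are half the single-channel sum
  duoNF <- list(
    renderFrames(em, bl, ab$phase, cam, 0, photonScale = 0.5,
                 shotNoise = FALSE, emNoise = FALSE, readNoise = FALSE),
    renderFrames(em, bl, corrPhase, cam, 0, photonScale = 0.5,
                 shotNoise = FALSE, emNoise = FALSE, readNoise = FALSE))
  full <- renderFrames(em, bl, ab$phase, cam, 0, photonScale = 1,
                       shotNoise = FALSE, emNoise = FALSE, readNoise = FALSE)
  base <- cam$baseline * 32^2
  expect_equal(sum(stackFrames(duoNF[[1]])) - base * 6,
               (sum(stackFrames(full)) - base * 6) / 2, tolerance = 0.01)
  # zero correction: the two channels are draws from the same distribution
  duo0 <- renderDualChannel(em, bl, ab$phase, phaseMap(rg), camera = cameraModel(),
                            backgroundPhotons = 20, seed = 11)
  set.seed(1)
  a <- as.vector(stackFrames(duo0$uncorrected)) + runif(6 * 32^2, 0, 0.01)
  b <- as.vector(stackFrames(duo0$corrected)) + runif(6 * 32^2, 0, 0.01)
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
})

test_that("stochastic renders are seed-deterministic end to end", {
  cam <- cameraModel()
  rg <- renderGrid(24, cam, 678, 1.2)
  em <- structureFixture("line_pair", 24 * 130, 20, seed = 2)
  bl <- simulateBlinking(em, 5, pOn = 0.2, seed = 3)
  s1 <- renderFrames(em, bl, phaseMap(rg), cam, seed = 42)
  s2 <- renderFrames(em, bl, phaseMap(rg), cam, seed = 42)
  expect_identical(stackFrames(s1), stackFrames(s2))
  s3 <- renderFrames(em, bl, phaseMap(rg), cam, seed = 43)
  expect_false(identical(stackFrames(s1), stackFrames(s3)))
})

test_that("frame stacks survive the 16-bit TIFF round trip", {
  cam <- cameraModel()
  rg <- renderGrid(24, cam, 678, 1.2)
  em <- structureFixture("random_points", 24 * 130, 5, seed = 1)
  bl <- simulateBlinking(em, 4, pOn = 0.3, seed = 1)
  st <- renderFrames(em, bl, phaseMap(rg), cam, seed = 7)
  path <- file.path(withr::local_tempdir(), "stack.tif")
  writeFrameStackTiff(st, path)
  back <- readFrameStackTiff(path)
  expect_equal(stackFrames(back), stackFrames(st), tolerance = 1e-7)
  expect_equal(stackCamera(back)$emGain, cam$emGain)
})
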