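# Nearest-neighbor precision, FRC, Nyquist scaling, ensemble PSF, photon and
# localization-number statistics.

test_that("consecutive-frame NN displacements follow the Rayleigh distance law", {
  # single molecule re-localized every frame: displacement between two
  # estimates with per-axis sigma is Rayleigh(sigma*sqrt(2)), mean sigma*sqrt(pi)
  tab <- jitterTable(sigmaNm = 25, nFrames = 4000, seed = 8)
  d <- nnPairwiseDisplacements(tab)
  expect_length(d, 3999)
  expect_equal(mean(d), 25 * sqrt(pi), tolerance = 0.03)
  # two distant static molecules never cross-pair
  t2 <- rbind(jitterTable(1, 500, seed = 1, x0 = 0, y0 = 0),
              jitterTable(1, 500, seed = 2, x0 = 5000, y0 = 5000))
  d2 <- nnPairwiseDisplacements(t2[order(t2$frame), ])
  expect_lt(max(d2), 50)
  # empty input, empty output; sparse input warns
  expect_length(nnPairwiseDisplacements(tab[0, ]), 0)
  expect_warning(nnPairwiseDisplacements(jitterTable(10, 20, seed = 1)),
                 "pairs")
})

test_that("the two-term precision fit recovers sigma across the working range", {
  for (s in c(10, 20, 30, 50)) {
    tab <- jitterTable(s, 5001, seed = s)
    fit <- fitNNPrecision(nnPairwiseDisplacements(tab))
    expect_equal(precisionSigma(fit), s, tolerance = 0.1,
                 label = paste("sigma_true", s))
  }
  # degenerate limit: identical positions collapse below one bin
  tabz <- jitterTable(1e-4, 400, seed = 2)
  fz <- suppressWarnings(fitNNPrecision(nnPairwiseDisplacements(tabz)))
  expect_true(fz@degenerate)
  expect_lt(precisionSigma(fz), 5)
})

test_that("cross-molecule pairs are absorbed by the correction term", {
  tab <- twoMoleculeTable(sigmaNm = 30, sepNm = 200, nFrames = 6000, seed = 7)
  fit <- fitNNPrecision(nnPairwiseDisplacements(tab))
  expect_equal(precisionSigma(fit), 30, tolerance = 0.15)
  expect_equal(fit@dCNm, 200, tolerance = 0.1)
  expect_gt(fit@a2, 0.01)
})

test_that("Nyquist enhancement is the square root of the density ratio", {
  expect_equal(round(nyquistEnhancement(37.4), 2), 6.12)
  expect_identical(nyquistEnhancement(1), 1)
  expect_identical(nyquistEnhancement(4), 2)
  expect_error(nyquistEnhancement(-2))
})

test_that("FRC is ~1 for duplicated halves, ~0 for independent noise, and improves with density", {
  set.seed(3)
  filament <- function(n, seed) {
    set.seed(seed)
    t <- runif(n)
    data.frame(frame = sample(1:200, n, replace = TRUE),
               x_nm = 500 + 4000 * t + rnorm(n, 0, 20),
               y_nm = 2500 + 1500 * sin(2 * pi * t) + rnorm(n, 0, 20))
  }
  tab <- filament(4000, seed = 5)
  dup <- tab; dup$frame <- tab$frame + 1L   # odd/even halves identical
  dup2 <- rbind(tab, dup)
  frcDup <- frcResolution(dup2, renderPxNm = 20, fovNm = 6000)
  expect_gt(mean(frcDup@correlation[1:50]), 0.95)
  # independent uniform tables decorrelate beyond the lowest rings
  set.seed(4)
  u <- data.frame(frame = rep(1:2, each = 2000),
                  x_nm = runif(4000, 0, 6000), y_nm = runif(4000, 0, 6000))
  frcU <- frcResolution(u, renderPxNm = 20, fovNm = 6000)
  expect_lt(mean(abs(frcU@correlation[-(1:10)])), 0.1)
  expect_lt(stats::quantile(abs(frcU@correlation[-(1:10)]), 0.9), 0.25)
  # ten-fold more localizations strictly improve the resolution
  rSparse <- frcResolution(filament(800, seed = 6), renderPxNm = 10, fovNm = 6000)
  rDense <- frcResolution(filament(8000, seed = 7), renderPxNm = 10, fovNm = 6000)
  expect_true(rDense@resolved)
  expect_lt(frcValue(rDense), frcValue(rSparse))
  # invariance to a global translation of the table
  shifted <- filament(4000, seed = 5)
  shifted$x_nm <- shifted$x_nm + 400
  shifted$y_nm <- shifted$y_nm + 250
  r0 <- frcResolution(filament(4000, seed = 5), renderPxNm = 10, fovNm = 8000)
  r1 <- frcResolution(shifted, renderPxNm = 10, fovNm = 8000)
  expect_equal(frcValue(r1), frcValue(r0), tolerance = 0.05)
})

test_that("ensemble PSF averaging preserves width for identical spots and widens unaligned", {
  cam <- cameraModel(qe = 1, emGain = 1, readNoiseE = 0)
  rg <- renderGrid(32, cam, 678, 1.2)
  nF <- 30
  set.seed(12)
  em <- structureFixture("random_points", 32 * 130, 1, photonRate = 4000, seed = 2)
  frames <- array(0, dim = c(32, 32, nF))
  poss <- matrix(0, nF, 2)
  for (f in seq_len(nF)) {
    em@positions[1, ] <- (c(16, 16) + runif(2, -0.5, 0.5)) * 130
    poss[f, ] <- em@positions[1, ]
    bl <- simulateBlinking(em, 1, pOn = 0.9999, meanOnFrames = 1e6, seed = f)
    st <- renderFrames(em, bl, phaseMap(rg), cam, backgroundPhotons = 0,
                       shotNoise = FALSE, emNoise = FALSE, readNoise = FALSE)
    frames[, , f] <- st@frames[, , 1]
  }
  stack <- new("FrameStack", frames = frames, channel = "single",
               camera = cam, psfPhase = phaseMap(rg))
  tab <- data.frame(frame = seq_len(nF), x_nm = poss[, 1], y_nm = poss[, 2],
                    sigma_nm = 119, photons = 4000, background = 0,
                    uncertainty_nm = 1)
  # identical PSFs: the average of aligned crops keeps the width of one crop
  aligned <- ensembleAveragePsf(stack, tab, windowPx = 15L)
  single <- ensembleAveragePsf(stack, tab[1, , drop = FALSE], windowPx = 15L)
  expect_equal(aligned$fwhmNm, single$fwhmNm, tolerance = 0.02)
  # disabling alignment leaves the sub-pixel scatter in the average
  unaligned <- ensembleAveragePsf(stack, tab, windowPx = 15L, align = FALSE)
  expect_gt(unaligned$fwhmNm, aligned$fwhmNm)
  expect_error(ensembleAveragePsf(stack, tab[0, ]), "no localizations")
})

test_that("corrected channel beats the uncorrected one on every headline metric", {
  fx <- dualChannelFixture()
  tOn <- localizeStack(fx$stacks$corrected)
  tOff <- localizeStack(fx$stacks$uncorrected)
  r <- localizationNumberRatio(tOn, tOff)
  expect_gt(r$ratio, 2)
  # the corrected ensemble PSF is close to the ideal width; the full-scale
  # cross-channel FWHM comparison lives in the end-to-end acceptance check
  fOn <- ensembleAveragePsf(fx$stacks$corrected, tOn, windowPx = 17L)
  expect_lt(fOn$fwhmNm, 600)
  ph <- photonHistogram(tOn)
  expect_gte(ph$median, if (nrow(tOff)) photonHistogram(tOff)$median else 0)
})

test_that("localization-number ratio flags an empty uncorrected channel", {
  tab <- jitterTable(10, 50, seed = 1)
  expect_equal(localizationNumberRatio(tab, tab)$ratio, 1)
  r <- localizationNumberRatio(tab, tab[0, ])
  expect_true(is.infinite(r$ratio))
  expect_true(r$offEmpty)
  roi <- list(xmin = 0, xmax = 500, ymin = 0, ymax = 500)
  expect_equal(localizationNumberRatio(tab, tab, roi)$nOn,
               sum(tab$x_nm <= 500 & tab$y_nm <= 500))
})

test_that("photon histograms carry their summary statistics", {
  tab <- jitterTable(10, 200, seed = 1)
  tab$photons <- 1000
  h <- photonHistogram(tab, binWidth = 100)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$median, 1000)
  expect_error(photonHistogram(tab[0, ]), "empty")
})
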