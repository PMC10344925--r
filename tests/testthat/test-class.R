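# Reflection-matrix construction and the CLASS aberration-recovery iteration.

test_that("reflection matrix has one aperture-pixel row per column spectrum", {
  g <- smallGrid()
  ks <- spiralAngles(g, 20)
  obj <- pointScatterPhantom(g, 5, seed = 1)
  fields <- simulateAngleScan(obj, ks, phaseMap(g), phaseMap(g))
  R <- buildReflectionMatrix(fields, ks, g)
  expect_equal(nrow(reflectionEntries(R)), sum(apertureMask(g)))
  expect_equal(ncol(reflectionEntries(R)), nrow(ks))
  # zero fields give a zero matrix
  zf <- replicate(3, complexField(g, matrix(0 + 0i, g@nPx, g@nPx)))
  Rz <- buildReflectionMatrix(zf, ks[1:3, ], g)
  expect_equal(max(abs(reflectionEntries(Rz))), 0)
  expect_error(buildReflectionMatrix(fields[1], ks[1, , drop = FALSE], g),
               "at least two")
})

test_that("point-scatterer columns are shift-aligned copies of one spectrum", {
  g <- smallGrid()
  c0 <- gridCenter(g)
  obj <- matrix(0 + 0i, g@nPx, g@nPx)
  obj[c0 + 3, c0 - 4] <- 1
  ks <- rbind(c(0L, 0L), c(5L, 2L), c(-6L, 4L), c(9L, -7L))
  fields <- simulateAngleScan(obj, ks, phaseMap(g), phaseMap(g))
  R <- buildReflectionMatrix(fields, ks, g)
  # re-index each column alone to the difference frame; all must match on
  # their common support
  colSpec <- function(j) {
    Rj <- R
    Rj@entries <- R@entries[, j, drop = FALSE]
    Rj@illumKs <- R@illumKs[j, , drop = FALSE]
    accumulateSingleScattering(Rj)$spectrum
  }
  s1 <- colSpec(1)
  for (j in 2:4) {
    sj <- colSpec(j)
    common <- abs(s1) > 0 & abs(sj) > 0
    corr <- abs(sum(s1[common] * Conj(sj[common]))) /
      sqrt(sum(abs(s1[common])^2) * sum(abs(sj[common])^2))
    expect_equal(corr, 1, tolerance = 1e-9)
  }
})

test_that("coherent accumulation scales as N^2, scrambled phases as N", {
  g <- smallGrid()
  ks <- spiralAngles(g, 40)
  obj <- pointScatterPhantom(g, 10, seed = 2)
  fields <- simulateAngleScan(obj, ks, phaseMap(g), phaseMap(g))
  R <- buildReflectionMatrix(fields, ks, g)
  nAng <- ncol(reflectionEntries(R))
  coh <- accumulateSingleScattering(R)$totalIntensity
  set.seed(11)
  gains <- replicate(5, {
    Rr <- R
    Rr@entries <- sweep(R@entries, 2, exp(2i * pi * runif(nAng)), `*`)
    coh / accumulateSingleScattering(Rr)$totalIntensity
  })
  # coherent/incoherent intensity ratio is about the number of angles
  expect_gt(median(gains), nAng / 3)
  expect_lt(median(gains), nAng * 3)
  # single column: accumulation is the column itself, re-indexed
  R1 <- R
  R1@entries <- R@entries[, 5, drop = FALSE]
  R1@illumKs <- R@illumKs[5, , drop = FALSE]
  acc1 <- accumulateSingleScattering(R1)
  expect_equal(sum(abs(acc1$spectrum)^2),
               sum(abs(reflectionEntries(R1))^2), tolerance = 1e-9)
})

test_that("CLASS recovers a strong 100-mode aberration from a noiseless scan", {
  fx <- recoveryFixture(seed = 21)
  res <- classIterate(fx$R)
  expect_true(res@converged)
  expect_lt(phaseResidualRms(phaseOut(res), fx$truth$phase), 0.1)
  # the correction map cancels the aberration
  corr <- correctionMap(res)
  resid <- phaseMap(fx$grid, phaseValues(fx$truth$phase) + phaseValues(corr))
  expect_lt(phaseResidualRms(resid, phaseMap(fx$grid)), 0.05)
  expect_gt(strehlRatio(resid), 0.95)
  # aberration-free input: recovered phases are flat
  g <- fx$grid
  ks <- fx$illumKs
  f0 <- simulateAngleScan(pointScatterPhantom(g, 50, seed = 3), ks,
                          phaseMap(g), phaseMap(g))
  res0 <- classIterate(buildReflectionMatrix(f0, ks, g))
  expect_lt(phaseResidualRms(phaseOut(res0), phaseMap(g)), 0.05)
  expect_lt(phaseResidualRms(phaseIn(res0), phaseMap(g)), 0.05)
})

test_that("recovery survives 20 dB measurement noise", {
  fx <- recoveryFixture(seed = 33)
  Rn <- addReflectionNoise(fx$R, snrDb = 20, seed = 7)
  res <- classIterate(Rn)
  expect_lt(phaseResidualRms(phaseOut(res), fx$truth$phase), 0.3)
})

test_that("single-scattering intensity trace is non-decreasing on seeded problems", {
  for (seed in 1:10) {
    fx <- recoveryFixture(seed = seed, rms = 1.5, nAngles = 60L,
                          nScatter = 15L, grid = smallGrid(),
                          modeRange = 5:40)
    res <- classIterate(fx$R, maxIter = 15L)
    tr <- intensityTrace(res)
    expect_true(all(diff(tr) >= -1e-3 * tr[-length(tr)]),
                label = paste("trace monotone, seed", seed))
  }
})

test_that("leave-one-out and equal-weighting variants also recover the phase", {
  fx <- recoveryFixture(seed = 40, rms = 1.5, nAngles = 100L, nScatter = 20L,
                        grid = smallGrid(), modeRange = 5:40)
  resLoo <- classIterate(fx$R, leaveOneOut = TRUE)
  expect_lt(phaseResidualRms(phaseOut(resLoo), fx$truth$phase), 0.1)
  resEq <- classIterate(fx$R, weighting = "equal")
  expect_lt(phaseResidualRms(phaseOut(resEq), fx$truth$phase), 0.15)
})

test_that("doubling the angle count never worsens median recovery", {
  errAt <- function(nAngles) {
    e <- numeric(10)
    for (s in 1:10) {
      fx <- recoveryFixture(seed = 100 + s, rms = 2, nAngles = nAngles,
                            nScatter = 15L, grid = smallGrid(),
                            modeRange = 5:40)
      e[s] <- phaseResidualRms(phaseOut(classIterate(fx$R)), fx$truth$phase)
    }
    median(e)
  }
  e50 <- errAt(50L); e100 <- errAt(100L); e200 <- errAt(200L)
  expect_lte(e100, e50 * 1.0001)
  expect_lte(e200, e100 * 1.0001)
})

test_that("correction map composes with a pre-measured system aberration", {
  fx <- recoveryFixture(seed = 55, rms = 1, nAngles = 60L, nScatter = 15L,
                        grid = smallGrid(), modeRange = 5:30)
  res <- classIterate(fx$R)
  sys <- randomAberration(0.8, fx$grid, seed = 9)$phase
  withSys <- correctionMap(res, systemPhase = sys)
  alone <- correctionMap(res)
  # difference equals the negated system phase up to the removed gauge
  diffMap <- phaseMap(fx$grid, phaseValues(withSys) - phaseValues(alone))
  expect_lt(phaseResidualRms(diffMap, phaseMap(fx$grid, -phaseValues(sys))), 0.05)
  # zero result gives a zero map
  res0 <- classIterate(buildReflectionMatrix(
    simulateAngleScan(pointScatterPhantom(fx$grid, 15, seed = 2), fx$illumKs,
                      phaseMap(fx$grid), phaseMap(fx$grid)),
    fx$illumKs, fx$grid))
  expect_lt(max(abs(phaseValues(correctionMap(res0)))), 0.2)
})

test_that("per-patch CLASS recovers uniform and piecewise aberrations", {
  g <- stdGrid()
  truth <- randomAberration(1.0, g, modeRange = 5:20, seed = 3)
  ks <- spiralAngles(g, 200)
  obj <- pointScatterPhantom(g, 80, seed = 5)
  fields <- simulateAngleScan(obj, ks, truth$phase, truth$phase)
  patches <- subareaClass(fields, ks, patchPx = 64L)
  expect_length(patches, 4L)
  pg <- pupilGrid(phaseOut(patches[[1]]$result))
  truthPatch <- zernikePhase(coefValues(truth$coeffs), pg)
  # every patch sees the same aberration
  for (p in patches)
    expect_lt(phaseResidualRms(phaseOut(p$result), truthPatch), 0.2)
  # and the patches agree pairwise
  for (i in 2:4)
    expect_lt(phaseResidualRms(phaseOut(patches[[1]]$result),
                               phaseValues(phaseOut(patches[[i]]$result))), 0.15)
  expect_error(subareaClass(fields, ks, patchPx = 16L), "at least 32")
  expect_error(subareaClass(fields, ks, patchPx = 256L), "larger than")
})

test_that("two-zone phantoms yield zone-specific patch corrections", {
  g <- stdGrid()
  zoneA <- randomAberration(1.0, g, modeRange = 5:20, seed = 61)
  zoneB <- randomAberration(1.0, g, modeRange = 5:20, seed = 62)
  ks <- spiralAngles(g, 200)
  obj <- pointScatterPhantom(g, 120, seed = 8)
  maskA <- matrix(0, 128, 128); maskA[, 1:64] <- 1
  # the model is linear in the object: each zone's scatterers see their own
  # aberration
  fields <- lapply(seq_len(nrow(ks)), function(j) {
    fa <- reflectanceField(obj * maskA, ks[j, ], zoneA$phase, zoneA$phase)
    fb <- reflectanceField(obj * (1 - maskA), ks[j, ], zoneB$phase, zoneB$phase)
    complexField(g, fieldAmplitude(fa) + fieldAmplitude(fb))
  })
  patches <- subareaClass(fields, ks, patchPx = 64L)
  pg <- pupilGrid(phaseOut(patches[[1]]$result))
  truthA <- zernikePhase(coefValues(zoneA$coeffs), pg)
  truthB <- zernikePhase(coefValues(zoneB$coeffs), pg)
  for (p in patches) {
    truth <- if (p$region[["col0"]] == 1L) truthA else truthB
    other <- if (p$region[["col0"]] == 1L) truthB else truthA
    expect_lt(phaseResidualRms(phaseOut(p$result), truth), 0.2)
    expect_gt(phaseResidualRms(phaseOut(p$result), other), 0.4)
  }
})

test_that("a patch covering the whole FOV reproduces the global iteration", {
  fx <- recoveryFixture(seed = 70, rms = 1, nAngles = 50L, nScatter = 15L,
                        grid = smallGrid(), modeRange = 5:30)
  whole <- classIterate(fx$R)
  one <- subareaClass(fx$fields, fx$illumKs, patchPx = fx$grid@nPx)
  expect_length(one, 1L)
  expect_equal(phaseValues(phaseOut(one[[1]]$result)),
               phaseValues(phaseOut(whole)), tolerance = 1e-10)
})
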