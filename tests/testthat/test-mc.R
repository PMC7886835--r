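test_that("Compton sampling respects the backscatter energy bound at 76 keV", {
  s <- kleinNishinaSample(76, 2e5, seed = 4)
  bound <- 76 / (1 + 2 * 76 / 510.998950)
  expect_gte(min(s$energyOut), bound - 1e-9)
  expect_lt(min(s$energyOut), bound + 0.5)    # the bound is approached
  expect_lte(max(s$energyOut), 76 + 1e-9)
  # Compton relation holds exactly for every sample
  expect_equal(s$energyOut,
               76 / (1 + 76 / 510.998950 * (1 - s$cosTheta)),
               tolerance = 1e-12)
})

test_that("Compton sampling approaches Thomson symmetry at low energy", {
  s <- kleinNishinaSample(1, 1e6, seed = 2)
  expect_lt(abs(mean(s$cosTheta)), 0.005)
})

test_that("sampled mean scattered-energy fraction matches quadrature at 100 keV", {
  s <- kleinNishinaSample(100, 2e5, seed = 9)
  expect_equal(mean(s$energyOut) / 100, knOracleMeanRatio(100),
               tolerance = 5e-3)
})

test_that("primary transmission through a water slab follows Beer-Lambert", {
  ph <- uniformPhantom("water", 1.0, dims = c(30, 30, 30), spacingMm = 5)
  # slab front face at y = -65 mm (2 air voxels margin); source just outside
  src <- c(0, -85, 0)
  n <- 2e5
  depths <- sampleFirstInteractionDepth(ph, 60, n, src, c(0, 1, 0), seed = 6)
  n <- length(depths)
  mu <- attenuationCoefficient("water", 60, 1.0)
  # exclude the coherent part: transport runs with Rayleigh off
  tab <- materialTable()
  code <- match("water", materialNames())
  fra <- approx(tab@energyKeV, tab@fRa[, code], 60)$y
  mu <- mu * (1 - fra)
  dAir <- (85 - 65) / 10                       # cm of air before the slab
  for (t in c(2, 5, 8)) {
    p <- exp(-mu * t)
    phat <- mean(depths > dAir + t)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n) + 2e-3)
  }
})

test_that("skin dose on an all-air phantom is identically zero", {
  g <- simulateSkinDose(allAirPhantom(), carmPose(), fluoroConditions(),
                        mcConfig(nPhotons = 5000, nBatches = 2))
  expect_true(all(doseArray(g) == 0))
})

test_that("energy bookkeeping balances to machine precision", {
  ph <- smallTorso()
  g <- simulateSkinDose(ph, carmPose(), fluoroConditions(),
                        mcConfig(nPhotons = 5e4, seed = 2))
  e <- g@energyKeV
  expect_lt(abs(e[["emitted"]] - e[["deposited"]] - e[["escaped"]]) /
              e[["emitted"]], 1e-6)
  expect_lte(e[["deposited"]], e[["emitted"]])
})

test_that("a fixed seed reproduces the dose grid bit-identically", {
  ph <- smallTorso()
  mc <- mcConfig(nPhotons = 3e4, seed = 17)
  g1 <- simulateSkinDose(ph, carmPose(), fluoroConditions(), mc)
  g2 <- simulateSkinDose(ph, carmPose(), fluoroConditions(), mc)
  expect_identical(doseArray(g1), doseArray(g2))
  expect_identical(relUncertainty(g1), relUncertainty(g2))
  g3 <- simulateSkinDose(ph, carmPose(), fluoroConditions(),
                         mcConfig(nPhotons = 3e4, seed = 18))
  expect_false(identical(doseArray(g1), doseArray(g3)))
})

test_that("uncertainty scales as one over root n", {
  ph <- smallTorso()
  cc <- fluoroConditions()
  g1 <- simulateSkinDose(ph, carmPose(), cc, mcConfig(nPhotons = 1e5, seed = 3))
  g4 <- simulateSkinDose(ph, carmPose(), cc, mcConfig(nPhotons = 4e5, seed = 4))
  sel <- doseArray(g1) > 0 & doseArray(g4) > 0 &
    doseArray(g1) > 0.05 * max(doseArray(g1))
  ratio <- median(relUncertainty(g1)[sel] / relUncertainty(g4)[sel])
  expect_gt(ratio, 1.6); expect_lt(ratio, 2.4)
})

test_that("dose-rate scaling is linear in tube current and follows the protocol arithmetic", {
  cc <- fluoroConditions()                     # 2.5 mA, 15 fps, continuous
  expect_equal(doseRateScale(1e-15, cc, 1), 2.5e-15, tolerance = 1e-15)
  expect_identical(doseRateScale(2e-15, fluoroConditions(ma = 5), 1),
                   2 * doseRateScale(2e-15, cc, 1))
  expect_gt(doseRateScale(1e-15, fluoroConditions(ma = 1e-9), 1), 0)
  expect_error(doseRateScale(1e-15, cc, 0), "calibration")
  # pulsed mode: duty = fps x pulse width
  expect_equal(doseRateScale(1e-15, cc, 1, pulseWidthS = 0.02),
               1e-15 * 2.5 * 15 * 0.02)
})

test_that("a phantom in the beam increases scattered kerma beside it", {
  room <- roomModel(sizeM = c(4, 3, 4), wallThicknessCm = 0)
  cc <- fluoroConditions()
  mc <- mcConfig(nPhotons = 2e5, nBatches = 2, seed = 31)
  gWith <- simulateAirKerma(room, smallTorso(), carmPose(), cc,
                            gridSpacingCm = 20, mc = mc)
  gWithout <- simulateAirKerma(room, allAirPhantom(), carmPose(), cc,
                               gridSpacingCm = 20, mc = mc)
  # 1 m lateral, below the beam exit: the patient-backscatter region
  at1m <- function(g) {
    idx <- floor((c(1000, -400, 0) - originMm(g)) / spacingMm(g)) + 1
    doseArray(g)[idx[1], idx[2], idx[3]]
  }
  expect_gt(at1m(gWith), at1m(gWithout))
})
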