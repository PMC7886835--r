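sessionFixture <- function(nPhotons = 2e4, tableSeed = 5) {
  ph <- smallTorso()
  list(phantom = ph,
       airdoseTable = tinyAirdoseTable(nPhotons = 1000, seed = tableSeed,
                                       phantom = allAirPhantom()),
       mc = mcConfig(nPhotons = nPhotons, nBatches = 2, seed = 11))
}

condRecord <- function(timestampS, beamOn = TRUE, periodS = 1, ...) {
  list(conditions = table2Conditions(beamOn = beamOn,
                                     timestampS = timestampS, ...),
       timestampS = timestampS, stale = FALSE, periodS = periodS)
}

test_that("a beam-off session accumulates zero dose but predicts eye-lens risk", {
  cfg <- sessionFixture()
  stream <- lapply(0:4, function(k) condRecord(k * 1.0, beamOn = FALSE))
  obs <- list(observerState(0, c(500, 200, 300)))
  out <- runSession(cfg, stream, obs)
  expect_true(all(doseArray(out$cumulative) == 0))
  el <- out$payloads[[3]]$eyelens
  expect_false(is.null(el))
  expect_true(el$predicted)
  expect_identical(el$lens_dose_rate_Gy_s, 1.550 * el$air_kerma_rate_Gy_s)
})

test_that("identical consecutive records accumulate exactly linearly (cache hit)", {
  cfg <- sessionFixture()
  one <- runSession(cfg, list(condRecord(0, periodS = 1)))
  two <- runSession(cfg, list(condRecord(0), condRecord(1, periodS = 1)))
  expect_identical(two$nFingerprints, 1L)
  expect_equal(doseArray(two$cumulative), 2 * doseArray(one$cumulative),
               tolerance = 1e-12)
})

test_that("replaying the same streams and seed is bit-identical", {
  cfg <- sessionFixture()
  stream <- list(condRecord(0), condRecord(1, lateralDeg = 30),
                 condRecord(2, beamOn = FALSE))
  obs <- list(observerState(0, c(400, 0, 0)), observerState(1.5, c(600, 100, 0)))
  a <- runSession(cfg, stream, obs)
  b <- runSession(cfg, stream, obs)
  expect_identical(doseArray(a$cumulative), doseArray(b$cumulative))
  expect_identical(a$payloads, b$payloads)
})

test_that("cumulative dose is invariant to stream chunking", {
  cfg <- sessionFixture()
  coarse <- runSession(cfg, list(condRecord(0, periodS = 4)))
  fine <- runSession(cfg, c(lapply(0:3, function(k) condRecord(k)),
                            list(condRecord(4, beamOn = FALSE,
                                            periodS = 0.01))))
  expect_equal(max(doseArray(fine$cumulative)),
               max(doseArray(coarse$cumulative)), tolerance = 1e-12)
  expect_equal(doseArray(fine$cumulative), doseArray(coarse$cumulative),
               tolerance = 1e-12)
})

test_that("dose accumulation is associative, monotone and duration-linear", {
  cfg <- sessionFixture(nPhotons = 1e4)
  inc <- simulateSkinDose(cfg$phantom, carmPose(), table2Conditions(),
                          cfg$mc)
  cum0 <- array(0, dim(doseArray(inc)))
  expect_identical(accumulateDose(cum0, inc, 0, table2Conditions()), cum0)
  once <- accumulateDose(cum0, inc, 3, table2Conditions())
  halves <- accumulateDose(accumulateDose(cum0, inc, 1.5, table2Conditions()),
                           inc, 1.5, table2Conditions())
  expect_equal(halves, once, tolerance = 1e-12)
  expect_true(all(once >= cum0))
  bad <- new("DoseGrid", dosePerPhoton = array(0, c(2, 2, 2)),
             relUncertainty = array(0, c(2, 2, 2)), spacingMm = rep(1, 3),
             originMm = rep(0, 3), nPhotonsRun = 1, quantity = "skin_dose",
             energyKeV = c(emitted = 0, deposited = 0, escaped = 0))
  expect_error(accumulateDose(cum0, bad, 1, table2Conditions()), "lattice")
})

test_that("the PA peak skin dose sits on the posterior surface", {
  ph <- smallTorso()
  g <- simulateSkinDose(ph, carmPose(), table2Conditions(),
                        mcConfig(nPhotons = 1e5, seed = 8))
  pk <- arrayInd(which.max(doseArray(g)), dim(doseArray(g)))
  yPeak <- originMm(g)[2] + (pk[2] - 0.5) * spacingMm(g)[2]
  expect_lt(yPeak, 0)   # below the isocenter: the side facing the tube
})

test_that("payloads color monotonically, round-trip dose values, and flag zero dose", {
  cfg <- sessionFixture()
  ph <- cfg$phantom
  zero <- makePayload(list(timestampS = 0, cumulative = array(0, dim(huGrid(ph))),
                           phantom = ph, frustum = NULL, eyelens = NULL))
  expect_true(all(zero$skin_points$color == zero$skin_points$color[1]))

  out <- runSession(cfg, list(condRecord(0)))
  sp <- out$payloads[[1]]$skin_points
  ord <- order(sp$dose_Gy)
  idx <- fluorodose:::.dose_colors(sp$dose_Gy, max(sp$dose_Gy))$index
  expect_true(all(diff(idx[ord]) >= 0))

  path <- file.path(tempdir(), "payloads.jsonl")
  writePayloadsJsonl(out$payloads, path)
  lines <- readLines(path)
  expect_length(lines, 1)
  back <- jsonlite::fromJSON(lines[1])
  expect_identical(back$skin_points$dose_Gy, sp$dose_Gy)
  expect_identical(back$colorbar$max, max(sp$dose_Gy))
})

test_that("stream contract errors: out-of-order timestamps, fingerprint mismatch", {
  cfg <- sessionFixture()
  expect_error(runSession(cfg, list(condRecord(1), condRecord(0))),
               "out of order")
  stream <- list(condRecord(0, kvp = 80))
  obs <- list(observerState(0, c(400, 0, 0)))
  expect_error(runSession(cfg, stream, obs), "fingerprint")
})

test_that("offline rendering writes a deterministic, parseable PNG", {
  cfg <- sessionFixture(nPhotons = 5e3)
  out <- runSession(cfg, list(condRecord(0)))
  p1 <- file.path(tempdir(), "view1.png")
  p2 <- file.path(tempdir(), "view2.png")
  renderOffline(cfg$phantom, out$cumulative, carmPose(), p1)
  renderOffline(cfg$phantom, out$cumulative, carmPose(), p2)
  expect_gt(file.size(p1), 100)
  img <- png::readPNG(p1)
  expect_identical(dim(img)[3], 3L)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_error(renderOffline(allAirPhantom(), out$cumulative, carmPose(),
                             p1), "no skin")
})
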