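test_that("the default angular grid has 13 x 5 nodes", {
  expect_length(seq(-90, 90, by = 15), 13)
  expect_length(seq(-30, 30, by = 30), 3)
  tab <- tinyAirdoseTable(nPhotons = 400)
  expect_length(tab@latNodes, 3)   # 90-degree steps
  expect_length(tab@ccNodes, 3)    # 30-degree steps
  expect_true(tab@complete)
  expect_error(precomputeTable(roomModel(), allAirPhantom(),
                               fluoroConditions(), latStepDeg = 17),
               "divide")
})

test_that("a rebuild with the same seed is bit-identical; slices match standalone runs", {
  a <- tinyAirdoseTable(nPhotons = 600, seed = 5)
  b <- tinyAirdoseTable(nPhotons = 600, seed = 5)
  expect_identical(a@kermaPerPhoton, b@kermaPerPhoton)

  # node (0 deg, 0 deg) is node (2, 2) of the 3x3 grid
  cc <- table2Conditions()
  room <- roomModel(sizeM = c(3, 3, 3), wallThicknessCm = 0)
  g <- simulateAirKerma(room, allAirPhantom(), carmPose(0, 0, cc@sidCm), cc,
                        gridSpacingCm = 50,
                        mc = mcConfig(nPhotons = 600, nBatches = 2,
                                      seed = airdoseNodeSeed(5, 2, 2, 3)))
  expect_identical(a@kermaPerPhoton[2, 2, , , ], doseArray(g))
})

test_that("an interrupted build resumes from its checkpoint and is flagged", {
  ck <- file.path(tempdir(), "airdose_ck.rds")
  unlink(ck)
  room <- roomModel(sizeM = c(3, 3, 3), wallThicknessCm = 0)
  part <- precomputeTable(room, allAirPhantom(), table2Conditions(),
                          latStepDeg = 90, ccStepDeg = 30,
                          mc = mcConfig(nPhotons = 400, nBatches = 2, seed = 5),
                          gridSpacingCm = 50, checkpointPath = ck,
                          nodeLimit = 4)
  expect_false(part@complete)
  full <- precomputeTable(room, allAirPhantom(), table2Conditions(),
                          latStepDeg = 90, ccStepDeg = 30,
                          mc = mcConfig(nPhotons = 400, nBatches = 2, seed = 5),
                          gridSpacingCm = 50, checkpointPath = ck)
  expect_true(full@complete)
  fresh <- precomputeTable(room, allAirPhantom(), table2Conditions(),
                           latStepDeg = 90, ccStepDeg = 30,
                           mc = mcConfig(nPhotons = 400, nBatches = 2, seed = 5),
                           gridSpacingCm = 50)
  expect_identical(full@kermaPerPhoton, fresh@kermaPerPhoton)
  unlink(ck)
})

test_that("queries are exact at nodes, linear between them, zero at beam-off", {
  tab <- tinyAirdoseTable(nPhotons = 1500, seed = 7)
  cc <- table2Conditions()
  d <- dim(tab@kermaPerPhoton)[3:5]
  ijk <- pmax(d %/% 2, 1)
  pos <- tab@latticeOriginMm + (ijk - 0.5) * tab@latticeSpacingMm
  stored <- tab@kermaPerPhoton[2, 2, ijk[1], ijk[2], ijk[3]]
  got <- queryAirKerma(tab, 0, 0, pos, cc, tubeOutputCalibration = 1)
  expect_equal(got, stored * cc@ma, tolerance = 1e-12)

  # midway between lateral nodes 0 and 90: arithmetic mean of the two
  k0 <- tab@kermaPerPhoton[2, 2, ijk[1], ijk[2], ijk[3]]
  k90 <- tab@kermaPerPhoton[3, 2, ijk[1], ijk[2], ijk[3]]
  mid <- queryAirKerma(tab, 45, 0, pos, cc, tubeOutputCalibration = 1)
  expect_equal(mid, (k0 + k90) / 2 * cc@ma, tolerance = 1e-12)

  off <- table2Conditions(beamOn = FALSE, ma = 1)
  expect_identical(queryAirKerma(tab, 0, 0, pos, off), 0)
})

test_that("interpolated kerma is bounded by the surrounding node values", {
  tab <- tinyAirdoseTable(nPhotons = 1500, seed = 7)
  cc <- table2Conditions()
  set.seed(13)
  d <- dim(tab@kermaPerPhoton)[3:5]
  for (i in 1:40) {
    lat <- runif(1, -90, 90); ccd <- runif(1, -30, 30)
    pos <- tab@latticeOriginMm + runif(3, 0.5, d - 0.5) * tab@latticeSpacingMm
    v <- queryAirKerma(tab, lat, ccd, pos, cc, tubeOutputCalibration = 1) /
      cc@ma
    # all 32 corners of the (lat, cc, x, y, z) cell
    wl <- fluorodose:::.lin_weights(tab@latNodes, lat)
    wc <- fluorodose:::.lin_weights(tab@ccNodes, ccd)
    ctrs <- lapply(1:3, function(a)
      tab@latticeOriginMm[a] + (seq_len(d[a]) - 0.5) * tab@latticeSpacingMm[a])
    wp <- lapply(1:3, function(a) fluorodose:::.lin_weights(ctrs[[a]], pos[a]))
    corners <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1, 0:1))
    vals <- apply(corners, 1, function(s)
      tab@kermaPerPhoton[wl$i + s[1], wc$i + s[2], wp[[1]]$i + s[3],
                         wp[[2]]$i + s[4], wp[[3]]$i + s[5]])
    expect_gte(v, min(vals) - 1e-18); expect_lte(v, max(vals) + 1e-18)
  }
})

test_that("angle range, lattice range and fingerprint mismatches are errors", {
  tab <- tinyAirdoseTable(nPhotons = 400)
  cc <- table2Conditions()
  expect_error(queryAirKerma(tab, 95, 0, c(0, 0, 0), cc), "range")
  expect_error(queryAirKerma(tab, 0, -31, c(0, 0, 0), cc), "range")
  expect_error(queryAirKerma(tab, 0, 0, c(9e4, 0, 0), cc), "lattice")
  expect_error(queryAirKerma(tab, 0, 0, c(0, 0, 0),
                             table2Conditions(kvp = 80)), "fingerprint")
})

test_that("mirrored lateral angles give mirrored kerma within MC noise", {
  ph <- smallTorso()
  room <- roomModel(sizeM = c(3, 3, 3), wallThicknessCm = 0)
  tab <- precomputeTable(room, ph, table2Conditions(), latStepDeg = 90,
                         ccStepDeg = 30,
                         mc = mcConfig(nPhotons = 3e4, nBatches = 2, seed = 3),
                         gridSpacingCm = 50)
  kL <- tab@kermaPerPhoton[1, 2, , , ]   # lateral -90
  kR <- tab@kermaPerPhoton[3, 2, , , ]   # lateral +90
  nx <- dim(kL)[1]
  kRm <- kR[nx:1, , ]
  sel <- kL > 0 & kRm > 0
  # mirrored fields agree in the large: total kerma within a few percent
  expect_equal(sum(kL[sel]), sum(kRm[sel]), tolerance = 0.1)
})

test_that("eye-lens conversion is exactly the 1.550 scalar and linear", {
  e <- eyelensDoseRate(1.0e-3)
  expect_identical(e@lensDoseRate, 1.550 * 1.0e-3)
  expect_identical(e@conversionFactor, 1.550)
  expect_identical(eyelensDoseRate(0)@lensDoseRate, 0)
  a <- 2.7e-6; b <- 3.9e-5
  expect_equal(eyelensDoseRate(a)@lensDoseRate +
                 eyelensDoseRate(b)@lensDoseRate,
               eyelensDoseRate(a + b)@lensDoseRate, tolerance = 1e-18)
  expect_error(eyelensDoseRate(-1), "nonnegative")
})

test_that("air-dose tables round-trip losslessly and reject corrupt files", {
  tab <- tinyAirdoseTable(nPhotons = 400)
  prefix <- file.path(tempdir(), "adt")
  saveAirDoseTable(tab, prefix)
  back <- loadAirDoseTable(prefix)
  expect_identical(back@kermaPerPhoton, tab@kermaPerPhoton)
  expect_identical(back@latNodes, tab@latNodes)
  expect_equal(back@fingerprint, tab@fingerprint)
  expect_equal(back@meta$nPhotons, tab@meta$nPhotons)
  expect_equal(back@meta$seed, tab@meta$seed)
  # truncate the payload
  sz <- file.size(paste0(prefix, ".bin"))
  con <- file(paste0(prefix, ".bin"), "r+b")
  truncate_ok <- tryCatch({ seek(con, sz - 16); TRUE },
                          error = function(e) FALSE)
  close(con)
  bin <- readBin(paste0(prefix, ".bin"), "raw", sz)
  writeBin(bin[1:(sz - 16)], paste0(prefix, ".bin"))
  expect_error(loadAirDoseTable(prefix), "truncated")
  # schema mismatch
  saveAirDoseTable(tab, prefix)
  expect_error(loadDoseGrid(prefix), "mismatch")
})
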