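test_that("HU calibration hits the air and water anchors and is monotone", {
  expect_identical(huToMaterial(0)$materialId, 3L)
  expect_equal(huToMaterial(0)$density, 1.000)
  expect_identical(huToMaterial(-1000)$materialId, 1L)
  expect_equal(huToMaterial(-1000)$density, 0.0012)
  expect_equal(huToMaterial(1000)$density, 1.80)
  hus <- seq(-1024, 3000, by = 7)
  expect_true(all(diff(huToMaterial(hus)$density) >= 0))
})

test_that("HU-density mapping is continuous at segment boundaries", {
  for (b in c(-900, -200, 150)) {
    lo <- huToMaterial(b - 1e-7)$density
    hi <- huToMaterial(b + 1e-7)$density
    expect_lt(abs(hi - lo), 1e-9)
  }
  expect_warning(huToMaterial(3500), "clamped")
})

test_that("synthetic torso is deterministic and anatomically plausible", {
  a <- synthCtTorso(48, 48, 32, spacingMm = 6, seed = 9)
  b <- synthCtTorso(48, 48, 32, spacingMm = 6, seed = 9)
  expect_identical(huGrid(a), huGrid(b))
  c2 <- synthCtTorso(48, 48, 32, spacingMm = 6, seed = 10)
  expect_false(identical(huGrid(a), huGrid(c2)))
  frac <- mean(materialIds(a) != 1L)
  expect_gt(frac, 0.2); expect_lt(frac, 0.7)
  expect_gt(sum(skinMask(a)), 0)
  # regression: tissue fraction of the default full-size torso (frozen)
  full <- synthCtTorso()
  expect_equal(mean(materialIds(full) != 1L), 0.3188, tolerance = 0.01)
})

test_that("the torso surface is closed: entering rays meet skin first", {
  ph <- smallTorso()
  d <- dim(huGrid(ph)); mid <- d %/% 2
  # march along +x, +y, -y at mid-lines: first non-air voxel must be skin
  paths <- list(cbind(seq_len(d[1]), mid[2], mid[3]),
                cbind(mid[1], seq_len(d[2]), mid[3]),
                cbind(mid[1], rev(seq_len(d[2])), mid[3]))
  for (pt in paths) {
    mats <- materialIds(ph)[pt]
    first <- which(mats != 1L)[1]
    expect_true(skinMask(ph)[matrix(pt[first, ], 1)])
  }
})

test_that("raw container round-trips the HU grid bit-identically", {
  ph <- smallTorso()
  prefix <- file.path(tempdir(), "torso_rt")
  savePhantomRaw(ph, prefix)
  back <- loadCt(prefix)
  expect_identical(round(huGrid(back)), round(huGrid(ph)))
  expect_identical(spacingMm(back), spacingMm(ph))
  expect_identical(originMm(back), originMm(ph))
  expect_error(loadCt(file.path(tempdir(), "nonexistent")), "sidecar")
})

test_that("an all-air volume has an empty skin mask", {
  ph <- allAirPhantom()
  expect_identical(sum(skinMask(ph)), 0L)
})

test_that("skin mask equals the brute-force air-distance oracle on a sphere", {
  n <- 24; sp <- 2
  hu <- array(-1000, c(n, n, n))
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= 10^2) hu[i, j, k] <- 0
  ph <- phantomFromHu(hu, sp, rep(-n * sp / 2, 3), skinLayerMm = sp)
  # brute force: tissue voxels with a 6-adjacent air voxel
  oracle <- array(FALSE, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (hu[i, j, k] < -900) next
    for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                     c(0,0,1), c(0,0,-1))) {
      q <- c(i, j, k) + off
      if (any(q < 1) || any(q > n) || hu[q[1], q[2], q[3]] < -900) {
        oracle[i, j, k] <- TRUE; break
      }
    }
  }
  expect_identical(skinMask(ph), oracle)
  # doubling the layer gives a superset
  deeper <- extractSkinMask(ph, 2 * sp)
  expect_true(all(deeper[skinMask(ph)]))
  expect_gt(sum(deeper), sum(skinMask(ph)))
})

test_that("skin mask is invariant under volume translation", {
  ph <- smallTorso()
  shifted <- phantomFromHu(huGrid(ph), spacingMm(ph),
                           originMm(ph) + c(100, -50, 30),
                           skinLayerMm = max(spacingMm(ph)))
  expect_identical(skinMask(shifted), skinMask(ph))
})

test_that("DICOM series load matches the written volume; gaps are rejected", {
  dirp <- file.path(tempdir(), "dcm_ok")
  dir.create(dirp, showWarnings = FALSE)
  set.seed(3)
  nz <- 6
  vol <- array(sample(0:2000, 12 * 10 * nz, replace = TRUE), c(12, 10, nz))
  for (k in 1:nz)
    writeDicomSlice(file.path(dirp, sprintf("s%02d.dcm", k)), vol[, , k],
                    zMm = 2.5 * (k - 1), pixelSpacingMm = c(2, 2))
  ph <- loadCt(dirp)
  expect_identical(dim(huGrid(ph)), c(12L, 10L, as.integer(nz)))
  expect_equal(huGrid(ph), vol - 1024)
  expect_equal(spacingMm(ph), c(2, 2, 2.5))

  dirg <- file.path(tempdir(), "dcm_gap")
  dir.create(dirg, showWarnings = FALSE)
  for (k in c(1, 2, 4, 5))
    writeDicomSlice(file.path(dirg, sprintf("s%02d.dcm", k)),
                    matrix(1000, 10, 12), zMm = 2.5 * (k - 1))
  expect_error(loadCt(dirg), "inconsistent slice spacing")
})
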