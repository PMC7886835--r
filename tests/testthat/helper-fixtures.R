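# Fixtures are built in code; nothing binary ships with the tests.

# homogeneous block of one material inside an air margin
uniformPhantom <- function(material = "water", density = 1.0,
                           dims = c(30, 30, 30), spacingMm = 5,
                           originMm = NULL, airMargin = 2) {
  spacing <- rep(spacingMm, 3)
  if (is.null(originMm)) originMm <- -dims * spacing / 2
  mat <- array(1L, dims)
  dens <- array(0.0012, dims)
  i <- (airMargin + 1):(dims[1] - airMargin)
  j <- (airMargin + 1):(dims[2] - airMargin)
  k <- (airMargin + 1):(dims[3] - airMargin)
  code <- match(material, materialNames())
  mat[i, j, k] <- code
  dens[i, j, k] <- density
  hu <- array(-1000, dims)
  hu[i, j, k] <- if (material == "bone") 700 else 0
  skin <- fluorodose:::.skin_mask(mat, spacing, max(spacing))
  new("VoxelPhantom", hu = hu, materialId = mat, density = dens,
      skinMask = skin, spacingMm = spacing, originMm = originMm)
}

allAirPhantom <- function(dims = c(16, 16, 16), spacingMm = 10) {
  spacing <- rep(spacingMm, 3)
  hu <- array(-1000, dims)
  phantomFromHu(hu, spacing, -dims * spacing / 2)
}

smallTorso <- function(seed = 1) synthCtTorso(48, 48, 32, spacingMm = 6,
                                              seed = seed)

table2Conditions <- function(...) fluoroConditions(...)

# tiny air-dose table for query/session tests: 3 x 3 angular nodes
tinyAirdoseTable <- function(nPhotons = 3000, seed = 5, phantom = NULL,
                             conditions = table2Conditions(),
                             gridSpacingCm = 50) {
  if (is.null(phantom)) phantom <- allAirPhantom()
  room <- roomModel(sizeM = c(3, 3, 3), wallThicknessCm = 0)
  precomputeTable(room, phantom, conditions, latStepDeg = 90,
                  ccStepDeg = 30, mc = mcConfig(nPhotons = nPhotons,
                                                nBatches = 2, seed = seed),
                  gridSpacingCm = gridSpacingCm)
}

# minimal explicit-VR little-endian DICOM slice writer (test fixture)
writeDicomSlice <- function(path, pixels, zMm, pixelSpacingMm = c(1, 1),
                            rescaleIntercept = -1024) {
  # pixels: (nx, ny) matrix, written x-fastest; DICOM Rows = ny, Columns = nx
  stopifnot(is.matrix(pixels))
  rows <- ncol(pixels); cols <- nrow(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  elem_short <- function(group, el, vr, value) {
    u16(group); u16(el)
    writeChar(vr, con, eos = NULL)
    if (vr == "US") { u16(2); u16(value) }
    else {            # string VRs, even-length padded
      s <- as.character(value)
      if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
      u16(nchar(s)); writeChar(s, con, eos = NULL)
    }
  }
  elem_short(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", zMm))
  elem_short(0x0028, 0x0010, "US", rows)
  elem_short(0x0028, 0x0011, "US", cols)
  elem_short(0x0028, 0x0030, "DS",
             sprintf("%g\\%g", pixelSpacingMm[1], pixelSpacingMm[2]))
  elem_short(0x0028, 0x1052, "DS", rescaleIntercept)
  elem_short(0x0028, 0x1053, "DS", 1)
  # PixelData, OW with 4-byte length
  u16(0x7fe0); u16(0x0010)
  writeChar("OW", con, eos = NULL); u16(0)
  writeBin(as.integer(2 * rows * cols), con, size = 4, endian = "little")
  # column-fastest within a row? store x-fastest to match the reader
  writeBin(as.integer(as.vector(pixels)), con, size = 2, endian = "little")
  invisible(path)
}

# Klein-Nishina quadrature oracle: mean scattered-energy fraction from
# numeric integration of the differential cross section over cos(theta)
knOracleMeanRatio <- function(energyKeV) {
  k <- energyKeV / 510.998950
  r <- function(c) 1 / (1 + k * (1 - c))
  f <- function(c) r(c)^2 * (r(c) + 1 / r(c) - (1 - c^2))
  num <- integrate(function(c) r(c) * f(c), -1, 1, rel.tol = 1e-10)$value
  den <- integrate(f, -1, 1, rel.tol = 1e-10)$value
  num / den
}

randomConditions <- function(n, seed = 42) {
  fluorodose:::.with_seed(seed, lapply(seq_len(n), function(i) {
    fluoroConditions(
      kvp = sample(40:150, 1), ma = sample(1:999, 1) / 10,
      fovCm = sample(10:48, 1), sidCm = sample(80:120, 1),
      lateralDeg = sample(-90:90, 1), caudcranDeg = sample(-30:30, 1),
      fps = sample(1:30, 1), filterCuMm = sample(0:9, 1) / 10,
      beamOn = sample(c(TRUE, FALSE), 1),
      irradiationTimeS = sample(0:9999, 1) / 10)
  }))
}
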