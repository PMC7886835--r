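EYE_LENS_FACTOR <- 1.550  # ICRP air kerma -> lens dose conversion, Gy/Gy

#' Per-node seed for the air-dose precompute
#'
#' Deterministic seed for angular node (i, j) (1-based indices into the
#' lateral and cranio-caudal node lists), so a standalone
#' [simulateAirKerma()] run can reproduce any table slice.
#'
#' @param seed build seed
#' @param i,j node indices (lateral, cranio-caudal)
#' @param nLat number of lateral nodes
#' @return an integer seed
#' @export
airdoseNodeSeed <- function(seed, i, j, nLat) {
  as.integer((as.double(seed) + 7919 * ((j - 1) * nLat + (i - 1))) %%
               2147483647)
}

#' Precompute the angular air-dose lookup table
#'
#' Runs [simulateAirKerma()] at every node of the angular grid spanning
#' -90..90 degrees lateral and -30..30 degrees cranio-caudal, at the fixed
#' beam-condition fingerprint (kVp, filtration, fov, SID). Node runs use
#' per-node derived seeds ([airdoseNodeSeed()]) so a build is
#' deterministic and any slice independently reproducible. With
#' \code{checkpointPath} the build is resumable: finished nodes are saved
#' after each run and an interrupted build resumes where it stopped.
#'
#' @param room a [RoomModel-class]
#' @param phantom a [VoxelPhantom-class]
#' @param conditions a [FluoroConditions-class]; mA scales at query time
#' @param latStepDeg,ccStepDeg angular steps; must divide 180 and 60
#' @param mc an [MCConfig-class] (per node)
#' @param gridSpacingCm room-lattice pitch
#' @param checkpointPath optional RDS checkpoint file
#' @param nodeLimit run at most this many nodes (returns an incomplete,
#'   checkpointed table; default all)
#' @return an [AirDoseTable-class]
#' @export
precomputeTable <- function(room, phantom, conditions, latStepDeg = 15,
                            ccStepDeg = 15, mc = mcConfig(),
                            gridSpacingCm = 10, checkpointPath = NULL,
                            nodeLimit = Inf) {
  if (180 %% latStepDeg != 0 || 60 %% ccStepDeg != 0)
    stop("angular steps must divide the -90..90 and -30..30 degree ranges")
  latNodes <- seq(-90, 90, by = latStepDeg)
  ccNodes <- seq(-30, 30, by = ccStepDeg)
  nL <- length(latNodes); nC <- length(ccNodes)
  done <- matrix(FALSE, nL, nC)
  kerma <- NULL; latticeMeta <- NULL
  if (!is.null(checkpointPath) && file.exists(checkpointPath)) {
    ck <- readRDS(checkpointPath)
    stopifnot(identical(ck$latNodes, latNodes), identical(ck$ccNodes, ccNodes))
    done <- ck$done; kerma <- ck$kerma; latticeMeta <- ck$latticeMeta
  }
  ran <- 0
  for (j in seq_len(nC)) for (i in seq_len(nL)) {
    if (done[i, j]) next
    if (ran >= nodeLimit) break
    mcNode <- mcConfig(mc@nPhotons, mc@cutoffKeV, mc@nBatches,
                       airdoseNodeSeed(mc@seed, i, j, nL),
                       mc@rayleighEnabled)
    pose <- carmPose(latNodes[i], ccNodes[j], conditions@sidCm)
    g <- simulateAirKerma(room, phantom, pose, conditions,
                          gridSpacingCm = gridSpacingCm, mc = mcNode)
    if (is.null(kerma)) {
      kerma <- array(0, c(nL, nC, dim(g@dosePerPhoton)))
      latticeMeta <- list(origin = g@originMm, spacing = g@spacingMm)
    }
    kerma[i, j, , , ] <- g@dosePerPhoton
    done[i, j] <- TRUE
    ran <- ran + 1
    if (!is.null(checkpointPath))
      saveRDS(list(latNodes = latNodes, ccNodes = ccNodes, done = done,
                   kerma = kerma, latticeMeta = latticeMeta), checkpointPath)
  }
  new("AirDoseTable", latNodes = latNodes, ccNodes = ccNodes,
      kermaPerPhoton = kerma,
      latticeOriginMm = latticeMeta$origin,
      latticeSpacingMm = latticeMeta$spacing,
      fingerprint = list(kvp = conditions@kvp,
                         filterCuMm = conditions@filterCuMm,
                         fovCm = conditions@fovCm, sidCm = conditions@sidCm),
      meta = list(nPhotons = mc@nPhotons, seed = mc@seed,
                  version = "airdose-table/1"),
      complete = all(done))
}

.lin_weights <- function(nodes, x) {
  n <- length(nodes)
  if (x <= nodes[1]) return(list(i = 1L, w = 0))
  if (x >= nodes[n]) return(list(i = n - 1L, w = 1))
  i <- findInterval(x, nodes)
  list(i = as.integer(i), w = (x - nodes[i]) / (nodes[i + 1] - nodes[i]))
}

#' Query the air-dose table
#'
#' Multilinear interpolation of the precomputed air kerma per photon --
#' bilinear over the angular nodes, trilinear over the room lattice (cell
#' centers) -- then scaled to a rate by [doseRateScale()] with the current
#' tube current. Returns 0 when the beam is off. Interpolation is exact at
#' nodes/cell centers and bounded by the neighboring node values; queries
#' outside the angular range or the lattice are errors, never
#' extrapolations.
#'
#' @param table an [AirDoseTable-class]
#' @param lateralDeg,caudcranDeg query angles (degrees)
#' @param positionXyzMm observer position, room frame (mm)
#' @param conditions current [FluoroConditions-class]; its (kVp,
#'   filtration, fov, SID) must match the table fingerprint
#' @param tubeOutputCalibration,pulseWidthS see [doseRateScale()]
#' @return air-kerma rate, Gy/s
#' @export
queryAirKerma <- function(table, lateralDeg, caudcranDeg, positionXyzMm,
                          conditions, tubeOutputCalibration = 2e10,
                          pulseWidthS = NULL) {
  stopifnot(is(table, "AirDoseTable"))
  fp <- table@fingerprint
  if (fp$kvp != conditions@kvp || fp$filterCuMm != conditions@filterCuMm ||
      fp$fovCm != conditions@fovCm || fp$sidCm != conditions@sidCm)
    stop("condition fingerprint mismatch: table built for ",
         sprintf("%g kV / %g mm Cu / fov %g / SID %g", fp$kvp, fp$filterCuMm,
                 fp$fovCm, fp$sidCm))
  if (lateralDeg < table@latNodes[1] ||
      lateralDeg > table@latNodes[length(table@latNodes)] ||
      caudcranDeg < table@ccNodes[1] ||
      caudcranDeg > table@ccNodes[length(table@ccNodes)])
    stop("query angle outside the precomputed range")
  if (!conditions@beamOn) return(0)
  d <- dim(table@kermaPerPhoton)[3:5]
  centers <- lapply(1:3, function(a)
    table@latticeOriginMm[a] + (seq_len(d[a]) - 0.5) * table@latticeSpacingMm[a])
  for (a in 1:3)
    if (positionXyzMm[a] < table@latticeOriginMm[a] ||
        positionXyzMm[a] > table@latticeOriginMm[a] +
          d[a] * table@latticeSpacingMm[a])
      stop("query position outside the room lattice")
  wl <- .lin_weights(table@latNodes, lateralDeg)
  wc <- .lin_weights(table@ccNodes, caudcranDeg)
  wp <- lapply(1:3, function(a) .lin_weights(centers[[a]], positionXyzMm[a]))
  acc <- 0
  for (a in 0:1) for (b in 0:1) for (x in 0:1) for (y in 0:1) for (z in 0:1) {
    w <- (if (a) wl$w else 1 - wl$w) * (if (b) wc$w else 1 - wc$w) *
         (if (x) wp[[1]]$w else 1 - wp[[1]]$w) *
         (if (y) wp[[2]]$w else 1 - wp[[2]]$w) *
         (if (z) wp[[3]]$w else 1 - wp[[3]]$w)
    if (w == 0) next
    acc <- acc + w * table@kermaPerPhoton[wl$i + a, wc$i + b,
                                          wp[[1]]$i + x, wp[[2]]$i + y,
                                          wp[[3]]$i + z]
  }
  doseRateScale(acc, conditions, tubeOutputCalibration, pulseWidthS)
}

#' Eye-lens dose rate from air kerma
#'
#' Applies the ICRP scalar conversion factor 1.550 Gy/Gy to the air-kerma
#' rate at the tracked head position. Exactly linear.
#'
#' @param airKermaRate air-kerma rate(s), Gy/s (>= 0)
#' @return an [EyeLensDose-class]
#' @export
eyelensDoseRate <- function(airKermaRate) {
  if (any(airKermaRate < 0)) stop("air kerma rate must be nonnegative")
  new("EyeLensDose", airKermaRate = airKermaRate,
      lensDoseRate = EYE_LENS_FACTOR * airKermaRate,
      conversionFactor = EYE_LENS_FACTOR)
}

#' Save / load an air-dose table
#'
#' Lossless round-trip through the two-file array container
#' (\code{/kerma} 5-D, \code{/lat_nodes}, \code{/cc_nodes} + metadata).
#' Schema mismatches and truncated payloads are format errors.
#'
#' @param table an [AirDoseTable-class]
#' @param prefix container path prefix
#' @return the prefix / the loaded [AirDoseTable-class]
#' @export
saveAirDoseTable <- function(table, prefix) {
  stopifnot(is(table, "AirDoseTable"))
  .write_array_container(prefix,
    list(kerma = table@kermaPerPhoton, lat_nodes = table@latNodes,
         cc_nodes = table@ccNodes),
    schema = "airdose-table/1",
    meta = list(lattice_origin_mm = table@latticeOriginMm,
                lattice_spacing_mm = table@latticeSpacingMm,
                fingerprint = table@fingerprint, build = table@meta,
                complete = table@complete))
}

#' @rdname saveAirDoseTable
#' @export
loadAirDoseTable <- function(prefix) {
  x <- .read_array_container(prefix, "airdose-table/1")
  new("AirDoseTable", latNodes = as.double(x$arrays$lat_nodes),
      ccNodes = as.double(x$arrays$cc_nodes),
      kermaPerPhoton = x$arrays$kerma,
      latticeOriginMm = as.double(x$meta$lattice_origin_mm),
      latticeSpacingMm = as.double(x$meta$lattice_spacing_mm),
      fingerprint = x$meta$fingerprint,
      meta = x$meta$build, complete = isTRUE(x$meta$complete))
}
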