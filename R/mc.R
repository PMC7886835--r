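#' Monte Carlo configuration
#'
#' @param nPhotons source photons (default 1e6; use 1e7 for
#'   production skin-dose maps)
#' @param cutoffKeV transport cutoff (>= 5 keV)
#' @param nBatches batches for the batch-variance uncertainty estimate
#' @param seed integer seed for the kernel's own bit-reproducible RNG
#' @param rayleighEnabled simulate coherent scatter
#' @return an [MCConfig-class]
#' @export
mcConfig <- function(nPhotons = 1e6, cutoffKeV = 5, nBatches = 10L,
                     seed = 1L, rayleighEnabled = FALSE) {
  new("MCConfig", nPhotons = nPhotons, cutoffKeV = cutoffKeV,
      nBatches = as.integer(nBatches), seed = as.integer(seed),
      rayleighEnabled = rayleighEnabled)
}

#' Sample the Klein-Nishina distribution
#'
#' Kahn's rejection method; the scattered energy satisfies the Compton
#' relation E' = E / (1 + (E/511)(1 - cos theta)) exactly.
#'
#' @param energyKeV incident photon energy
#' @param n number of samples
#' @param seed RNG seed (kernel RNG, bit-reproducible)
#' @return data.frame with \code{energyOut} (keV) and \code{cosTheta}
#' @export
kleinNishinaSample <- function(energyKeV, n, seed = 1) {
  stopifnot(energyKeV > 0)
  m <- cpp_kn_sample(energyKeV, as.integer(n), as.double(seed))
  data.frame(energyOut = m[, 1], cosTheta = m[, 2])
}

.mat_args <- function() {
  tab <- materialTable()
  list(egrid = tab@energyKeV, muRho = tab@muRho, mutrRho = tab@mutrRho,
       fPe = tab@fPe, fCo = tab@fCo)
}

# room that is just a padded air box around phantom and source (no walls)
.default_room <- function(phantom, sourceMm) {
  box <- rbind(phantom@originMm,
               phantom@originMm + dim(phantom@hu) * phantom@spacingMm,
               sourceMm)
  lo <- apply(box, 2, min) - 200; hi <- apply(box, 2, max) + 200
  lo <- pmin(lo, -1); hi <- pmax(hi, 1)   # keep the isocenter inside
  new("RoomModel", boxMinMm = lo, boxMaxMm = hi, wallThicknessMm = 0,
      wallDensity = 2.3, tableMinMm = c(0, 0, 0), tableMaxMm = c(0, 0, 0),
      tableDensity = 0.3, airDensity = 0.0012)
}

.run_transport <- function(phantom, room, pose, spectrum, mc,
                           scoreSkin, scoreAir, airSpacingCm = 10,
                           sourceModel = "beam", fovCm = NULL,
                           firstDepth = FALSE, sourceMm = NULL,
                           directionUnit = NULL) {
  g <- if (is.null(sourceMm)) carmPoseToSource(pose) else
    list(sourceXyz = sourceMm,
         detectorCenterXyz = sourceMm + directionUnit,
         axisUnit = directionUnit)
  origin <- phantom@originMm + (if (!is.null(pose)) pose@tableOffsetMm else 0)
  if (is.null(room)) room <- .default_room(phantom, g$sourceXyz)
  b <- .frustum_basis(g$axisUnit)
  cdf <- cumsum(spectrum@relFluence); cdf[length(cdf)] <- 1
  keep <- spectrum@relFluence > 0
  specE <- spectrum@energyBins
  halfFov <- if (sourceModel == "isotropic") -1 else
    if (is.null(fovCm) || fovCm <= 0) 0 else fovCm / 2
  airDims <- c(1L, 1L, 1L); airOrigin <- c(0, 0, 0)
  if (scoreAir) {
    ext <- (room@boxMaxMm - room@boxMinMm) / 10
    airDims <- pmax(as.integer(floor(ext / airSpacingCm)), 1L)
    airOrigin <- room@boxMinMm / 10
  }
  res <- cpp_transport(
    dim(phantom@hu), phantom@spacingMm / 10, origin / 10,
    phantom@materialId, phantom@density,
    array(as.integer(phantom@skinMask), dim(phantom@hu)),
    egrid = .mat_args()$egrid, muRho = .mat_args()$muRho,
    mutrRho = .mat_args()$mutrRho, fPe = .mat_args()$fPe,
    fCo = .mat_args()$fCo,
    specE = specE, specCdf = cdf,
    srcCm = g$sourceXyz / 10, detCm = g$detectorCenterXyz / 10,
    detU = b$u, detV = b$v, halfFovCm = halfFov,
    roomMinCm = room@boxMinMm / 10, roomMaxCm = room@boxMaxMm / 10,
    wallThickCm = room@wallThicknessMm / 10, wallDensity = room@wallDensity,
    wallMat = 4L, tableMinCm = room@tableMinMm / 10,
    tableMaxCm = room@tableMaxMm / 10, tableDensity = room@tableDensity,
    tableMat = 3L, airDensity = room@airDensity,
    scoreSkin = scoreSkin, scoreAir = scoreAir,
    airOriginCm = airOrigin, airSpacingCm = rep(airSpacingCm, 3),
    airDims = airDims,
    nPhotons = mc@nPhotons, nBatches = mc@nBatches,
    seed = as.double(mc@seed), rayleigh = mc@rayleighEnabled,
    cutoffKeV = mc@cutoffKeV, firstDepthMode = firstDepth)
  res$airDims <- airDims
  res$airOriginMm <- airOrigin * 10
  res$airSpacingMm <- rep(airSpacingCm * 10, 3)
  res
}

.energy_vec <- function(res) c(emitted = res$emitted_keV,
                               deposited = res$deposited_keV,
                               escaped = res$escaped_keV)

#' Simulate the patient skin-dose distribution
#'
#' Transports photons sampled from the filtered tube spectrum through the
#' collimated beam frustum into the voxel phantom (Woodcock tracking) and
#' scores energy deposited in skin-mask voxels, per source photon, with
#' per-voxel batch-variance uncertainty. Deterministic for a fixed seed.
#'
#' @param phantom a [VoxelPhantom-class]
#' @param pose a [CArmPose-class]; its table offset translates the phantom
#' @param conditions a [FluoroConditions-class] (kVp, filtration, fov)
#' @param mc an [MCConfig-class]
#' @param room optional [RoomModel-class]; default is a padded wall-less
#'   air box (room scatter contributes little to skin dose)
#' @return a [DoseGrid-class] on the phantom lattice
#' @export
simulateSkinDose <- function(phantom, pose, conditions, mc = mcConfig(),
                             room = NULL) {
  stopifnot(is(phantom, "VoxelPhantom"), is(pose, "CArmPose"),
            is(conditions, "FluoroConditions"), is(mc, "MCConfig"))
  g <- carmPoseToSource(pose)
  origin <- phantom@originMm + pose@tableOffsetMm
  lo <- origin / 10; hi <- (origin + dim(phantom@hu) * phantom@spacingMm) / 10
  hit <- .ray_aabb(g$sourceXyz / 10, g$axisUnit, lo, hi)
  if (!hit) stop("beam axis does not intersect the phantom (no-entrance)")
  spec <- generateSpectrum(conditions@kvp, conditions@filterCuMm)
  res <- .run_transport(phantom, room, pose, spec, mc, scoreSkin = TRUE,
                        scoreAir = FALSE, fovCm = conditions@fovCm)
  d <- dim(phantom@hu)
  new("DoseGrid", dosePerPhoton = array(res$skin_dose, d),
      relUncertainty = array(res$skin_relse, d),
      spacingMm = phantom@spacingMm,
      originMm = phantom@originMm + pose@tableOffsetMm,
      nPhotonsRun = res$n_photons_run, quantity = "skin_dose",
      energyKeV = .energy_vec(res))
}

.ray_aabb <- function(p, d, lo, hi) {
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(d[a]) < 1e-15) { if (p[a] < lo[a] || p[a] > hi[a]) return(FALSE) }
    else {
      tt <- sort(c((lo[a] - p[a]) / d[a], (hi[a] - p[a]) / d[a]))
      t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
    }
  }
  t1 > max(t0, 0)
}

#' Simulate the room air-kerma distribution
#'
#' Scores air kerma per source photon on a coarse room lattice with a
#' track-length fluence estimator (fluence x E x (mu_tr/rho)_air summed
#' over the spectrum), including photons scattered by the phantom, the
#' table slab and the concrete walls.
#'
#' @param room a [RoomModel-class]
#' @param phantom a [VoxelPhantom-class] (may be all air)
#' @param pose a [CArmPose-class]
#' @param conditions a [FluoroConditions-class]
#' @param gridSpacingCm air-lattice pitch (default 10 cm)
#' @param mc an [MCConfig-class]
#' @param sourceModel "beam" (collimated frustum) or "isotropic" (point
#'   source, for benchmark geometries)
#' @return a [DoseGrid-class] on the room lattice ("air_kerma")
#' @export
simulateAirKerma <- function(room, phantom, pose, conditions,
                             gridSpacingCm = 10, mc = mcConfig(),
                             sourceModel = c("beam", "isotropic")) {
  sourceModel <- match.arg(sourceModel)
  stopifnot(is(room, "RoomModel"))
  spec <- generateSpectrum(conditions@kvp, conditions@filterCuMm)
  res <- .run_transport(phantom, room, pose, spec, mc, scoreSkin = FALSE,
                        scoreAir = TRUE, airSpacingCm = gridSpacingCm,
                        sourceModel = sourceModel, fovCm = conditions@fovCm)
  new("DoseGrid", dosePerPhoton = array(res$air_kerma, res$airDims),
      relUncertainty = array(res$air_relse, res$airDims),
      spacingMm = res$airSpacingMm, originMm = res$airOriginMm,
      nPhotonsRun = res$n_photons_run, quantity = "air_kerma",
      energyKeV = .energy_vec(res))
}

#' First-interaction depths for a monoenergetic pencil beam
#'
#' Benchmark helper: fires a monoenergetic pencil beam from
#' \code{sourceMm} along \code{directionUnit} and returns the free path to
#' the first real interaction for every photon (Inf if it escapes). The
#' survival fraction beyond depth t in a homogeneous slab is exp(-mu t).
#'
#' @param phantom a [VoxelPhantom-class]
#' @param energyKeV beam energy
#' @param n photons
#' @param sourceMm,directionUnit beam geometry (room frame, mm / unit)
#' @param seed RNG seed
#' @return free paths in cm
#' @export
sampleFirstInteractionDepth <- function(phantom, energyKeV, n, sourceMm,
                                        directionUnit, seed = 1) {
  spec <- new("Spectrum", kvp = max(energyKeV, 40), filterCuMm = 0,
              energyBins = energyKeV, relFluence = 1, meanKeV = energyKeV)
  mc <- mcConfig(nPhotons = n, nBatches = 2L, seed = seed)
  res <- .run_transport(phantom, NULL, NULL, spec, mc, scoreSkin = FALSE,
                        scoreAir = FALSE, firstDepth = TRUE,
                        sourceMm = sourceMm, directionUnit = directionUnit)
  res$first_depth_cm[seq_len(res$n_photons_run)]
}

#' Scale per-photon dose to a clinical dose rate
#'
#' rate = dose_per_photon x calibration (photons/mAs) x mA x duty. The
#' pulse duty cycle defaults to continuous (1); pass the pulse width to
#' model pulsed fluoroscopy (duty = fps x pulse width).
#'
#' @param dosePerPhoton Gy per source photon (scalar or array)
#' @param conditions a [FluoroConditions-class] (mA, fps)
#' @param tubeOutputCalibration photons emitted into the beam per mAs;
#'   the default 2e10 is a nominal value, to be replaced by a site
#'   calibration
#' @param pulseWidthS optional pulse width (s) for pulsed mode
#' @return dose rate in Gy/s, same shape as \code{dosePerPhoton}
#' @export
doseRateScale <- function(dosePerPhoton, conditions,
                          tubeOutputCalibration = 2e10, pulseWidthS = NULL) {
  if (tubeOutputCalibration <= 0) stop("tube output calibration must be > 0")
  duty <- if (is.null(pulseWidthS)) 1 else conditions@fps * pulseWidthS
  dosePerPhoton * tubeOutputCalibration * conditions@ma * duty
}
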