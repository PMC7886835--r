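#' @useDynLib fluorodose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

MATERIALS <- c("air", "lung", "soft_tissue", "bone", "water", "copper")

#' Photon cross-section table
#'
#' Mass attenuation and mass energy-transfer coefficients for the six
#' materials the toolkit knows about (air, lung, soft tissue, bone, water,
#' copper), on a common ascending energy grid covering at least 5--150 keV,
#' together with the per-interaction partition of the total coefficient into
#' photoelectric, incoherent (Compton) and coherent (Rayleigh) fractions.
#' Interpolation between grid points is log-log, which is positive by
#' construction.
#'
#' @slot energyKeV ascending energy grid (keV)
#' @slot materials material names, column order of the coefficient matrices
#' @slot muRho mass attenuation coefficients (cm^2/g), energy x material
#' @slot mutrRho mass energy-transfer coefficients (cm^2/g)
#' @slot fPe,fCo,fRa interaction-type fractions of the total coefficient;
#'   they sum to 1 at every grid point
#' @export
setClass("MaterialTable",
  representation(energyKeV = "numeric", materials = "character",
                 muRho = "matrix", mutrRho = "matrix",
                 fPe = "matrix", fCo = "matrix", fRa = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (is.unsorted(object@energyKeV, strictly = TRUE))
      msg <- c(msg, "energy grid must be strictly ascending")
    if (min(object@energyKeV) > 5 || max(object@energyKeV) < 150)
      msg <- c(msg, "energy grid must cover 5-150 keV")
    if (any(object@muRho <= 0) || any(object@mutrRho <= 0))
      msg <- c(msg, "all coefficients must be positive")
    if (max(abs(object@fPe + object@fCo + object@fRa - 1)) > 1e-9)
      msg <- c(msg, "interaction fractions must sum to 1 at every grid point")
    if (is.null(msg)) TRUE else msg
  })

#' Filtered x-ray tube spectrum
#'
#' Discrete photon-fluence spectrum from a tungsten tube model (Kramers
#' bremsstrahlung shaped by copper filtration), binned on a regular energy
#' grid. Weights are zero above the tube potential and below the 5 keV
#' transport cutoff and sum to 1.
#'
#' @slot kvp tube potential (kV); equals the maximum photon energy in keV
#' @slot filterCuMm copper filtration (mm)
#' @slot energyBins bin-center energies (keV)
#' @slot relFluence normalized fluence weights
#' @slot meanKeV continuous fluence-weighted mean energy of the closed-form
#'   spectrum (Simpson quadrature, stored at construction)
#' @export
setClass("Spectrum",
  representation(kvp = "numeric", filterCuMm = "numeric",
                 energyBins = "numeric", relFluence = "numeric",
                 meanKeV = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@energyBins) != length(object@relFluence))
      msg <- c(msg, "bins and weights differ in length")
    if (any(object@relFluence < 0)) msg <- c(msg, "negative fluence weight")
    if (abs(sum(object@relFluence) - 1) > 1e-12)
      msg <- c(msg, "weights must sum to 1")
    if (any(object@relFluence[object@energyBins > object@kvp] > 0))
      msg <- c(msg, "nonzero fluence above the tube potential")
    if (any(object@energyBins[object@relFluence > 0] < 5))
      msg <- c(msg, "nonzero fluence below the 5 keV cutoff")
    if (is.null(msg)) TRUE else msg
  })

#' CT-derived voxel phantom
#'
#' Regular voxel grid in the room frame with per-voxel Hounsfield units,
#' material identity, mass density and a skin-layer mask. Indices are
#' 0-based in the geometry convention: the center of voxel (i,j,k) sits at
#' \code{origin + (c(i,j,k) + 0.5) * spacing} (mm), with the room origin at
#' the C-arm isocenter.
#'
#' @slot hu 3-D array of Hounsfield units
#' @slot materialId 3-D integer array, codes into \code{materialNames()}
#' @slot density 3-D array, g/cm^3
#' @slot skinMask 3-D logical array; a subset of non-air voxels adjacent to
#'   the air surface
#' @slot spacingMm,originMm voxel pitch and corner offset of voxel (0,0,0)
#' @export
setClass("VoxelPhantom",
  representation(hu = "array", materialId = "array", density = "array",
                 skinMask = "array", spacingMm = "numeric",
                 originMm = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@hu)
    if (length(d) != 3) msg <- c(msg, "hu must be a 3-D array")
    for (s in c("materialId", "density", "skinMask"))
      if (!identical(dim(slot(object, s)), d))
        msg <- c(msg, paste(s, "dimensions differ from hu"))
    if (length(object@spacingMm) != 3 || any(object@spacingMm <= 0))
      msg <- c(msg, "spacing must be three positive lengths")
    if (length(object@originMm) != 3) msg <- c(msg, "origin must be length 3")
    if (any(object@density < 0.0012 - 1e-12))
      msg <- c(msg, "density below dry air (0.0012 g/cm^3)")
    if (any(object@skinMask & object@materialId == 1L))
      msg <- c(msg, "skin mask marks air voxels")
    if (is.null(msg)) TRUE else msg
  })

#' C-arm pose
#'
#' Gantry angulation and distances of an isocentric C-arm. The lateral
#' angle spans RAO(-90) to LAO(+90) degrees, the cranio-caudal angle
#' caudal(-30) to cranial(+30) degrees -- the range covered by the
#' precomputed air-dose table. Table motion is represented as a phantom
#' translation (\code{tableOffsetMm}), not as C-arm motion.
#'
#' @slot lateralDeg,caudcranDeg gantry angles (degrees)
#' @slot sidCm source-to-image-receptor distance (cm)
#' @slot sisoCm source-to-isocenter distance (cm)
#' @slot tableOffsetMm (longitudinal, lateral, vertical) displacement (mm)
#' @export
setClass("CArmPose",
  representation(lateralDeg = "numeric", caudcranDeg = "numeric",
                 sidCm = "numeric", sisoCm = "numeric",
                 tableOffsetMm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (abs(object@lateralDeg) > 90) msg <- c(msg, "lateral angle outside [-90, 90]")
    if (abs(object@caudcranDeg) > 30) msg <- c(msg, "cranio-caudal angle outside [-30, 30]")
    if (!(object@sidCm > object@sisoCm && object@sisoCm > 0))
      msg <- c(msg, "need sid > siso > 0")
    if (length(object@tableOffsetMm) != 3) msg <- c(msg, "table offset must be length 3")
    if (is.null(msg)) TRUE else msg
  })

#' X-ray beam frustum
#'
#' Square pyramid from the focal spot through the collimated fov x fov
#' square on the detector plane.
#'
#' @slot sourceXyz,detectorCenterXyz mm, room frame
#' @slot axisUnit unit vector source -> detector
#' @slot fovAtDetectorCm side of the square field at the detector
#' @slot cornerRays 3 x 4 matrix of unit vectors through the field corners
#' @export
setClass("BeamFrustum",
  representation(sourceXyz = "numeric", detectorCenterXyz = "numeric",
                 axisUnit = "numeric", fovAtDetectorCm = "numeric",
                 cornerRays = "matrix"))

#' Interventional-suite room model
#'
#' Axis-aligned room box centered on the isocenter, concrete walls of given
#' thickness outside it, a low-density patient-table slab, and air filling
#' the rest. Wall photon transport uses cortical-bone cross sections at
#' concrete density (similar effective Z).
#'
#' @slot boxMinMm,boxMaxMm inner (air) box corners, mm, room frame
#' @slot wallThicknessMm concrete wall thickness (0 disables walls)
#' @slot wallDensity g/cm^3
#' @slot tableMinMm,tableMaxMm table-slab corners (zero-volume disables it)
#' @slot tableDensity g/cm^3 (carbon-fiber sandwich, low bulk density)
#' @slot airDensity g/cm^3
#' @export
setClass("RoomModel",
  representation(boxMinMm = "numeric", boxMaxMm = "numeric",
                 wallThicknessMm = "numeric", wallDensity = "numeric",
                 tableMinMm = "numeric", tableMaxMm = "numeric",
                 tableDensity = "numeric", airDensity = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@boxMaxMm <= object@boxMinMm))
      msg <- c(msg, "degenerate room box")
    if (any(object@boxMinMm > 0) || any(object@boxMaxMm < 0))
      msg <- c(msg, "isocenter (origin) must lie inside the room box")
    if (object@wallThicknessMm < 0) msg <- c(msg, "negative wall thickness")
    if (is.null(msg)) TRUE else msg
  })

#' Fluoroscopic system state
#'
#' One timestamped snapshot of the x-ray system: tube potential and current,
#' field of view, source-to-image-receptor distance, gantry angles, pulse
#' rate, copper filtration, the irradiation (beam-on) flag, cumulative
#' irradiation time and the table offset recovered from the ultrasonic
#' ranging unit.
#'
#' @export
setClass("FluoroConditions",
  representation(kvp = "numeric", ma = "numeric", fovCm = "numeric",
                 sidCm = "numeric", lateralDeg = "numeric",
                 caudcranDeg = "numeric", fps = "numeric",
                 filterCuMm = "numeric", beamOn = "logical",
                 irradiationTimeS = "numeric", tableOffsetMm = "numeric",
                 timestampS = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@kvp < 40 || object@kvp > 150) msg <- c(msg, "kvp outside [40, 150]")
    if (object@beamOn && object@ma <= 0) msg <- c(msg, "beam on with nonpositive mA")
    if (!(object@fps %in% 1:30)) msg <- c(msg, "fps outside 1..30")
    if (length(object@tableOffsetMm) != 3) msg <- c(msg, "table offset must be length 3")
    if (is.null(msg)) TRUE else msg
  })

#' Monte Carlo run configuration
#'
#' @slot nPhotons source photons to run
#' @slot cutoffKeV transport cutoff; photons below it deposit locally (>= 5)
#' @slot nBatches statistically independent batches for the uncertainty
#'   estimate
#' @slot seed integer RNG seed (the transport kernel has its own
#'   counter-based generator; results are bit-reproducible across platforms)
#' @slot rayleighEnabled simulate coherent scatter (default off; when off the
#'   coherent part of the attenuation coefficient is excluded consistently)
#' @export
setClass("MCConfig",
  representation(nPhotons = "numeric", cutoffKeV = "numeric",
                 nBatches = "integer", seed = "integer",
                 rayleighEnabled = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@nBatches < 2) msg <- c(msg, "need at least 2 batches")
    if (object@nPhotons < object@nBatches)
      msg <- c(msg, "need nPhotons >= nBatches")
    if (object@cutoffKeV < 5) msg <- c(msg, "cutoff below 5 keV")
    if (is.null(msg)) TRUE else msg
  })

#' Scored dose grid
#'
#' Per-voxel dose (or air kerma) per source photon on a regular lattice,
#' with per-voxel relative statistical uncertainty from batch variance
#' (relative standard error of the batch mean). For skin-dose runs the
#' lattice is the phantom lattice and only skin-mask voxels are nonzero;
#' for air-kerma runs it is a coarse room lattice.
#'
#' @slot dosePerPhoton Gy per source photon, 3-D array
#' @slot relUncertainty fractional standard error per voxel (NA where zero)
#' @slot spacingMm,originMm lattice geometry
#' @slot nPhotonsRun photons simulated
#' @slot quantity "skin_dose" or "air_kerma"
#' @slot energyKeV emitted/deposited/escaped bookkeeping (named vector)
#' @export
setClass("DoseGrid",
  representation(dosePerPhoton = "array", relUncertainty = "array",
                 spacingMm = "numeric", originMm = "numeric",
                 nPhotonsRun = "numeric", quantity = "character",
                 energyKeV = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@dosePerPhoton), dim(object@relUncertainty)))
      msg <- c(msg, "dose and uncertainty dimensions differ")
    if (any(object@dosePerPhoton < 0)) msg <- c(msg, "negative dose")
    ru <- object@relUncertainty[object@dosePerPhoton > 0]
    if (any(!is.finite(ru)) || any(ru < 0))
      msg <- c(msg, "uncertainty must be finite and nonnegative where dose > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Angular air-dose lookup table
#'
#' Air kerma per source photon on a 3-D room lattice, precomputed at every
#' node of a (lateral, cranio-caudal) angular grid spanning -90..90 and
#' -30..30 degrees. A table is valid for exactly one beam-condition
#' fingerprint (kVp, filtration, field of view, SID); tube current and time
#' scale linearly at query time. Queries outside the angular range are an
#' error, never an extrapolation.
#'
#' @slot latNodes,ccNodes strictly ascending angle nodes (degrees)
#' @slot kermaPerPhoton 5-D array (lat, cc, x, y, z), Gy per source photon
#' @slot latticeOriginMm,latticeSpacingMm room-lattice geometry
#' @slot fingerprint list(kvp, filterCuMm, fovCm, sidCm)
#' @slot meta build metadata: nPhotons per node, seed, schema/code version
#' @slot complete FALSE while a checkpointed build is unfinished
#' @export
setClass("AirDoseTable",
  representation(latNodes = "numeric", ccNodes = "numeric",
                 kermaPerPhoton = "array", latticeOriginMm = "numeric",
                 latticeSpacingMm = "numeric", fingerprint = "list",
                 meta = "list", complete = "logical"),
  validity = function(object) {
    msg <- NULL
    if (is.unsorted(object@latNodes, strictly = TRUE) ||
        is.unsorted(object@ccNodes, strictly = TRUE))
      msg <- c(msg, "angle nodes must be strictly ascending")
    if (object@latNodes[1] > -90 || object@latNodes[length(object@latNodes)] < 90)
      msg <- c(msg, "lateral nodes must span -90..90 degrees")
    if (object@ccNodes[1] > -30 || object@ccNodes[length(object@ccNodes)] < 30)
      msg <- c(msg, "cranio-caudal nodes must span -30..30 degrees")
    d <- dim(object@kermaPerPhoton)
    if (length(d) != 5 || d[1] != length(object@latNodes) ||
        d[2] != length(object@ccNodes))
      msg <- c(msg, "kerma array must be 5-D indexed (lat, cc, x, y, z)")
    if (isTRUE(object@complete) && any(object@kermaPerPhoton < 0))
      msg <- c(msg, "negative kerma")
    if (is.null(msg)) TRUE else msg
  })

#' Eye-lens dose from air kerma
#'
#' Scalar conversion of air kerma at the tracked head position to
#' crystalline-lens dose using the ICRP factor 1.550 Gy/Gy.
#'
#' @slot airKermaRate Gy/s at the observer position
#' @slot lensDoseRate Gy/s; exactly 1.550 x airKermaRate
#' @slot conversionFactor the constant 1.550
#' @export
setClass("EyeLensDose",
  representation(airKermaRate = "numeric", lensDoseRate = "numeric",
                 conversionFactor = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@airKermaRate < 0)) msg <- c(msg, "negative air kerma")
    if (any(abs(object@lensDoseRate -
                object@conversionFactor * object@airKermaRate) > 0))
      msg <- c(msg, "lens dose must be exactly factor x kerma")
    if (is.null(msg)) TRUE else msg
  })
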