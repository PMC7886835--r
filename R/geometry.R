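#' Construct fluoroscopic conditions
#'
#' Defaults are the toolkit's reference beam protocol: 76 kV, 2.5 mA,
#' 20 x 20 cm field of view, 15 frames/s, SID 100 cm, 0.3 mm Cu.
#'
#' @param kvp,ma,fovCm,sidCm,lateralDeg,caudcranDeg,fps,filterCuMm beam
#'   parameters
#' @param beamOn irradiation flag
#' @param irradiationTimeS cumulative irradiation time (s)
#' @param tableOffsetMm table displacement (longitudinal, lateral, vertical)
#' @param timestampS record timestamp (s)
#' @return a [FluoroConditions-class]
#' @export
fluoroConditions <- function(kvp = 76, ma = 2.5, fovCm = 20, sidCm = 100,
                             lateralDeg = 0, caudcranDeg = 0, fps = 15,
                             filterCuMm = 0.3, beamOn = TRUE,
                             irradiationTimeS = 0, tableOffsetMm = c(0, 0, 0),
                             timestampS = 0) {
  new("FluoroConditions", kvp = as.double(kvp), ma = as.double(ma),
      fovCm = as.double(fovCm), sidCm = as.double(sidCm),
      lateralDeg = as.double(lateralDeg),
      caudcranDeg = as.double(caudcranDeg), fps = as.double(fps),
      filterCuMm = as.double(filterCuMm), beamOn = beamOn,
      irradiationTimeS = as.double(irradiationTimeS),
      tableOffsetMm = as.double(tableOffsetMm),
      timestampS = as.double(timestampS))
}

#' Construct a C-arm pose
#'
#' @param lateralDeg,caudcranDeg gantry angles (degrees)
#' @param sidCm source-to-image-receptor distance (cm)
#' @param sisoCm source-to-isocenter distance (cm); default 72 cm, typical
#'   for an isocentric C-arm
#' @param tableOffsetMm table displacement, modeled as a phantom translation
#' @return a [CArmPose-class]
#' @export
carmPose <- function(lateralDeg = 0, caudcranDeg = 0, sidCm = 100,
                     sisoCm = 72, tableOffsetMm = c(0, 0, 0)) {
  new("CArmPose", lateralDeg = lateralDeg, caudcranDeg = caudcranDeg,
      sidCm = sidCm, sisoCm = sisoCm, tableOffsetMm = tableOffsetMm)
}

#' @rdname carmPose
#' @param conditions a [FluoroConditions-class] whose angles, SID and table
#'   offset define the pose
#' @export
poseFromConditions <- function(conditions, sisoCm = 72) {
  carmPose(conditions@lateralDeg, conditions@caudcranDeg,
           conditions@sidCm, sisoCm, conditions@tableOffsetMm)
}

#' Construct a room model
#'
#' Room box centered laterally on the isocenter with the floor
#' \code{floorBelowIsoM} below it; concrete walls outside the box; a
#' low-density table slab under the patient.
#'
#' @param sizeM room box (x, y, z) in meters
#' @param floorBelowIsoM floor depth below the isocenter (m)
#' @param wallThicknessCm concrete thickness (0 disables wall transport)
#' @param wallDensity,tableDensity,airDensity g/cm^3
#' @param tableSlab list(min, max) corners in mm, or NULL for the default
#'   slab just below the patient
#' @return a [RoomModel-class]
#' @export
roomModel <- function(sizeM = c(4, 3, 4), floorBelowIsoM = 1.2,
                      wallThicknessCm = 10, wallDensity = 2.3,
                      tableDensity = 0.3, airDensity = 0.0012,
                      tableSlab = NULL) {
  half <- sizeM * 1000 / 2
  bmin <- c(-half[1], -floorBelowIsoM * 1000, -half[3])
  bmax <- c(half[1], sizeM[2] * 1000 - floorBelowIsoM * 1000, half[3])
  if (is.null(tableSlab))
    tableSlab <- list(min = c(-250, -155, -1000), max = c(250, -125, 1000))
  new("RoomModel", boxMinMm = bmin, boxMaxMm = bmax,
      wallThicknessMm = wallThicknessCm * 10, wallDensity = wallDensity,
      tableMinMm = tableSlab$min, tableMaxMm = tableSlab$max,
      tableDensity = tableDensity, airDensity = airDensity)
}

.rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}
.rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

#' Source and detector positions for a C-arm pose
#'
#' Room frame: right-handed, origin at the isocenter, +x patient-left,
#' +y patient-anterior (up for a supine patient), +z cranial. The PA pose
#' (0, 0) puts the source under the table at (0, -siso, 0). Rotation order
#' is frozen as lateral about +z first, then cranio-caudal about the
#' rotated +x (this convention may differ from a given vendor's console).
#' Table motion translates the phantom, never the C-arm.
#'
#' @param pose a [CArmPose-class]
#' @return list with \code{sourceXyz}, \code{detectorCenterXyz} (mm) and
#'   \code{axisUnit} (source -> detector)
#' @export
carmPoseToSource <- function(pose) {
  stopifnot(is(pose, "CArmPose"))
  R <- .rot_z(pose@lateralDeg) %*% .rot_x(pose@caudcranDeg)
  src <- as.vector(R %*% c(0, -pose@sisoCm * 10, 0))
  axis <- -src / sqrt(sum(src^2))
  list(sourceXyz = src,
       detectorCenterXyz = src + axis * pose@sidCm * 10,
       axisUnit = axis)
}

.frustum_basis <- function(axis) {
  ref <- if (abs(axis[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- c(ref[2] * axis[3] - ref[3] * axis[2],
         ref[3] * axis[1] - ref[1] * axis[3],
         ref[1] * axis[2] - ref[2] * axis[1])
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = v)
}

#' Beam frustum for a pose and field of view
#'
#' Square pyramid from the focal spot through the fov x fov square on the
#' detector plane; the side half-angle is atan((fov/2) / SID).
#'
#' @param pose a [CArmPose-class]
#' @param fovCm field side length at the detector (cm)
#' @return a [BeamFrustum-class]
#' @export
beamFrustum <- function(pose, fovCm) {
  stopifnot(fovCm > 0)
  g <- carmPoseToSource(pose)
  b <- .frustum_basis(g$axisUnit)
  half <- fovCm * 10 / 2
  corners <- vapply(list(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)),
    function(s) {
      p <- g$detectorCenterXyz + s[1] * half * b$u + s[2] * half * b$v
      d <- p - g$sourceXyz
      d / sqrt(sum(d^2))
    }, numeric(3))
  new("BeamFrustum", sourceXyz = g$sourceXyz,
      detectorCenterXyz = g$detectorCenterXyz, axisUnit = g$axisUnit,
      fovAtDetectorCm = fovCm, cornerRays = corners)
}

#' Frustum membership and size
#'
#' \code{inFrustum} tests points (mm, room frame; rows of a matrix) against
#' the pyramid; \code{frustumHalfAngle} returns atan((fov/2)/SID) in
#' degrees; \code{frustumSolidAngle} the subtended solid angle (sr).
#'
#' @param frustum a [BeamFrustum-class]
#' @param pointsMm n x 3 matrix of room coordinates (mm)
#' @return logical vector / numbers
#' @export
inFrustum <- function(frustum, pointsMm) {
  pointsMm <- matrix(pointsMm, ncol = 3)
  b <- .frustum_basis(frustum@axisUnit)
  rel <- sweep(pointsMm, 2, frustum@sourceXyz)
  t <- rel %*% frustum@axisUnit
  sidMm <- sqrt(sum((frustum@detectorCenterXyz - frustum@sourceXyz)^2))
  halfSlope <- frustum@fovAtDetectorCm * 10 / 2 / sidMm
  du <- abs(rel %*% b$u); dv <- abs(rel %*% b$v)
  as.vector(t > 0 & du <= t * halfSlope + 1e-9 & dv <= t * halfSlope + 1e-9)
}

#' @rdname inFrustum
#' @export
frustumHalfAngle <- function(frustum) {
  sidMm <- sqrt(sum((frustum@detectorCenterXyz - frustum@sourceXyz)^2))
  atan(frustum@fovAtDetectorCm * 10 / 2 / sidMm) * 180 / pi
}

#' @rdname inFrustum
#' @export
frustumSolidAngle <- function(frustum) {
  a <- frustumHalfAngle(frustum) * pi / 180
  4 * asin(sin(a) * sin(a))
}

#' Source-to-surface distance along the central axis
#'
#' Ray-marches from the focal spot along the beam axis at sub-voxel steps
#' and returns the distance (cm) to the first skin voxel, honoring the
#' pose's table offset (phantom translation).
#'
#' @param pose a [CArmPose-class]
#' @param phantom a [VoxelPhantom-class]
#' @return SSD in cm
#' @export
entranceSsd <- function(pose, phantom) {
  stopifnot(is(phantom, "VoxelPhantom"))
  g <- carmPoseToSource(pose)
  origin <- phantom@originMm + pose@tableOffsetMm
  d <- dim(phantom@hu); sp <- phantom@spacingMm
  step <- 0.2 * min(sp)
  tmax <- pose@sidCm * 10 + sqrt(sum((d * sp)^2))
  for (t in seq(0, tmax, by = step)) {
    p <- g$sourceXyz + t * g$axisUnit
    idx <- floor((p - origin) / sp) + 1
    if (all(idx >= 1) && all(idx <= d) &&
        phantom@skinMask[idx[1], idx[2], idx[3]])
      return(t / 10)
  }
  stop("beam axis does not enter the phantom surface (no-entrance)")
}
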