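#' Accessors
#'
#' Small accessor generics for the toolkit's S4 objects; slot access from
#' user code should go through these.
#'
#' @param object an S4 object from this package
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("doseArray", function(object) standardGeneric("doseArray"))
#' @rdname accessors
#' @export
setGeneric("relUncertainty", function(object) standardGeneric("relUncertainty"))
#' @rdname accessors
#' @export
setGeneric("spacingMm", function(object) standardGeneric("spacingMm"))
#' @rdname accessors
#' @export
setGeneric("originMm", function(object) standardGeneric("originMm"))
#' @rdname accessors
#' @export
setGeneric("skinMask", function(object) standardGeneric("skinMask"))
#' @rdname accessors
#' @export
setGeneric("materialIds", function(object) standardGeneric("materialIds"))
#' @rdname accessors
#' @export
setGeneric("densityGrid", function(object) standardGeneric("densityGrid"))
#' @rdname accessors
#' @export
setGeneric("huGrid", function(object) standardGeneric("huGrid"))
#' @rdname accessors
#' @export
setGeneric("energyBins", function(object) standardGeneric("energyBins"))
#' @rdname accessors
#' @export
setGeneric("relFluence", function(object) standardGeneric("relFluence"))
#' @rdname accessors
#' @export
setGeneric("meanEnergy", function(object) standardGeneric("meanEnergy"))
#' @rdname accessors
#' @export
setGeneric("beamOn", function(object) standardGeneric("beamOn"))

#' @rdname accessors
setMethod("doseArray", "DoseGrid", function(object) object@dosePerPhoton)
#' @rdname accessors
setMethod("relUncertainty", "DoseGrid", function(object) object@relUncertainty)
#' @rdname accessors
setMethod("spacingMm", "DoseGrid", function(object) object@spacingMm)
#' @rdname accessors
setMethod("originMm", "DoseGrid", function(object) object@originMm)
#' @rdname accessors
setMethod("spacingMm", "VoxelPhantom", function(object) object@spacingMm)
#' @rdname accessors
setMethod("originMm", "VoxelPhantom", function(object) object@originMm)
#' @rdname accessors
setMethod("skinMask", "VoxelPhantom", function(object) object@skinMask)
#' @rdname accessors
setMethod("materialIds", "VoxelPhantom", function(object) object@materialId)
#' @rdname accessors
setMethod("densityGrid", "VoxelPhantom", function(object) object@density)
#' @rdname accessors
setMethod("huGrid", "VoxelPhantom", function(object) object@hu)
#' @rdname accessors
setMethod("energyBins", "Spectrum", function(object) object@energyBins)
#' @rdname accessors
setMethod("relFluence", "Spectrum", function(object) object@relFluence)
#' @rdname accessors
setMethod("meanEnergy", "Spectrum", function(object) object@meanKeV)
#' @rdname accessors
setMethod("beamOn", "FluoroConditions", function(object) object@beamOn)

#' Material names and codes
#'
#' Integer material codes used in voxel grids, in this order.
#' @return character vector of the six material names
#' @export
materialNames <- function() MATERIALS

setMethod("show", "VoxelPhantom", function(object) {
  d <- dim(object@hu)
  cat("VoxelPhantom", paste(d, collapse = " x "), "voxels @",
      paste(object@spacingMm, collapse = "/"), "mm\n")
  tab <- table(factor(MATERIALS[object@materialId], levels = MATERIALS))
  cat("  materials:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  skin voxels:", sum(object@skinMask), "\n")
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum %g kVp, %g mm Cu: %d bins, mean %.2f keV\n",
              object@kvp, object@filterCuMm, length(object@energyBins),
              object@meanKeV))
})

setMethod("show", "DoseGrid", function(object) {
  cat(sprintf("DoseGrid [%s] %s voxels, %.3g photons\n", object@quantity,
              paste(dim(object@dosePerPhoton), collapse = " x "),
              object@nPhotonsRun))
  nz <- object@dosePerPhoton > 0
  if (any(nz))
    cat(sprintf("  peak %.3e Gy/photon (rel. SE %.2f%%), %d nonzero voxels\n",
                max(object@dosePerPhoton),
                100 * object@relUncertainty[which.max(object@dosePerPhoton)],
                sum(nz)))
})

setMethod("show", "AirDoseTable", function(object) {
  cat(sprintf("AirDoseTable %d x %d angle nodes, lattice %s, %s\n",
              length(object@latNodes), length(object@ccNodes),
              paste(dim(object@kermaPerPhoton)[3:5], collapse = " x "),
              if (object@complete) "complete" else "INCOMPLETE"))
  fp <- object@fingerprint
  cat(sprintf("  fingerprint: %g kVp, %g mm Cu, fov %g cm, SID %g cm\n",
              fp$kvp, fp$filterCuMm, fp$fovCm, fp$sidCm))
})

setMethod("show", "FluoroConditions", function(object) {
  cat(sprintf("FluoroConditions t=%.2fs %s: %g kV %g mA fov %g SID %g lat %g cc %g %g fps\n",
              object@timestampS, if (object@beamOn) "ON" else "off",
              object@kvp, object@ma, object@fovCm, object@sidCm,
              object@lateralDeg, object@caudcranDeg, object@fps))
})
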