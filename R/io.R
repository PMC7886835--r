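# Two-file array container: <prefix>.json header + <prefix>.bin payload of
# little-endian float64 segments in header order. The header carries a
# schema tag, per-array dimensions and free-form metadata; the loader
# validates schema and payload size, so truncated files fail loudly.

.CONTAINER_SCHEMA <- "fluorodose-array/1"

.write_array_container <- function(prefix, arrays, schema, meta = list()) {
  hdr <- list(schema = .CONTAINER_SCHEMA, kind = schema,
              arrays = lapply(arrays, function(a)
                list(dim = as.integer(if (is.null(dim(a))) length(a) else dim(a)))),
              meta = meta)
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (a in arrays) writeBin(as.double(a), con, size = 8, endian = "little")
  invisible(prefix)
}

.read_array_container <- function(prefix, kind) {
  jpath <- paste0(prefix, ".json"); bpath <- paste0(prefix, ".bin")
  if (!file.exists(jpath) || !file.exists(bpath))
    stop("container not found at prefix ", prefix)
  hdr <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  if (!identical(hdr$schema, .CONTAINER_SCHEMA) || !identical(hdr$kind, kind))
    stop("container format/schema mismatch: expected ", kind)
  lens <- vapply(hdr$arrays, function(a) prod(as.integer(a$dim)), numeric(1))
  if (file.size(bpath) != 8 * sum(lens))
    stop("container payload truncated or corrupt: ", bpath)
  con <- file(bpath, "rb")
  on.exit(close(con))
  out <- list()
  for (nm in names(hdr$arrays)) {
    d <- as.integer(hdr$arrays[[nm]]$dim)
    v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
    out[[nm]] <- if (length(d) > 1) array(v, d) else v
  }
  list(arrays = out, meta = hdr$meta)
}

#' Save / load a phantom in the raw-voxel container
#'
#' \code{<prefix>.raw} holds the HU grid as little-endian int16, x-fastest;
#' \code{<prefix>.json} is a sidecar with \code{shape}, \code{spacing_mm}
#' and \code{origin_mm}. The round-trip is bit-exact on the HU grid.
#'
#' @param phantom a [VoxelPhantom-class]
#' @param prefix file path prefix (no extension)
#' @return the prefix, invisibly
#' @export
savePhantomRaw <- function(phantom, prefix) {
  stopifnot(is(phantom, "VoxelPhantom"))
  side <- list(schema = "fluorodose-raw-ct/1",
               shape = dim(phantom@hu),
               spacing_mm = phantom@spacingMm,
               origin_mm = phantom@originMm)
  jsonlite::write_json(side, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.integer(round(phantom@hu)), con, size = 2, endian = "little")
  invisible(prefix)
}

#' Load a CT volume
#'
#' Accepts either a directory containing a single-series DICOM CT stack or
#' the raw-voxel container prefix written by [savePhantomRaw()]. HU are
#' mapped to material and density via [huToMaterial()] and the skin layer
#' is extracted.
#'
#' @param path DICOM directory or raw-container prefix
#' @param spacingOverride optional length-3 voxel pitch (mm) replacing the
#'   stored one
#' @param skinLayerMm skin-layer depth
#' @return a [VoxelPhantom-class]
#' @export
loadCt <- function(path, spacingOverride = NULL, skinLayerMm = 3) {
  if (dir.exists(path)) {
    vol <- .read_dicom_series(path)
  } else {
    jpath <- paste0(path, ".json")
    if (!file.exists(jpath)) stop("no raw-container sidecar at ", jpath)
    side <- jsonlite::read_json(jpath, simplifyVector = TRUE)
    for (f in c("shape", "spacing_mm", "origin_mm"))
      if (is.null(side[[f]])) stop("raw-container sidecar missing field ", f)
    shape <- as.integer(side$shape)
    con <- file(paste0(path, ".raw"), "rb")
    hu <- readBin(con, "integer", n = prod(shape), size = 2, signed = TRUE,
                  endian = "little")
    close(con)
    if (length(hu) != prod(shape)) stop("raw voxel payload truncated")
    vol <- list(hu = array(as.double(hu), shape),
                spacing = as.double(side$spacing_mm),
                origin = as.double(side$origin_mm))
  }
  spacing <- if (is.null(spacingOverride)) vol$spacing else
    rep(spacingOverride, length.out = 3)
  phantomFromHu(vol$hu, spacing, vol$origin, skinLayerMm = skinLayerMm)
}

#' Save / load a dose grid
#'
#' Lossless round-trip of a [DoseGrid-class] through the two-file array
#' container (\code{/dose}, \code{/rel_unc} plus metadata).
#'
#' @param grid a [DoseGrid-class]
#' @param prefix container path prefix
#' @return the prefix ([saveDoseGrid()]) or the grid ([loadDoseGrid()])
#' @export
saveDoseGrid <- function(grid, prefix) {
  stopifnot(is(grid, "DoseGrid"))
  ru <- grid@relUncertainty
  ru[!is.finite(ru)] <- -1
  .write_array_container(prefix,
    list(dose = grid@dosePerPhoton, rel_unc = ru),
    schema = "dose-grid/1",
    meta = list(spacing_mm = grid@spacingMm, origin_mm = grid@originMm,
                n_photons = grid@nPhotonsRun, quantity = grid@quantity,
                energy_keV = as.list(grid@energyKeV)))
}

#' @rdname saveDoseGrid
#' @export
loadDoseGrid <- function(prefix) {
  x <- .read_array_container(prefix, "dose-grid/1")
  ru <- x$arrays$rel_unc
  ru[ru < 0] <- NA_real_
  new("DoseGrid", dosePerPhoton = x$arrays$dose, relUncertainty = ru,
      spacingMm = as.double(x$meta$spacing_mm),
      originMm = as.double(x$meta$origin_mm),
      nPhotonsRun = as.double(x$meta$n_photons),
      quantity = x$meta$quantity,
      energyKeV = unlist(x$meta$energy_keV))
}

#' Export the skin-dose layer as a point list
#'
#' Writes one CSV row (x_mm, y_mm, z_mm, dose_Gy) per skin voxel with
#' nonzero dose, voxel-center coordinates in the room frame, for external
#' renderers.
#'
#' @param grid a skin [DoseGrid-class]
#' @param phantom the matching [VoxelPhantom-class]
#' @param path output CSV path
#' @export
exportSkinDoseCsv <- function(grid, phantom, path) {
  idx <- which(phantom@skinMask, arr.ind = TRUE)
  pos <- sweep((idx - 0.5) %*% diag(phantom@spacingMm), 2,
               phantom@originMm, "+")
  df <- data.frame(x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
                   dose_Gy = grid@dosePerPhoton[phantom@skinMask])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
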