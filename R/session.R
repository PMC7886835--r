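#' Observer (tracked head) state
#'
#' Stand-in for the headset pose stream: a timestamped head position in
#' the room frame.
#'
#' @param timestampS timestamp (s)
#' @param headPositionXyzMm position, mm, room frame
#' @param valid tracking-valid flag
#' @return observer record (list)
#' @export
observerState <- function(timestampS, headPositionXyzMm, valid = TRUE) {
  list(timestampS = timestampS, headPositionXyzMm = headPositionXyzMm,
       valid = valid)
}

#' Accumulate skin dose
#'
#' cumulative += increment_per_photon x calibration x mA x duration.
#' Associative in duration and per-voxel monotone non-decreasing.
#'
#' @param cumulative 3-D array of cumulative dose (Gy), phantom lattice
#' @param incrementGrid a per-photon skin [DoseGrid-class]
#' @param durationS exposure duration (s)
#' @param conditions a [FluoroConditions-class] (mA, fps)
#' @param tubeOutputCalibration,pulseWidthS see [doseRateScale()]
#' @return updated cumulative array
#' @export
accumulateDose <- function(cumulative, incrementGrid, durationS, conditions,
                           tubeOutputCalibration = 2e10, pulseWidthS = NULL) {
  if (!identical(dim(cumulative), dim(incrementGrid@dosePerPhoton)))
    stop("cumulative and increment grids are on different lattices")
  if (durationS < 0) stop("negative duration")
  cumulative + doseRateScale(incrementGrid@dosePerPhoton, conditions,
                             tubeOutputCalibration, pulseWidthS) * durationS
}

.DOSE_RAMP <- c("#00008B", "#0000FF", "#00FFFF", "#00FF00", "#FFFF00",
                "#FF8000", "#FF0000")

# map dose values to color indices (1..256) and hex colors
.dose_colors <- function(dose, maxDose, scale = "linear") {
  pal <- grDevices::colorRampPalette(.DOSE_RAMP)(256)
  if (maxDose <= 0) return(list(index = rep(1L, length(dose)),
                                hex = pal[rep(1L, length(dose))], pal = pal))
  frac <- if (scale == "log") {
    floorv <- maxDose * 1e-4
    pmax(log(pmax(dose, floorv) / floorv), 0) / log(maxDose / floorv)
  } else dose / maxDose
  idx <- pmin(pmax(1L + as.integer(round(frac * 255)), 1L), 256L)
  list(index = idx, hex = pal[idx], pal = pal)
}

#' Build a hologram payload
#'
#' One streamed visualization record: skin voxels as colored points
#' (dose values in Gy carried alongside the colors -- colors are
#' presentation, values are data), the color-bar scale, the beam frustum
#' corners, the observer's eye-lens dose rate and staleness flags.
#'
#' @param state list with \code{timestampS}, \code{cumulative} (Gy array),
#'   \code{phantom}, \code{frustum}, \code{eyelens} (or NULL),
#'   \code{staleConditions}, \code{predicted}
#' @param colormap list(scale = "linear" or "log")
#' @return payload list, serializable to one JSONL record
#' @export
makePayload <- function(state, colormap = list(scale = "linear")) {
  ph <- state$phantom
  idx <- which(ph@skinMask, arr.ind = TRUE)
  pos <- sweep((idx - 0.5) %*% diag(ph@spacingMm), 2, ph@originMm, "+")
  dose <- state$cumulative[ph@skinMask]
  maxDose <- max(dose, 0)
  cols <- .dose_colors(dose, maxDose, colormap$scale)
  list(timestamp_s = state$timestampS,
       skin_points = data.frame(x_mm = pos[, 1], y_mm = pos[, 2],
                                z_mm = pos[, 3], dose_Gy = dose,
                                color = cols$hex),
       colorbar = list(min = 0, max = maxDose,
                       scale = if (is.null(colormap$scale)) "linear"
                               else colormap$scale),
       frustum = if (is.null(state$frustum)) NULL else
         list(source_mm = state$frustum@sourceXyz,
              corners = t(state$frustum@cornerRays),
              detector_mm = state$frustum@detectorCenterXyz),
       eyelens = if (is.null(state$eyelens)) NULL else
         list(air_kerma_rate_Gy_s = state$eyelens@airKermaRate,
              lens_dose_rate_Gy_s = state$eyelens@lensDoseRate,
              predicted = isTRUE(state$predicted)),
       stale = isTRUE(state$staleConditions))
}

#' Run a dose-visualization session
#'
#' Consumes a timestamp-ordered condition stream and an observer stream.
#' Per condition record with the beam on, the per-photon skin-dose
#' distribution for that (conditions, pose, table offset) fingerprint is
#' simulated (or served from the session cache, bit-identically) and
#' accumulated into the cumulative grid over the record duration; per
#' tick, the observer's eye-lens dose rate is interpolated from the
#' air-dose table and a hologram payload is emitted. During beam-off
#' intervals no dose accumulates but payloads still carry the eye-lens
#' rate predicted for the latest conditions (flagged \code{predicted}),
#' as a pre-exposure risk cue.
#'
#' @param config list: \code{phantom}, \code{airdoseTable}, optional
#'   \code{room}, \code{mc} (template [MCConfig-class]; per-fingerprint
#'   seeds are derived from its seed in first-seen order), \code{sisoCm},
#'   \code{tubeOutputCalibration}, \code{pulseWidthS}, \code{colormap},
#'   \code{latestOnly} (visualize only the latest run instead of the
#'   cumulative dose)
#' @param conditionStream list of records as from [streamConditions()] /
#'   [readConditionsJsonl()]
#' @param observerStream list of [observerState()] records
#' @return list(payloads, cumulative = [DoseGrid-class], cache fingerprints)
#' @export
runSession <- function(config, conditionStream, observerStream = list()) {
  ph <- config$phantom
  stopifnot(is(ph, "VoxelPhantom"))
  mcT <- if (is.null(config$mc)) mcConfig(nPhotons = 1e5) else config$mc
  calib <- if (is.null(config$tubeOutputCalibration)) 2e10 else
    config$tubeOutputCalibration
  siso <- if (is.null(config$sisoCm)) 72 else config$sisoCm
  colormap <- if (is.null(config$colormap)) list(scale = "linear") else
    config$colormap
  ts <- vapply(conditionStream, `[[`, numeric(1), "timestampS")
  if (is.unsorted(ts)) stop("condition stream timestamps out of order")
  obsTs <- vapply(observerStream, `[[`, numeric(1), "timestampS")
  if (is.unsorted(obsTs)) stop("observer stream timestamps out of order")
  cumulative <- array(0, dim(ph@hu))
  cache <- new.env(parent = emptyenv())
  nFp <- 0L
  payloads <- vector("list", length(conditionStream))
  lastConditions <- NULL
  for (i in seq_along(conditionStream)) {
    rec <- conditionStream[[i]]
    if (isTRUE(rec$gap)) {
      payloads[[i]] <- list(timestamp_s = rec$timestampS, gap = TRUE)
      next
    }
    cc <- rec$conditions
    lastConditions <- cc
    duration <- if (i < length(conditionStream))
      conditionStream[[i + 1]]$timestampS - rec$timestampS
    else if (!is.null(rec$periodS)) rec$periodS else 0.2
    pose <- poseFromConditions(cc, siso)
    frustum <- beamFrustum(pose, cc@fovCm)
    if (cc@beamOn && duration > 0) {
      key <- paste(cc@kvp, cc@filterCuMm, cc@fovCm, cc@sidCm, cc@lateralDeg,
                   cc@caudcranDeg, paste(cc@tableOffsetMm, collapse = ","),
                   sep = "|")
      if (is.null(cache[[key]])) {
        nFp <- nFp + 1L
        mcK <- mcConfig(mcT@nPhotons, mcT@cutoffKeV, mcT@nBatches,
                        as.integer((as.double(mcT@seed) + 104729 * nFp) %%
                                     2147483647),
                        mcT@rayleighEnabled)
        cache[[key]] <- simulateSkinDose(ph, pose, cc, mcK,
                                         room = config$room)
      }
      inc <- cache[[key]]
      if (isTRUE(config$latestOnly))
        cumulative <- accumulateDose(array(0, dim(ph@hu)), inc, duration,
                                     cc, calib, config$pulseWidthS)
      else
        cumulative <- accumulateDose(cumulative, inc, duration, cc, calib,
                                     config$pulseWidthS)
    }
    # observer at (or before) this tick
    eyelens <- NULL; predicted <- FALSE
    if (length(observerStream) > 0) {
      k <- findInterval(rec$timestampS, obsTs)
      if (k >= 1 && isTRUE(observerStream[[k]]$valid)) {
        ccOn <- cc
        if (!cc@beamOn) { ccOn@beamOn <- TRUE
          if (ccOn@ma <= 0) ccOn@ma <- 1
          predicted <- TRUE }
        rate <- queryAirKerma(config$airdoseTable, cc@lateralDeg,
                              cc@caudcranDeg,
                              observerStream[[k]]$headPositionXyzMm, ccOn,
                              calib, config$pulseWidthS)
        eyelens <- eyelensDoseRate(rate)
      }
    }
    payloads[[i]] <- makePayload(
      list(timestampS = rec$timestampS, cumulative = cumulative,
           phantom = ph, frustum = frustum, eyelens = eyelens,
           staleConditions = isTRUE(rec$stale), predicted = predicted),
      colormap)
  }
  finalGrid <- new("DoseGrid", dosePerPhoton = cumulative,
                   relUncertainty = array(0, dim(cumulative)),
                   spacingMm = ph@spacingMm, originMm = ph@originMm,
                   nPhotonsRun = 0, quantity = "cumulative_skin_dose_Gy",
                   energyKeV = c(emitted = 0, deposited = 0, escaped = 0))
  list(payloads = payloads, cumulative = finalGrid, nFingerprints = nFp)
}

#' Write hologram payloads as JSONL
#'
#' One payload per line; skin-point dose values round-trip losslessly
#' (full double precision).
#'
#' @param payloads list from [runSession()]
#' @param path output file
#' @export
writePayloadsJsonl <- function(payloads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in payloads)
    writeLines(jsonlite::toJSON(p, auto_unbox = TRUE, digits = I(17),
                                dataframe = "columns"), con)
  invisible(path)
}

#' Offline rendering of a session result
#'
#' Documentation stand-in for the holographic view: writes a PNG with the
#' skin surface scattered in the lateral (x-z) plane colored by cumulative
#' dose, plus the beam frustum wireframe. Pixel output is deterministic
#' for fixed inputs.
#'
#' @param phantom a [VoxelPhantom-class]
#' @param cumulativeGrid a [DoseGrid-class] (Gy)
#' @param pose a [CArmPose-class] for the frustum overlay
#' @param outPath PNG path
#' @param fovCm field of view for the frustum
#' @param widthPx image width (height scales with the scene)
#' @export
renderOffline <- function(phantom, cumulativeGrid, pose, outPath,
                          fovCm = 20, widthPx = 400) {
  idx <- which(phantom@skinMask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("phantom has no skin surface to render")
  pos <- sweep((idx - 0.5) %*% diag(phantom@spacingMm), 2,
               phantom@originMm, "+")
  dose <- cumulativeGrid@dosePerPhoton[phantom@skinMask]
  frustum <- beamFrustum(pose, fovCm)
  pts <- rbind(pos[, c(1, 3)], frustum@sourceXyz[c(1, 3)],
               frustum@detectorCenterXyz[c(1, 3)])
  lim <- apply(pts, 2, range)
  pad <- 0.05 * (lim[2, ] - lim[1, ] + 1)
  lo <- lim[1, ] - pad; hi <- lim[2, ] + pad
  H <- as.integer(round(widthPx * (hi[2] - lo[2]) / (hi[1] - lo[1])))
  H <- max(H, 50)
  img <- array(1, c(H, widthPx, 3))
  toPx <- function(xy) {
    c(x = 1 + (xy[1] - lo[1]) / (hi[1] - lo[1]) * (widthPx - 1),
      y = H - (xy[2] - lo[2]) / (hi[2] - lo[2]) * (H - 1))
  }
  drawLine <- function(a, b, col) {
    n <- max(2, ceiling(max(abs(b - a))) )
    for (t in seq(0, 1, length.out = n)) {
      p <- round(a + t * (b - a))
      if (p[2] >= 1 && p[2] <= H && p[1] >= 1 && p[1] <= widthPx)
        img[p[2], p[1], ] <<- col
    }
  }
  cols <- .dose_colors(dose, max(dose, 0))
  rgb <- t(grDevices::col2rgb(cols$hex) / 255)
  for (i in seq_len(nrow(pos))) {
    p <- round(toPx(pos[i, c(1, 3)]))
    if (p[2] >= 1 && p[2] < H && p[1] >= 1 && p[1] < widthPx)
      img[p[2]:(p[2] + 1), p[1]:(p[1] + 1), ] <-
        matrix(rgb[i, ], 4, 3, byrow = TRUE)
  }
  src <- toPx(frustum@sourceXyz[c(1, 3)])
  sidMm <- sqrt(sum((frustum@detectorCenterXyz - frustum@sourceXyz)^2))
  for (k in 1:4) {
    end3 <- frustum@sourceXyz + frustum@cornerRays[, k] * sidMm
    drawLine(src, toPx(end3[c(1, 3)]), c(0.3, 0.3, 0.3))
  }
  png::writePNG(img, outPath)
  invisible(outPath)
}
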