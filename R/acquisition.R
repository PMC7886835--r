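# Console-screen acquisition: a synthetic seven-segment display stands in
# for the vendor console; the recognizer (normalized cross-correlation
# against digit templates) is the same code that would run on camera
# frames after rectification.

.SEGMENTS <- list(
  "0" = c("a", "b", "c", "d", "e", "f"),
  "1" = c("b", "c"),
  "2" = c("a", "b", "g", "e", "d"),
  "3" = c("a", "b", "g", "c", "d"),
  "4" = c("f", "g", "b", "c"),
  "5" = c("a", "f", "g", "c", "d"),
  "6" = c("a", "f", "g", "e", "c", "d"),
  "7" = c("a", "b", "c"),
  "8" = c("a", "b", "c", "d", "e", "f", "g"),
  "9" = c("a", "b", "c", "d", "f", "g"),
  "-" = "g",
  " " = character(0))

.BG <- 0.1; .FG <- 0.9

# one glyph as a cellH x cellW matrix (row = y)
.glyph <- function(ch, cellW = 16, cellH = 24, thick = 3) {
  m <- matrix(.BG, cellH, cellW)
  on <- .SEGMENTS[[ch]]
  if (is.null(on)) stop("glyph not representable: ", ch)
  half <- cellH %/% 2
  put <- function(y0, y1, x0, x1) m[y0:y1, x0:x1] <<- .FG
  if ("a" %in% on) put(1, thick, 2, cellW - 1)
  if ("d" %in% on) put(cellH - thick + 1, cellH, 2, cellW - 1)
  if ("g" %in% on) put(half - 1, half + 1, 2, cellW - 1)
  if ("f" %in% on) put(2, half, 1, thick)
  if ("e" %in% on) put(half, cellH - 1, 1, thick)
  if ("b" %in% on) put(2, half, cellW - thick + 1, cellW)
  if ("c" %in% on) put(half, cellH - 1, cellW - thick + 1, cellW)
  m
}

#' Console screen layout
#'
#' Pixel geometry of the synthetic console frame: one rectangular
#' digit-field ROI per fluoroscopic parameter (slot count, fixed-point
#' divisor, optional sign slot) plus the irradiation indicator box. The
#' layout is plain-list data and can be serialized to JSON so a real,
#' rectified camera frame could be described the same way.
#'
#' @return layout list
#' @export
defaultScreenLayout <- function() {
  f <- function(x, y, nslots, divisor = 1, signed = FALSE)
    list(x = x, y = y, nslots = nslots, divisor = divisor, signed = signed)
  layout <- list(
    frameH = 190, frameW = 180, cellW = 16, cellH = 24, gap = 4,
    fields = list(
      kvp = f(10, 10, 3), ma = f(95, 10, 3, divisor = 10),
      fovCm = f(10, 44, 2), sidCm = f(95, 44, 3),
      lateralDeg = f(10, 78, 3, signed = TRUE),
      caudcranDeg = f(95, 78, 3, signed = TRUE),
      fps = f(10, 112, 2), filterCuMm = f(95, 112, 2, divisor = 10),
      irradiationTimeS = f(10, 146, 4, divisor = 10)),
    beam = list(x = 120, y = 146, w = 24, h = 24))
  .validate_layout(layout)
  layout
}

.slot_x <- function(layout, field, k) {
  field$x + (k - 1) * (layout$cellW + layout$gap)
}

.validate_layout <- function(layout) {
  boxes <- lapply(layout$fields, function(f) {
    w <- f$nslots + if (isTRUE(f$signed)) 1 else 0
    c(f$x, f$y, f$x + w * (layout$cellW + layout$gap) - layout$gap,
      f$y + layout$cellH)
  })
  boxes$beam <- with(layout$beam, c(x, y, x + w, y + h))
  for (b in boxes)
    if (b[1] < 1 || b[2] < 1 || b[3] > layout$frameW || b[4] > layout$frameH)
      stop("layout ROI outside frame bounds")
  nb <- length(boxes)
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    a <- boxes[[i]]; b <- boxes[[j]]
    if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4])
      stop("layout ROIs overlap: ", names(boxes)[i], " / ", names(boxes)[j])
  }
  invisible(TRUE)
}

#' @rdname defaultScreenLayout
#' @param path JSON file
#' @export
saveScreenLayout <- function(layout, path) {
  jsonlite::write_json(layout, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname defaultScreenLayout
#' @param layout a layout list
#' @export
loadScreenLayout <- function(path) {
  layout <- jsonlite::read_json(path, simplifyVector = TRUE)
  layout$fields <- lapply(layout$fields, as.list)
  layout$beam <- as.list(layout$beam)
  .validate_layout(layout)
  layout
}

.field_chars <- function(value, spec) {
  v <- round(abs(value) * spec$divisor)
  digits <- if (v == 0) "0" else
    strsplit(format(v, scientific = FALSE, trim = TRUE), "")[[1]]
  if (length(digits) > spec$nslots)
    stop("value ", value, " not representable in ", spec$nslots, " slots")
  pad <- rep(" ", spec$nslots - length(digits))          # leading blanks
  chars <- c(pad, digits)
  if (isTRUE(spec$signed)) c(if (value < 0) "-" else " ", chars) else chars
}

#' Render a synthetic console frame
#'
#' Draws every fluoroscopic-condition field of \code{conditions} as
#' seven-segment digits into its layout ROI (grayscale in \[0, 1\]), the
#' irradiation indicator as a lit/unlit box, then adds zero-mean Gaussian
#' pixel noise and a global brightness jitter scaled by \code{noiseLevel}.
#' Deterministic per seed.
#'
#' @param conditions a [FluoroConditions-class]
#' @param layout a screen layout ([defaultScreenLayout()])
#' @param noiseLevel noise scale (0 = clean)
#' @param seed RNG seed
#' @return image matrix (rows = y)
#' @export
renderScreenFrame <- function(conditions, layout = defaultScreenLayout(),
                              noiseLevel = 0, seed = 1) {
  img <- matrix(.BG, layout$frameH, layout$frameW)
  for (nm in names(layout$fields)) {
    spec <- layout$fields[[nm]]
    chars <- .field_chars(slot(conditions, nm), spec)
    for (k in seq_along(chars)) {
      g <- .glyph(chars[k], layout$cellW, layout$cellH)
      x0 <- .slot_x(layout, spec, k)
      img[spec$y:(spec$y + layout$cellH - 1),
          x0:(x0 + layout$cellW - 1)] <- g
    }
  }
  b <- layout$beam
  img[b$y:(b$y + b$h - 1), b$x:(b$x + b$w - 1)] <-
    if (conditions@beamOn) .FG else 0.15
  if (noiseLevel > 0) {
    img <- .with_seed(seed, {
      jitter <- stats::runif(1, -0.5, 0.5) * noiseLevel
      img + jitter + matrix(stats::rnorm(length(img), 0, noiseLevel),
                            nrow(img))
    })
    img <- pmin(pmax(img, 0), 1)
  }
  img
}

#' Digit templates for the recognizer
#'
#' @param layout screen layout (cell geometry)
#' @return named list of glyph matrices for 0-9, minus and blank
#' @export
digitTemplates <- function(layout = defaultScreenLayout()) {
  chars <- c(as.character(0:9), "-", " ")
  stats::setNames(lapply(chars, .glyph, cellW = layout$cellW,
                         cellH = layout$cellH), chars)
}

.unreadable <- function(field, why = "unreadable") {
  stop(errorCondition(
    paste0("unreadable frame: field '", field, "' ", why),
    field = field, class = "fluorodose_unreadable_frame"))
}

.classify_slot <- function(patch, templates, threshold, margin) {
  pv <- as.vector(patch)
  if (stats::sd(pv) < 1e-12)
    return(if (mean(pv) < .BG + 0.15) " " else NA_character_)
  scores <- vapply(templates[names(templates) != " "], function(tm) {
    tv <- as.vector(tm)
    if (stats::sd(tv) == 0) return(-1)
    stats::cor(pv, tv)
  }, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  best <- scores[ord[1]]; second <- scores[ord[2]]
  if (best < threshold) {
    # no template fits: a dim, near-uniform patch is a blank slot
    if (mean(pv) < .BG + 0.15 && stats::sd(pv) < 0.15) return(" ")
    return(NA_character_)
  }
  if (best - second < margin) return(NA_character_)
  names(scores)[ord[1]]
}

#' Recognize fluoroscopic conditions in a console frame
#'
#' Template matching: every digit slot is scored by normalized
#' cross-correlation against the 0-9/minus templates (acceptance threshold
#' 0.6, runner-up margin 0.05 by default); near-uniform dim slots read as
#' blanks; the irradiation flag comes from the indicator ROI intensity.
#' Any slot below threshold or margin -- or a field with no digits at all
#' -- raises an unreadable-frame error (condition class
#' \code{fluorodose_unreadable_frame}) naming the failing field, so the
#' caller can keep its previous record.
#'
#' @param image grayscale frame matrix
#' @param layout screen layout
#' @param templates template set from [digitTemplates()]
#' @param threshold,margin matcher acceptance parameters
#' @param timestampS timestamp attached to the record
#' @return a [FluoroConditions-class]
#' @export
recognizeFrame <- function(image, layout = defaultScreenLayout(),
                           templates = digitTemplates(layout),
                           threshold = 0.6, margin = 0.05, timestampS = 0) {
  if (nrow(image) != layout$frameH || ncol(image) != layout$frameW)
    stop("image dimensions do not match the layout")
  vals <- list()
  for (nm in names(layout$fields)) {
    spec <- layout$fields[[nm]]
    ns <- spec$nslots + if (isTRUE(spec$signed)) 1 else 0
    chars <- character(ns)
    for (k in seq_len(ns)) {
      x0 <- .slot_x(layout, spec, k)
      patch <- image[spec$y:(spec$y + layout$cellH - 1),
                     x0:(x0 + layout$cellW - 1)]
      ch <- .classify_slot(patch, templates, threshold, margin)
      if (is.na(ch)) .unreadable(nm, "below matcher threshold/margin")
      chars[k] <- ch
    }
    sign <- 1
    if (isTRUE(spec$signed)) {
      if (chars[1] == "-") sign <- -1
      chars <- chars[-1]
    }
    digits <- chars[chars != " "]
    if (length(digits) == 0 || any(digits == "-"))
      .unreadable(nm, "no digits read")
    vals[[nm]] <- sign * as.numeric(paste(digits, collapse = "")) /
      spec$divisor
  }
  b <- layout$beam
  lit <- mean(image[b$y:(b$y + b$h - 1), b$x:(b$x + b$w - 1)]) > 0.5
  tryCatch(
    fluoroConditions(kvp = vals$kvp, ma = vals$ma, fovCm = vals$fovCm,
                     sidCm = vals$sidCm, lateralDeg = vals$lateralDeg,
                     caudcranDeg = vals$caudcranDeg, fps = vals$fps,
                     filterCuMm = vals$filterCuMm, beamOn = lit,
                     irradiationTimeS = vals$irradiationTimeS,
                     timestampS = timestampS),
    error = function(e) .unreadable("record", conditionMessage(e)))
}

#' Stream conditions from a frame source
#'
#' Emits one condition record per frame (frames arrive at the acquisition
#' period, 0.2 s by default). Unreadable frames re-emit the last good
#' record flagged \code{stale}; before any good record they emit a gap
#' marker. Table offsets are merged from the ultrasonic channel by nearest
#' timestamp.
#'
#' @param frames list of \code{list(timestampS, image)}
#' @param layout screen layout
#' @param periodS nominal acquisition period (recorded in the output)
#' @param ultrasonic optional data.frame(timestampS, dx_mm, dy_mm, dz_mm)
#' @param templates,threshold,margin matcher settings
#' @return list of records: either \code{list(gap = TRUE, timestampS)} or
#'   \code{list(conditions, timestampS, stale)}
#' @export
streamConditions <- function(frames, layout = defaultScreenLayout(),
                             periodS = 0.2, ultrasonic = NULL,
                             templates = digitTemplates(layout),
                             threshold = 0.6, margin = 0.05) {
  out <- vector("list", length(frames))
  last <- NULL
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    rec <- tryCatch(
      recognizeFrame(fr$image, layout, templates, threshold, margin,
                     timestampS = fr$timestampS),
      fluorodose_unreadable_frame = function(e) NULL)
    stale <- is.null(rec)
    if (stale && is.null(last)) {
      out[[i]] <- list(gap = TRUE, timestampS = fr$timestampS)
      next
    }
    if (stale) rec <- last else last <- rec
    if (!is.null(ultrasonic) && nrow(ultrasonic) > 0) {
      k <- which.min(abs(ultrasonic$timestampS - fr$timestampS))
      rec@tableOffsetMm <- as.numeric(ultrasonic[k, c("dx_mm", "dy_mm",
                                                      "dz_mm")])
    }
    rec@timestampS <- fr$timestampS
    out[[i]] <- list(conditions = rec, timestampS = fr$timestampS,
                     stale = stale, periodS = periodS)
  }
  out
}

#' Write / read a condition stream as JSONL
#'
#' One JSON record per line; gap markers carry \code{gap: true}.
#'
#' @param records output of [streamConditions()]
#' @param path JSONL file
#' @export
writeConditionsJsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    if (isTRUE(r$gap))
      return(jsonlite::toJSON(list(gap = TRUE, timestamp_s = r$timestampS),
                              auto_unbox = TRUE, digits = NA))
    cc <- r$conditions
    jsonlite::toJSON(list(
      timestamp_s = r$timestampS, stale = r$stale, kvp = cc@kvp, ma = cc@ma,
      fov_cm = cc@fovCm, sid_cm = cc@sidCm, lateral_deg = cc@lateralDeg,
      caudcran_deg = cc@caudcranDeg, fps = cc@fps,
      filter_cu_mm = cc@filterCuMm, beam_on = cc@beamOn,
      irradiation_time_s = cc@irradiationTimeS,
      table_offset_mm = cc@tableOffsetMm), auto_unbox = TRUE,
      digits = I(17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeConditionsJsonl
#' @export
readConditionsJsonl <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln)
    if (isTRUE(x$gap)) return(list(gap = TRUE, timestampS = x$timestamp_s))
    list(conditions = fluoroConditions(
           kvp = x$kvp, ma = x$ma, fovCm = x$fov_cm, sidCm = x$sid_cm,
           lateralDeg = x$lateral_deg, caudcranDeg = x$caudcran_deg,
           fps = x$fps, filterCuMm = x$filter_cu_mm, beamOn = x$beam_on,
           irradiationTimeS = x$irradiation_time_s,
           tableOffsetMm = as.numeric(x$table_offset_mm),
           timestampS = x$timestamp_s),
         timestampS = x$timestamp_s, stale = isTRUE(x$stale))
  })
}

# ------------------------------------------------------------ ultrasonics

#' Temperature-corrected speed of sound
#'
#' Linear model v = 331.3 + 0.606 T (m/s), the standard first-order
#' correction used to convert ultrasonic time of flight to distance.
#'
#' @param temperatureC air temperature, -10..50 C (sensor range)
#' @return speed of sound, m/s
#' @export
soundSpeed <- function(temperatureC) {
  if (any(temperatureC < -10 | temperatureC > 50))
    stop("temperature outside the sensor range (-10..50 C)")
  331.3 + 0.606 * temperatureC
}

#' Ultrasonic reading container
#'
#' @param tofS round-trip times of flight, one per axis sensor (s); NA for
#'   a missing axis
#' @param temperatureC air temperature for the sound-speed correction
#' @param timestampS timestamp
#' @return reading list
#' @export
ultrasonicReading <- function(tofS, temperatureC, timestampS = 0) {
  if (any(!is.na(tofS) & tofS <= 0)) stop("time of flight must be positive")
  list(tofS = tofS, temperatureC = temperatureC, timestampS = timestampS)
}

#' Convert time of flight to distance
#'
#' d = v(T) * tof / 2 per sensor (round trip halved). The inverse,
#' \code{distanceToTof}, is exact: composing the two is the identity.
#'
#' @param reading an [ultrasonicReading()]
#' @return distances in cm (NA where the axis is missing)
#' @export
tofToDistance <- function(reading) {
  v <- soundSpeed(reading$temperatureC)
  v * reading$tofS / 2 * 100
}

#' @rdname tofToDistance
#' @param distanceCm sensor-to-target distance(s), cm
#' @param temperatureC air temperature
#' @export
distanceToTof <- function(distanceCm, temperatureC) {
  2 * (distanceCm / 100) / soundSpeed(temperatureC)
}

#' Table position from ultrasonic readings
#'
#' Per-axis offset = (measured distance - calibration reference distance)
#' x sensor facing sign, returned in mm. A missing axis raises an
#' incomplete-position error.
#'
#' @param reading an [ultrasonicReading()] with three axes
#' @param calibration list(referenceCm = length-3, sign = length-3 in
#'   \{-1, +1\})
#' @return table offset (longitudinal, lateral, vertical), mm
#' @export
tablePosition <- function(reading, calibration) {
  d <- tofToDistance(reading)
  if (length(d) != 3 || any(is.na(d)))
    stop("incomplete position: need all three axis readings")
  sign <- if (is.null(calibration$sign)) c(1, 1, 1) else calibration$sign
  (d - calibration$referenceCm) * sign * 10
}

#' Noiseless/noisy ultrasonic validation sweep
#'
#' Replays the bench validation protocol: per axis, true offsets from
#' -10 cm to +10 cm in 2 cm steps are converted to times of flight at the
#' given temperature (optionally with Gaussian ToF noise), run back
#' through [tofToDistance()] + [tablePosition()], and the per-point
#' recovery error is reported.
#'
#' @param calibration as in [tablePosition()]
#' @param temperatureC air temperature
#' @param tofNoiseSdS Gaussian ToF noise SD (s); 0 for the exact sweep
#' @param seed RNG seed for the noise
#' @return data.frame(axis, offset_cm, recovered_cm, error_cm)
#' @export
ultrasonicSweep <- function(calibration, temperatureC = 20, tofNoiseSdS = 0,
                            seed = 1) {
  offsets <- seq(-10, 10, by = 2)
  sign <- if (is.null(calibration$sign)) c(1, 1, 1) else calibration$sign
  rows <- list()
  noise <- .with_seed(seed, stats::rnorm(3 * length(offsets), 0, tofNoiseSdS))
  k <- 0
  for (ax in 1:3) for (off in offsets) {
    k <- k + 1
    trueCm <- calibration$referenceCm[ax] + off * sign[ax]
    tof <- distanceToTof(trueCm, temperatureC) +
      (if (tofNoiseSdS > 0) noise[k] else 0)
    tofs <- rep(NA_real_, 3); tofs[ax] <- tof
    # fill the other axes with their reference so tablePosition accepts
    others <- setdiff(1:3, ax)
    tofs[others] <- distanceToTof(calibration$referenceCm[others],
                                  temperatureC)
    rec <- tablePosition(ultrasonicReading(tofs, temperatureC), calibration)
    rows[[k]] <- data.frame(axis = ax, offset_cm = off,
                            recovered_cm = rec[ax] / 10,
                            error_cm = rec[ax] / 10 - off)
  }
  do.call(rbind, rows)
}
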