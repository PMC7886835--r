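test_that("the reference-protocol frame round-trips through the recognizer", {
  cc <- table2Conditions()
  img <- renderScreenFrame(cc)
  got <- recognizeFrame(img)
  for (f in c("kvp", "ma", "fovCm", "sidCm", "lateralDeg", "caudcranDeg",
              "fps", "filterCuMm", "irradiationTimeS"))
    expect_identical(slot(got, f), slot(cc, f))
  expect_true(beamOn(got))
  off <- table2Conditions(beamOn = FALSE)
  expect_false(beamOn(recognizeFrame(renderScreenFrame(off))))
})

test_that("rendering is deterministic per seed and value-range checked", {
  cc <- table2Conditions()
  expect_identical(renderScreenFrame(cc, noiseLevel = 0, seed = 1),
                   renderScreenFrame(cc, noiseLevel = 0, seed = 99))
  expect_identical(renderScreenFrame(cc, noiseLevel = 0.3, seed = 4),
                   renderScreenFrame(cc, noiseLevel = 0.3, seed = 4))
  expect_false(identical(renderScreenFrame(cc, noiseLevel = 0.3, seed = 4),
                         renderScreenFrame(cc, noiseLevel = 0.3, seed = 5)))
  # 4-digit value in a 3-slot field cannot be drawn
  bad <- table2Conditions(sidCm = 1000, ma = 2.5)
  expect_error(renderScreenFrame(bad), "not representable")
})

test_that("values narrower than their field render with leading blanks and round-trip", {
  cc <- table2Conditions(kvp = 76, sidCm = 90, fps = 7)  # all under-width
  got <- recognizeFrame(renderScreenFrame(cc))
  expect_identical(got@kvp, 76); expect_identical(got@sidCm, 90)
  expect_identical(got@fps, 7)
})

test_that("randomized clean frames are recognized field-perfectly", {
  layout <- defaultScreenLayout()
  tmpl <- digitTemplates(layout)
  for (cc in randomConditions(60, seed = 77)) {
    got <- recognizeFrame(renderScreenFrame(cc, layout), layout, tmpl)
    for (f in c("kvp", "ma", "fovCm", "sidCm", "lateralDeg", "caudcranDeg",
                "fps", "filterCuMm", "irradiationTimeS", "beamOn"))
      expect_identical(slot(got, f), slot(cc, f))
  }
})

test_that("unreadable frames raise errors naming the failing field", {
  layout <- defaultScreenLayout()
  black <- matrix(0, layout$frameH, layout$frameW)
  err <- tryCatch(recognizeFrame(black, layout),
                  fluorodose_unreadable_frame = function(e) e)
  expect_s3_class(err, "fluorodose_unreadable_frame")

  img <- renderScreenFrame(table2Conditions(), layout)
  f <- layout$fields$sidCm
  w <- f$nslots * (layout$cellW + layout$gap)
  img[f$y:(f$y + layout$cellH - 1), f$x:(f$x + w - 1)] <- 0
  err <- tryCatch(recognizeFrame(img, layout),
                  fluorodose_unreadable_frame = function(e) e)
  expect_identical(err$field, "sidCm")
  expect_match(conditionMessage(err), "sidCm")

  wrong <- matrix(0.5, 10, 10)
  expect_error(recognizeFrame(wrong, layout), "dimensions")
})

test_that("recognition accuracy degrades monotonically with noise in expectation", {
  layout <- defaultScreenLayout()
  tmpl <- digitTemplates(layout)
  conds <- randomConditions(80, seed = 5)
  acc <- vapply(c(0.05, 0.35, 0.7), function(nl) {
    ok <- vapply(seq_along(conds), function(i) {
      img <- renderScreenFrame(conds[[i]], layout, noiseLevel = nl, seed = i)
      got <- tryCatch(recognizeFrame(img, layout, tmpl),
                      fluorodose_unreadable_frame = function(e) NULL)
      !is.null(got) && isTRUE(all.equal(got@kvp, conds[[i]]@kvp)) &&
        isTRUE(all.equal(got@ma, conds[[i]]@ma))
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_gte(acc[1], acc[2] - 0.05)
  expect_gte(acc[2], acc[3] - 0.05)
  expect_lt(acc[3], acc[1])        # high noise really does hurt
})

test_that("condition streaming: cadence, latency, staleness, gaps, table merge", {
  layout <- defaultScreenLayout()
  ccA <- table2Conditions(kvp = 76)
  ccB <- table2Conditions(kvp = 80)
  frames <- lapply(0:49, function(k) {
    t <- k * 0.2
    cc <- if (t < 2.0) ccA else ccB
    list(timestampS = t, image = renderScreenFrame(cc, layout))
  })
  us <- data.frame(timestampS = c(0, 5), dx_mm = c(0, 12), dy_mm = c(0, -4),
                   dz_mm = c(0, 30))
  recs <- streamConditions(frames, layout, ultrasonic = us)
  expect_length(recs, 50)
  kvps <- vapply(recs, function(r) r$conditions@kvp, numeric(1))
  firstB <- recs[[which(kvps == 80)[1]]]
  expect_gte(firstB$timestampS, 2.0)
  expect_lte(firstB$timestampS, 2.2)
  expect_false(any(vapply(recs, function(r) r$stale, logical(1))))
  expect_equal(recs[[50]]$conditions@tableOffsetMm, c(12, -4, 30))

  # corrupt one mid-stream frame: its record is a stale re-emission
  frames[[10]]$image <- matrix(0, layout$frameH, layout$frameW)
  recs <- streamConditions(frames, layout)
  expect_true(recs[[10]]$stale)
  expect_identical(recs[[10]]$conditions@kvp, 76)
  expect_false(recs[[11]]$stale)

  # unreadable before any good record: gap marker
  frames[[1]]$image <- matrix(0, layout$frameH, layout$frameW)
  recs <- streamConditions(frames, layout)
  expect_true(isTRUE(recs[[1]]$gap))

  # JSONL round trip
  path <- file.path(tempdir(), "conds.jsonl")
  writeConditionsJsonl(recs, path)
  back <- readConditionsJsonl(path)
  expect_length(back, 50)
  expect_true(isTRUE(back[[1]]$gap))
  expect_identical(back[[20]]$conditions@kvp, recs[[20]]$conditions@kvp)
  expect_identical(back[[20]]$conditions@tableOffsetMm,
                   recs[[20]]$conditions@tableOffsetMm)
})

test_that("sound speed follows the linear temperature model", {
  expect_equal(soundSpeed(0), 331.3, tolerance = 1e-12)
  expect_equal(soundSpeed(20), 343.42, tolerance = 1e-12)
  expect_equal((soundSpeed(30) - soundSpeed(10)) / 20, 0.606,
               tolerance = 1e-12)
  expect_error(soundSpeed(60), "range")
})

test_that("time of flight converts to distance and back exactly", {
  r <- ultrasonicReading(1.165e-3, 20)
  expect_equal(tofToDistance(r), 343.42 * 1.165e-3 / 2 * 100,
               tolerance = 1e-12)
  expect_equal(tofToDistance(r), 20.0, tolerance = 0.01)
  half <- ultrasonicReading(1.165e-3 / 2, 20)
  expect_equal(tofToDistance(half), tofToDistance(r) / 2, tolerance = 1e-12)
  cold <- ultrasonicReading(1.165e-3, 0)
  expect_equal(tofToDistance(r) / tofToDistance(cold), 343.42 / 331.3,
               tolerance = 1e-12)
  set.seed(1)
  for (d in runif(20, 5, 300))
    expect_equal(tofToDistance(ultrasonicReading(distanceToTof(d, 24), 24)),
                 d, tolerance = 1e-12)
  expect_error(ultrasonicReading(-1e-3, 20), "positive")
})

test_that("table position: zero at calibration, signed offsets, missing axis", {
  calib <- list(referenceCm = c(60, 45, 80), sign = c(1, -1, 1))
  tofs <- distanceToTof(calib$referenceCm, 22)
  expect_equal(tablePosition(ultrasonicReading(tofs, 22), calib), c(0, 0, 0),
               tolerance = 1e-9)
  tofs2 <- distanceToTof(calib$referenceCm + c(3, 2, -1), 22)
  expect_equal(tablePosition(ultrasonicReading(tofs2, 22), calib),
               c(30, -20, -10), tolerance = 1e-9)
  expect_error(tablePosition(ultrasonicReading(tofs[1:2], 22), calib),
               "incomplete")
  tofs[2] <- NA
  expect_error(tablePosition(ultrasonicReading(tofs, 22), calib),
               "incomplete")
})

test_that("the noiseless bench sweep recovers every offset exactly", {
  calib <- list(referenceCm = c(60, 45, 80), sign = c(1, 1, -1))
  sw <- ultrasonicSweep(calib, temperatureC = 23)
  expect_identical(nrow(sw), 33L)              # 11 points x 3 axes
  expect_lt(max(abs(sw$error_cm)), 1e-9)
  swn <- ultrasonicSweep(calib, temperatureC = 23, tofNoiseSdS = 5e-6)
  expect_gt(max(abs(swn$error_cm)), 1e-4)
})
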