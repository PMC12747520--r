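test_that("state windows follow annotations and detect ADP exhaustion", {
  trA <- synthRespiroTrace(respiroParams(annotateExhaustion = TRUE))
  w <- segmentStates(trA, bufferS = 10)
  expect_equal(w$start_s[w$state == "State3"], 210)
  expect_equal(w$end_s[w$state == "State3"], 350)     # annotated boundary
  expect_equal(w$start_s[w$state == "State4"], 360)

  ## unannotated boundary: changepoint within 10 s of the true 350 s
  tr <- synthRespiroTrace(respiroParams(noiseSd = 0.3, seed = 5))
  wd <- segmentStates(tr, bufferS = 10)
  expect_lt(abs(wd$end_s[wd$state == "State3"] - 350), 10)

  ## without an ADP event only a basal window exists
  trB <- synthRespiroTrace(respiroParams())
  trB@events <- trB@events[trB@events$label == "substrate", , drop = FALSE]
  wb <- segmentStates(trB)
  expect_identical(wb$state, "basal")
})

test_that("OCR converts trace slopes through chamber volume and protein", {
  tr <- synthRespiroTrace(respiroParams(annotateExhaustion = TRUE))
  w <- segmentStates(tr)
  ## hand arithmetic: 10 nmol/mL/min x 0.5 mL / 0.05 mg
  expect_equal(as.numeric(ocr(tr, w[w$state == "State3", ])), 100,
               tolerance = 1e-9)
  expect_equal(as.numeric(ocr(tr, w[w$state == "State4", ])), 25,
               tolerance = 1e-9)

  flat <- tr
  flat@o2NmolPerMl <- rep(150, length(traceTime(tr)))
  expect_equal(as.numeric(ocr(flat, c(210, 350))), 0)
  rising <- tr
  rising@o2NmolPerMl <- 100 + 0.1 * traceTime(tr)
  o <- ocr(rising, c(210, 350))
  expect_equal(as.numeric(o), 0)
  expect_identical(attr(o, "flag"), "rising O2")
  expect_error(ocr(tr, c(210, 211)), "degenerate")

  ## invariance to time shift and O2 offset
  shifted <- tr
  shifted@timeS <- tr@timeS + 1000
  shifted@events$time_s <- shifted@events$time_s + 1000
  expect_equal(as.numeric(ocr(shifted, c(1210, 1350))),
               as.numeric(ocr(tr, c(210, 350))))
  offset <- tr
  offset@o2NmolPerMl <- tr@o2NmolPerMl + 50
  expect_equal(as.numeric(ocr(offset, c(210, 350))),
               as.numeric(ocr(tr, c(210, 350))))
})

test_that("respiratory control ratio recovers the generating slope ratio", {
  expect_equal(rcr(100, 25), 4)
  expect_equal(rcr(37, 37), 1)
  expect_error(rcr(100, 0), "positive")

  ## noiseless closure: exact
  res0 <- ocrSummary(synthRespiroTrace(respiroParams(annotateExhaustion = TRUE)))
  expect_equal(res0$rcr, 4, tolerance = 1e-9)

  ## ~1% amplitude noise keeps RCR within 2% over seeds
  rcrs <- vapply(1:10, function(s) {
    tr <- synthRespiroTrace(respiroParams(noiseSd = 0.25, seed = s))
    ocrSummary(tr)$rcr
  }, numeric(1))
  expect_lt(max(abs(rcrs - 4) / 4), 0.02)
})

test_that("H2O2 calibration is an OLS line with intercept", {
  cal <- h2o2Calibration(c(0.1, 0.2, 0.4), c(10, 20, 40))
  expect_equal(cal@slopeAuPerNmol, 100, tolerance = 1e-9)
  expect_equal(cal@interceptAu, 0, tolerance = 1e-9)
  expect_equal(cal@r2, 1)
  expect_error(h2o2Calibration(c(0.1, 0.2), c(10, 20)), "3")
  expect_error(h2o2Calibration(rep(0.2, 3), c(10, 20, 30)), "zero variance")

  ## noisy slope is nearly unbiased
  set.seed(4)
  slopes <- replicate(100, {
    x <- c(0.1, 0.2, 0.4, 0.8)
    h2o2Calibration(x, 5 + 100 * x + rnorm(4, sd = 1))@slopeAuPerNmol
  })
  expect_lt(abs(mean(slopes) - 100) / 100, 0.02)
})

test_that("H2O2 emission rate divides the pre-rotenone slope by calibration", {
  cal <- h2o2Calibration(c(0.1, 0.2, 0.4), c(10, 20, 40))
  tr <- synthFluoroTrace(fluoroParams("amplex"))   # 50 a.u./min before rotenone
  expect_equal(h2o2Rate(tr, cal, 0.05), 50 / 100 / 0.05, tolerance = 1e-9)

  flat <- tr
  flat@fluorescenceAu <- rep(20, length(traceTime(tr)))
  expect_equal(h2o2Rate(flat, cal, 0.05), 0)

  noRot <- tr
  noRot@events <- data.frame(time_s = 600, label = "antimycin")
  expect_error(h2o2Rate(noRot, cal, 0.05), "rotenone")

  ## linear in fluorescence slope, inverse-linear in calibration and protein
  fast <- synthFluoroTrace(fluoroParams("amplex",
    ratesAuS = c(pre = 100 / 60, rotenone = 1.5, antimycin = 0.2)))
  expect_equal(h2o2Rate(fast, cal, 0.05), 2 * h2o2Rate(tr, cal, 0.05),
               tolerance = 1e-9)
  cal2 <- h2o2Calibration(c(0.1, 0.2, 0.4), c(20, 40, 80))
  expect_equal(h2o2Rate(tr, cal2, 0.05), h2o2Rate(tr, cal, 0.05) / 2,
               tolerance = 1e-9)
  expect_equal(h2o2Rate(tr, cal, 0.1), h2o2Rate(tr, cal, 0.05) / 2,
               tolerance = 1e-9)
})

test_that("MitoSOX initial rate reads the pre-saturation slope", {
  tr <- synthFluoroTrace(fluoroParams("mitosox"))
  expect_equal(mitosoxRate(tr), 300, tolerance = 1e-9)      # 5 a.u./s x 60
  flat <- tr
  flat@fluorescenceAu <- rep(50, length(traceTime(tr)))
  expect_equal(mitosoxRate(flat), 0)
  expect_error(mitosoxRate(tr, windowS = 1e5), "longer than trace")

  ## saturating trace with noise: within 3%
  noisy <- synthFluoroTrace(fluoroParams("mitosox", noiseSd = 2, seed = 2))
  expect_equal(mitosoxRate(noisy), 300, tolerance = 0.03)
})

test_that("RH-123 quench depth and CCCP release come from plateau means", {
  tr <- synthFluoroTrace(fluoroParams("rh123"))
  d <- rh123Delta(tr)
  expect_equal(d$deltaFAu, 40, tolerance = 1e-6)
  expect_equal(d$cccpReleaseAu, 35, tolerance = 1e-6)

  ## no quench: plateau equals baseline
  none <- synthFluoroTrace(fluoroParams("rh123",
    plateausAu = c(quench = 100, recovery = 100)))
  expect_equal(rh123Delta(none)$deltaFAu, 0, tolerance = 1e-9)

  ## no CCCP event: release unavailable
  noC <- synthFluoroTrace(fluoroParams("rh123",
    eventTimesS = c(substrate = 320), plateausAu = c(quench = 60)))
  dn <- rh123Delta(noC)
  expect_equal(dn$deltaFAu, 40, tolerance = 1e-6)
  expect_true(is.na(dn$cccpReleaseAu))

  short <- tr
  short@events$time_s[short@events$label == "substrate"] <- 250
  expect_error(rh123Delta(short), "300 s")
})
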