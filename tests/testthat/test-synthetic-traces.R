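test_that("noiseless respirometry traces are exact piecewise lines", {
  p <- respiroParams(slopes = c(basal = 0, state2 = 0, state3 = -10,
                                state4 = -2.5, uncoupled = -2.5),
                     annotateExhaustion = TRUE)
  tr <- synthRespiroTrace(p)
  t <- traceTime(tr); y <- traceValues(tr)
  exh <- groundTruth(tr)$adp_exhausted_s
  inS3 <- t >= 200 & t <= exh
  expect_equal(diff(y[inS3]) / diff(t[inS3]), rep(-10 / 60, sum(inS3) - 1),
               tolerance = 1e-12)
  inS4 <- t >= exh & t <= max(t)
  expect_equal(diff(y[inS4]) / diff(t[inS4]), rep(-2.5 / 60, sum(inS4) - 1),
               tolerance = 1e-12)
  ## State 3 steeper than State 4 by construction in the defaults
  tr2 <- synthRespiroTrace(respiroParams())
  sl <- groundTruth(tr2)$slopes_nmol_ml_min
  expect_gt(abs(sl[["state3"]]), abs(sl[["state4"]]))
})

test_that("noisy window regression recovers the generating slopes within 5%", {
  tr <- synthRespiroTrace(respiroParams(noiseSd = 0.5, seed = 3,
                                        annotateExhaustion = TRUE))
  sl <- groundTruth(tr)$slopes_nmol_ml_min
  fitSlope <- function(a, b) {
    t <- traceTime(tr); y <- traceValues(tr)
    sel <- t >= a & t < b
    unname(coef(lm(y[sel] ~ t[sel]))[2]) * 60
  }
  expect_equal(fitSlope(210, 350), sl[["state3"]], tolerance = 0.05)
  expect_equal(fitSlope(360, 500), sl[["state4"]], tolerance = 0.05)
  expect_equal(fitSlope(510, 650), sl[["uncoupled"]], tolerance = 0.05)
})

test_that("respirometry parameter validation enforces the protocol", {
  expect_error(synthRespiroTrace(respiroParams(o2Start = 30)), "anoxia")
  expect_error(respiroParams(eventTimesS = c(substrate = 200, ADP = 100, DNP = 500)),
               "increasing")
  expect_error(respiroParams(slopes = c(basal = -1, state2 = -3, state3 = -2,
                                        state4 = -5, uncoupled = -9)),
               "State 3")
})

test_that("fluorometer traces carry their generating read-outs", {
  rh <- synthFluoroTrace(fluoroParams("rh123",
                                      baselineLevel = 100,
                                      plateausAu = c(quench = 60, recovery = 95)))
  expect_equal(groundTruth(rh)$delta_f_au, 40)
  expect_equal(groundTruth(rh)$cccp_release_au, 35)

  ms <- synthFluoroTrace(fluoroParams("mitosox", ratesAuS = c(initial = 5)))
  t <- traceTime(ms); y <- traceValues(ms)
  early <- t <= 300
  expect_equal(unname(coef(lm(y[early] ~ t[early]))[2]), 5, tolerance = 1e-12)

  ## calibration steps of a constructed sequence recover the linear response
  cal <- h2o2Calibration(c(0.1, 0.2, 0.4), c(10, 20, 40))
  expect_equal(cal@slopeAuPerNmol, 100, tolerance = 1e-9)
  expect_equal(cal@interceptAu, 0, tolerance = 1e-9)
  expect_equal(cal@r2, 1, tolerance = 1e-12)
})

test_that("event structure is enforced per assay kind", {
  expect_error(fluoroParams("amplex", eventTimesS = c(rotenone = 400)),
               "antimycin")
  expect_error(fluoroParams("rh123", eventTimesS = c(substrate = 100)),
               "300 s")
  expect_error(fluoroParams("mitosox", eventTimesS = c(rotenone = 100)),
               "no addition events")
  expect_error(fluoroParams("rh123", plateausAu = c(quench = 60),
                            eventTimesS = c(substrate = 320, cccp = 700)),
               "recovery")
})
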