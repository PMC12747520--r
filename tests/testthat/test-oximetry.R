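ext <- hbExtinctionTable()

test_that("unmixing hits the pure-species limits and the mixture round trip", {
  expect_equal(unmix(ext@epsOxy[1], ext@epsOxy[2], ext)$so2, 1)
  expect_equal(unmix(ext@epsDeoxy[1], ext@epsDeoxy[2], ext)$so2, 0)
  for (s in seq(0, 1, by = 0.1)) {
    a <- s * ext@epsOxy + (1 - s) * ext@epsDeoxy
    expect_lt(abs(unmix(a[1], a[2], ext)$so2 - s), 1e-10)
  }
  expect_error(unmix(0, 0, ext), "no signal")
  expect_error(hbExtinctionTable(epsOxy = c(10, 20), epsDeoxy = c(20, 40)),
               "singular")
})

test_that("unmixing is scale-invariant in sO2 and homogeneous in C_Hb", {
  a <- 0.3 * ext@epsOxy + 0.7 * ext@epsDeoxy
  u1 <- unmix(a[1], a[2], ext)
  u2 <- unmix(5 * a[1], 5 * a[2], ext)
  expect_equal(u2$so2, u1$so2, tolerance = 1e-12)
  expect_equal(u2$relChb, 5 * u1$relChb, tolerance = 1e-12)
})

test_that("sO2 stays in [0,1] for physically inconsistent amplitude pairs", {
  set.seed(8)
  a1 <- runif(500, 0, 10); a2 <- runif(500, 0, 10)
  u <- unmix(a1, a2, ext)
  ok <- !is.na(u$so2)
  expect_true(all(u$so2[ok] >= 0 & u$so2[ok] <= 1))
  expect_true(all(u$relChb[ok] >= 0))
})

test_that("per-vessel saturation aggregates per the weighting contract", {
  ## uniform phantom vessel: exact recovery
  scn <- makeScene(oneVesselConfig(so2 = 0.7, snr = Inf), seed = 1)
  img <- renderDualWavelength(scn, ext)
  expect_equal(vesselSo2(img, truthMask(scn, 1), ext), 0.7, tolerance = 1e-10)

  ## half sO2 = 1, half sO2 = 0 at equal amplitude: exactly 0.5
  mkAmp <- function(s) s * ext@epsOxy + (1 - s) * ext@epsDeoxy
  tot1 <- sum(mkAmp(1)); tot0 <- sum(mkAmp(0))
  ch1 <- matrix(c(mkAmp(1)[1] / tot1, mkAmp(0)[1] / tot0), 1, 2)
  ch2 <- matrix(c(mkAmp(1)[2] / tot1, mkAmp(0)[2] / tot0), 1, 2)
  ## scale so the 532 amplitudes (weights) are equal in both pixels
  w <- ch1[1, 1] / ch1[1, 2]
  ch1[1, 2] <- ch1[1, 2] * w; ch2[1, 2] <- ch2[1, 2] * w
  img2 <- new("DualWavelengthImage", channels = list(ch1, ch2),
              wavelengthsNm = c(532, 558), pixelSpacingUm = c(5, 5))
  msk <- new("VesselMask", pixels = matrix(TRUE, 1, 2), roi = c(0L, 1L, 0L, 2L),
             pixelSpacingUm = c(5, 5))
  expect_equal(vesselSo2(img2, msk, ext), 0.5, tolerance = 1e-12)
})

test_that("Monte-Carlo per-vessel sO2 recovery is accurate at 25 dB", {
  errs <- c()
  for (s in 1:15) {
    scn <- makeScene(defaultSceneConfig(25), seed = s)
    img <- renderDualWavelength(scn, ext)
    ras <- rasterizeScene(scn)
    for (i in seq_along(sceneVessels(scn))) {
      msk <- new("VesselMask", pixels = ras$label == i,
                 roi = sceneVesselRoi(scn, i),
                 pixelSpacingUm = pixelSpacing(scn))
      errs <- c(errs, vesselSo2(img, msk, ext) - sceneVessels(scn)[[i]]@so2)
    }
  }
  expect_lt(sqrt(mean(errs^2)), 0.03)
})

test_that("vessel classification follows the threshold rule and truth labels", {
  tb <- data.frame(so2 = c(0.95, 0.60, 0.80))
  out <- classifyVessels(tb, "threshold", arterySo2Min = 0.8)
  expect_equal(out$vessel_class, c("artery", "vein", "artery"))
  lab <- classifyVessels(tb, "labels", labels = c("vein", "vein", "artery"))
  expect_equal(lab$vessel_class, c("vein", "vein", "artery"))
  expect_error(classifyVessels(tb, "guess"), "unknown")
  expect_error(classifyVessels(tb, "labels"), "one label per vessel")

  ## well-separated phantom classes are recovered perfectly by threshold
  scn <- makeScene(defaultSceneConfig(25), seed = 6)
  img <- renderDualWavelength(scn, ext)
  meas <- vapply(seq_along(sceneVessels(scn)), function(i)
    vesselSo2(img, truthMask(scn, i), ext), numeric(1))
  pred <- classifyVessels(data.frame(so2 = meas), "threshold")$vessel_class
  truthCls <- vapply(sceneVessels(scn), function(v) v@vesselClass, character(1))
  expect_identical(pred, truthCls)
})
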