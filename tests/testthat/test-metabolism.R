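cfg <- metabolismConfig()

test_that("vessel flux follows the parabolic-profile formula with units", {
  expect_equal(vesselFlow(0, 50), 0)
  ## hand conversion: pi * 1000 um/s * (100 um)^2 / 8 * 60 s / 1e9 um^3/uL
  expect_equal(vesselFlow(1, 100), pi * 1000 * 100^2 / 8 * 60 / 1e9)
  expect_equal(vesselFlow(1, 100), 0.2356, tolerance = 1e-3)
  expect_equal(vesselFlow(1, 200), 4 * vesselFlow(1, 100))   # d^2 scaling
  expect_equal(vesselFlow(3, 80), 3 * vesselFlow(1, 80))     # linear in v
  expect_error(vesselFlow(-1, 50), ">= 0")
  expect_error(vesselFlow(1, 0), "positive")
})

test_that("regional CBF sums feeding-artery flux per region mass", {
  ## hand arithmetic: (0.236 + 0.471) uL/min = 0.707e-3 mL/min over 0.002 g
  a <- data.frame(peak_speed_mm_s = c(1, 2), diameter_um = c(100, 100))
  flows <- vesselFlow(a$peak_speed_mm_s, a$diameter_um)
  expect_equal(regionCbf(a, cfg), sum(flows) / 1000 / 0.002 * 100)
  expect_equal(regionCbf(a, cfg), 35.34, tolerance = 1e-3)

  expect_equal(regionCbf(data.frame(peak_speed_mm_s = 0, diameter_um = 80), cfg), 0)
  ## additivity: splitting one artery into two half-flow arteries
  one <- data.frame(peak_speed_mm_s = 2, diameter_um = 100)
  two <- data.frame(peak_speed_mm_s = c(1, 1), diameter_um = c(100, 100))
  expect_equal(regionCbf(one, cfg), regionCbf(two, cfg))
  expect_error(regionCbf(data.frame(), cfg), "artery")
})

test_that("OEF follows (sa - sv)/sa with flagged inversions", {
  a <- data.frame(so2 = 0.96, peak_speed_mm_s = 1, diameter_um = 100)
  v <- data.frame(so2 = 0.72, peak_speed_mm_s = 1, diameter_um = 100)
  expect_equal(regionOef(a, v)$oef, 0.25)
  v$so2 <- 0.96
  expect_equal(regionOef(a, v)$oef, 0)
  v$so2 <- 0
  expect_equal(regionOef(a, v)$oef, 1)
  v$so2 <- 0.99
  res <- regionOef(a, v)
  expect_lt(res$oef, 0)                       # unclipped
  expect_identical(res$flags, "negative OEF")

  ## flow weighting: the bigger vein dominates the venous saturation
  veins <- data.frame(so2 = c(0.6, 0.8), peak_speed_mm_s = c(1, 1),
                      diameter_um = c(100, 50))
  wFlow <- vesselFlow(veins$peak_speed_mm_s, veins$diameter_um)
  expect_equal(regionOef(a, veins, "flow")$svO2,
               sum(wFlow * veins$so2) / sum(wFlow))
  expect_equal(regionOef(a, veins, "uniform")$svO2, 0.7)
})

test_that("CMRO2 composes its five factors with correct units", {
  expect_equal(regionCmro2(30, 0.3, 0.9, 100, cfg), 11.34)
  expect_equal(regionCmro2(30, 0, 0.9, 100, cfg), 0)
  expect_equal(regionCmro2(60, 0.3, 0.9, 100, cfg),
               2 * regionCmro2(30, 0.3, 0.9, 100, cfg))
  ## strictly increasing in every factor
  base <- regionCmro2(30, 0.3, 0.9, 100, cfg)
  expect_gt(regionCmro2(31, 0.3, 0.9, 100, cfg), base)
  expect_gt(regionCmro2(30, 0.31, 0.9, 100, cfg), base)
  expect_gt(regionCmro2(30, 0.3, 0.91, 100, cfg), base)
  expect_gt(regionCmro2(30, 0.3, 0.9, 101, cfg), base)
  expect_gt(regionCmro2(30, 0.3, 0.9, 100, metabolismConfig(xi = 0.015)), base)
  expect_error(regionCmro2(-1, 0.3, 0.9, 100, cfg), ">= 0")
})

test_that("dimensional scaling audit holds across the formula chain", {
  ## flow ~ v * d^2 exactly
  expect_equal(vesselFlow(2 * 1.7, 60), 2 * vesselFlow(1.7, 60))
  expect_equal(vesselFlow(1.7, 3 * 60), 9 * vesselFlow(1.7, 60))
  ## CBF inversely proportional to region mass
  a <- data.frame(peak_speed_mm_s = 2, diameter_um = 80)
  expect_equal(regionCbf(a, metabolismConfig(regionMassG = 0.004)),
               regionCbf(a, metabolismConfig(regionMassG = 0.002)) / 2)
  ## CMRO2 multiplicative in xi and C_Hb
  expect_equal(regionCmro2(30, 0.3, 0.9, 200, cfg),
               2 * regionCmro2(30, 0.3, 0.9, 100, cfg))
})

test_that("region summary composes CBF, OEF and CMRO2 from scene truth", {
  scn <- makeScene(defaultSceneConfig(), seed = 1)
  reg <- regionHemodynamics(sceneVessels(scn), cfg)
  arts <- Filter(function(v) v@vesselClass == "artery", sceneVessels(scn))
  flows <- vapply(arts, function(v) vesselFlow(v@peakSpeedMmS, v@diameterUm),
                  numeric(1))
  expect_equal(reg@cbfMl100gMin, sum(flows) / 1000 / 0.002 * 100)
  expect_equal(reg@saO2, 0.95)
  expect_equal(reg@svO2, 0.65)
  expect_equal(reg@oef, (0.95 - 0.65) / 0.95)
  expect_equal(reg@cmro2Ml100gMin,
               0.014 * 100 * 0.95 * reg@oef * reg@cbfMl100gMin)
  expect_equal(reg@nArteries, 3L)
  expect_equal(reg@nVeins, 3L)
})

test_that("baseline percentages round half-up to integers", {
  expect_identical(baselinePercent(33.18, 38.37), 86L)
  expect_identical(baselinePercent(22.65, 38.37), 59L)
  expect_identical(baselinePercent(1.13, 2.27), 50L)
  expect_identical(baselinePercent(101, 200), 51L)   # half rounds up
  expect_error(baselinePercent(1, 0), "positive")
})
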