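test_that("Otsu threshold separates two-level and bimodal data", {
  thr <- otsuThreshold(c(rep(0, 4), rep(255, 4)))
  expect_true(all(c(0, 0, 0, 0) <= thr) && all(rep(255, 4) > thr))

  expect_error(otsuThreshold(rep(7, 10)), "degenerate histogram")

  set.seed(1)
  lab <- rep(c(FALSE, TRUE), each = 5000)
  v <- c(rnorm(5000, 30, 10), rnorm(5000, 200, 10))
  thr <- otsuThreshold(v)
  expect_lt(mean((v > thr) != lab), 0.01)
})

test_that("Otsu agrees with an exhaustive between-class-variance maximizer", {
  set.seed(21)
  for (i in 1:30) {
    mu <- sort(runif(2, 0, 255))
    v <- c(rnorm(300, mu[1], runif(1, 5, 25)), rnorm(300, mu[2], runif(1, 5, 25)))
    expect_equal(otsuThreshold(v), exhaustiveOtsu(v), tolerance = 1e-12)
  }
})

test_that("Otsu matches the reference implementation's classification", {
  skip_if_not_installed("EBImage")
  set.seed(5)
  v <- c(rnorm(2000, 60, 15), rnorm(2000, 180, 20))
  v <- pmin(pmax(v, 0), 255)
  norm <- (v - min(v)) / (max(v) - min(v))
  tRef <- EBImage::otsu(matrix(norm, 40, 100), range = c(0, 1), levels = 256)
  tOwn <- (otsuThreshold(v) - min(v)) / (max(v) - min(v))
  expect_lt(mean((norm > tOwn) != (norm > tRef)), 0.005)
})

test_that("fragment removal keeps large components and the largest always", {
  vals <- matrix(0, 40, 60)
  vals[10:29, 10:34] <- 1                    # 500-px component
  vals[c(3, 4, 5), 50] <- 1                  # 3-px speckle
  vals[35, c(3, 4, 5)] <- 1                  # 3-px speckle
  vals[cbind(36:38, 55:57)] <- 1             # 3-px diagonal speckle
  m <- amplitudeMapFromMatrix(vals, 5, 532)
  msk <- segmentVessel(m, c(0, 40, 0, 60), minFragmentPx = 10)
  expect_equal(sum(maskPixels(msk)), 500)
  expect_true(all(which(maskPixels(msk), arr.ind = TRUE)[, 1] %in% 10:29))

  ## raising the fragment threshold never adds pixels
  prev <- maskPixels(segmentVessel(m, c(0, 40, 0, 60), minFragmentPx = 1))
  for (mf in c(4, 10, 600)) {
    cur <- maskPixels(segmentVessel(m, c(0, 40, 0, 60), minFragmentPx = mf))
    expect_true(all(cur <= prev))
    prev <- cur
  }
  ## even above the largest component's size, the largest survives
  expect_equal(sum(maskPixels(segmentVessel(m, c(0, 40, 0, 60), 600))), 500)

  expect_error(segmentVessel(m, c(0, 5, 0, 5)), "degenerate histogram")
})

test_that("phantom vessels segment with high Dice and exact diameters at 30 dB", {
  scn <- makeScene(defaultSceneConfig(30), seed = 2)
  img <- renderDualWavelength(scn, hbExtinctionTable())
  a532 <- channelMap(img, 532)
  ras <- rasterizeScene(scn)
  for (i in seq_along(sceneVessels(scn))) {
    msk <- segmentVessel(a532, sceneVesselRoi(scn, i))
    expect_gt(diceCoef(maskPixels(msk), ras$label == i), 0.95)
    dia <- vesselDiameter(msk, vesselCenterline(msk))
    expect_lt(abs(dia - sceneVessels(scn)[[i]]@diameterUm),
              max(pixelSpacing(scn)))
  }
})

test_that("Dice stays above 0.9 across an SNR and diameter sweep", {
  for (snr in c(20, 30)) for (d in c(30, 60, 90)) {
    scn <- makeScene(oneVesselConfig(diameter = d, snr = snr), seed = snr + d)
    img <- renderDualWavelength(scn, hbExtinctionTable())
    msk <- segmentVessel(channelMap(img, 532), sceneVesselRoi(scn, 1))
    expect_gt(diceCoef(maskPixels(msk), rasterizeScene(scn)$label == 1), 0.9)
  }
})

test_that("centerlines follow the vessel axis for bars, disks and corners", {
  bar <- matrix(FALSE, 20, 60); bar[9:11, 6:55] <- TRUE
  p <- vesselCenterline(bar)
  expect_true(all(p[, 1] == 10))
  expect_gte(nrow(p), 46); expect_lte(nrow(p), 50)

  xy <- expand.grid(r = 1:41, c = 1:41)
  disk <- matrix((xy$r - 21)^2 + (xy$c - 21)^2 <= 15^2, 41, 41)
  pd <- vesselCenterline(disk)
  expect_lte(nrow(pd), 30)                  # no longer than the diameter
  expect_lte(max(abs(pd[, 1] - 21)), 3)     # passes through the center

  L <- matrix(FALSE, 40, 40); L[5:35, 5:9] <- TRUE; L[31:35, 5:35] <- TRUE
  pl <- vesselCenterline(L)
  arc <- cumsum(sqrt(rowSums(diff(pl)^2)))
  expect_true(all(diff(arc) > 0))           # monotone arc length
  expect_gt(nrow(pl), 40)                   # turns the corner (both arms)

  expect_error(vesselCenterline(matrix(c(TRUE, TRUE), 1, 2)), "3 pixels")
})

test_that("chord diameters are exact for rectangles and rotation-invariant", {
  rect <- matrix(FALSE, 30, 60); rect[11:20, 6:55] <- TRUE
  p <- vesselCenterline(rect)
  expect_equal(vesselDiameter(rect, p, c(2, 2)), 20, tolerance = 2 / 20)

  rot <- t(rect)[ncol(rect):1, ]
  pr <- vesselCenterline(rot)
  expect_lt(abs(vesselDiameter(rot, pr, c(2, 2)) -
                vesselDiameter(rect, p, c(2, 2))), 2)

  thin <- matrix(FALSE, 10, 30); thin[5, 3:28] <- TRUE
  pt <- vesselCenterline(thin)
  expect_equal(vesselDiameter(thin, pt, c(4, 4)), 4, tolerance = 1)

  expect_error(vesselDiameter(rect, p[1:4, , drop = FALSE], c(2, 2)),
               "too short")
})
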