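# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive Otsu maximizer: explicit sums over the 256-bin histogram of
# min-max-normalized values for every candidate cut, first maximizer on
# ties. Shares only the histogram definition with the implementation, not
# its arithmetic.
exhaustiveOtsu <- function(v) {
  vmin <- min(v); vmax <- max(v)
  bins <- pmin(floor((v - vmin) / (vmax - vmin) * 256) + 1L, 256L)
  h <- tabulate(bins, 256L)
  mids <- (1:256 - 0.5) / 256
  best <- -Inf; bestk <- NA_integer_
  for (k in 1:255) {
    n0 <- sum(h[1:k]); n1 <- sum(h[(k + 1):256])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / n0
    mu1 <- sum(h[(k + 1):256] * mids[(k + 1):256]) / n1
    sb <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; bestk <- k }
  }
  vmin + bestk / 256 * (vmax - vmin)
}

# Exact-enumeration / Monte-Carlo permutation p-value for the two-sample
# mean difference.
permutationP <- function(a, b, nPerm = 4000) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(nPerm)) {
    idx <- sample(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (nPerm + 1)
}

# One-way F from first-principles sums of squares.
bruteForceF <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# Dice coefficient of two logical masks.
diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Single-vessel scene used where per-vessel isolation matters.
oneVesselConfig <- function(so2 = 0.5, diameter = 60, chb = 120,
                            speed = 2, psf = 6, snr = Inf) {
  list(field_size_um = c(600, 300), pixel_spacing_um = c(5, 5),
       psf_fwhm_um = psf, noise_snr_db = snr,
       vessels = list(list(id = "v", centerline = cbind(c(60, 540), c(150, 150)),
                           diameter_um = diameter, peak_speed_mm_s = speed,
                           so2 = so2, vessel_class = "artery",
                           region = "ipsilateral", chb_g_per_L = chb)))
}

# Ground-truth mask of vessel i as a VesselMask on the scene grid.
truthMask <- function(scene, i) {
  ras <- rasterizeScene(scene)
  new("VesselMask", pixels = ras$label == i,
      roi = sceneVesselRoi(scene, i), pixelSpacingUm = pixelSpacing(scene))
}
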