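#' @include AllClasses.R
NULL

## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's stream afterwards so generators are pure functions of their seed.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Default phantom scene configuration
#'
#' A six-vessel, two-class phantom emulating a hemicortical imaging field at
#' reduced scale: three feeding arteries (sO2 0.95) and three draining veins
#' (sO2 0.65) as parallel straight vessels of 50-90 um diameter in a
#' 1200 x 800 um field at 5 um isotropic pixel spacing, hemoglobin
#' concentration 100 g/L, a 6 um FWHM Gaussian point-spread function and
#' 25 dB additive noise. These values define the study conditions used by
#' all bundled recovery analyses.
#'
#' @param noiseSnrDb additive noise level in dB; `Inf` disables noise.
#' @return A configuration list accepted by [makeScene()].
#' @examples
#' scn <- makeScene(defaultSceneConfig(), seed = 7)
#' @export
defaultSceneConfig <- function(noiseSnrDb = 25) {
  v <- function(id, y, d, speed, so2, cls)
    list(id = id, centerline = cbind(x_um = c(100, 1100), y_um = c(y, y)),
         diameter_um = d, peak_speed_mm_s = speed, so2 = so2,
         vessel_class = cls, region = "ipsilateral", chb_g_per_L = 100)
  list(
    field_size_um = c(1200, 800),
    pixel_spacing_um = c(5, 5),
    psf_fwhm_um = 6,
    noise_snr_db = noiseSnrDb,
    vessels = list(
      v("a1", 110, 60, 3.0, 0.95, "artery"),
      v("v1", 230, 90, 1.5, 0.65, "vein"),
      v("a2", 350, 80, 4.0, 0.95, "artery"),
      v("v2", 470, 70, 1.2, 0.65, "vein"),
      v("a3", 590, 50, 2.5, 0.95, "artery"),
      v("v3", 700, 60, 1.0, 0.65, "vein")
    )
  )
}

.vesselFromList <- function(x) {
  cl <- x$centerline
  if (is.list(cl)) cl <- cbind(x_um = as.numeric(cl$x_um), y_um = as.numeric(cl$y_um))
  vesselSpec(x$id, cl, x$diameter_um, x$peak_speed_mm_s, x$so2,
             x$vessel_class,
             if (is.null(x$region)) "ipsilateral" else x$region,
             if (is.null(x$chb_g_per_L)) 100 else x$chb_g_per_L)
}

## Minimum distance between two polylines, by dense sampling.
.polylineMinDist <- function(a, b, step = 5) {
  dense <- function(p) {
    out <- list()
    for (i in seq_len(nrow(p) - 1)) {
      L <- sqrt(sum((p[i + 1, ] - p[i, ])^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(L / step) + 1L))
      out[[i]] <- cbind(p[i, 1] + t * (p[i + 1, 1] - p[i, 1]),
                        p[i, 2] + t * (p[i + 1, 2] - p[i, 2]))
    }
    do.call(rbind, out)
  }
  pa <- dense(a); pb <- dense(b)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  sqrt(min(d2))
}

#' Build a phantom scene from a configuration
#'
#' Constructs a [PhantomScene-class] from a configuration list. Vessels may
#' be given explicitly (`vessels`, a list of per-vessel lists as in
#' [defaultSceneConfig()]) and/or drawn at random (`n_random_vessels`
#' horizontal vessels with uniformly drawn position, diameter, speed, class
#' and saturation). The result is fully determined by `(config, seed)`.
#'
#' Vessels whose extent leaves the field raise an error; centerline pairs
#' approaching closer than the sum of vessel radii are allowed but flagged
#' with a warning.
#'
#' @param config configuration list; see [defaultSceneConfig()] for the
#'   recognized fields.
#' @param seed integer seed stored in the scene and governing both random
#'   vessel placement and later noise rendering.
#' @return A [PhantomScene-class] object.
#' @examples
#' scn <- makeScene(defaultSceneConfig(), seed = 7)
#' sceneVessels(scn)[[1]]
#' @export
makeScene <- function(config, seed = 1L) {
  field <- as.numeric(config$field_size_um)
  sp <- as.numeric(config$pixel_spacing_um)
  if (length(sp) == 1L) sp <- rep(sp, 2L)
  vessels <- lapply(if (is.null(config$vessels)) list() else config$vessels,
                    .vesselFromList)
  nR <- if (is.null(config$n_random_vessels)) 0L else as.integer(config$n_random_vessels)
  if (nR > 0L) {
    rng <- function(nm, default) if (is.null(config[[nm]])) default else as.numeric(config[[nm]])
    dr <- rng("random_diameter_um", c(40, 90))
    spd <- rng("random_speed_mm_s", c(0.5, 4))
    rand <- .withSeed(seed, {
      lapply(seq_len(nR), function(i) {
        d <- stats::runif(1, dr[1], dr[2])
        y <- stats::runif(1, d / 2 + sp[2], field[2] - d / 2 - sp[2])
        x0 <- d / 2 + sp[1]
        cls <- sample(c("artery", "vein"), 1L)
        vesselSpec(sprintf("r%d", i),
                   cbind(c(x0, field[1] - x0), c(y, y)), d,
                   stats::runif(1, spd[1], spd[2]),
                   if (cls == "artery") stats::runif(1, 0.9, 0.98) else stats::runif(1, 0.6, 0.75),
                   cls, chbGPerL = 100)
      })
    })
    vessels <- c(vessels, rand)
  }
  snr <- config$noise_snr_db
  snr <- if (is.null(snr) || identical(snr, "none")) Inf else as.numeric(snr)
  overlap <- FALSE
  if (length(vessels) > 1L) {
    for (i in seq_len(length(vessels) - 1L)) for (j in seq(i + 1L, length(vessels))) {
      dmin <- .polylineMinDist(vessels[[i]]@centerline, vessels[[j]]@centerline,
                               step = min(sp))
      if (dmin < (vessels[[i]]@diameterUm + vessels[[j]]@diameterUm) / 2) {
        overlap <- TRUE
        warning(sprintf("vessels '%s' and '%s' overlap (centerline distance %.1f um)",
                        vessels[[i]]@id, vessels[[j]]@id, dmin))
      }
    }
  }
  new("PhantomScene", fieldSizeUm = field, pixelSpacingUm = sp,
      vessels = vessels, noiseSnrDb = snr,
      psfFwhmUm = as.numeric(if (is.null(config$psf_fwhm_um)) 0 else config$psf_fwhm_um),
      seed = as.integer(seed), overlapFlag = overlap)
}

#' Recover the configuration list of a scene
#'
#' Inverse of [makeScene()] up to random vessels (which are emitted as
#' explicit vessels): `makeScene(sceneConfig(x), x@seed)` reproduces `x`.
#'
#' @param scene a [PhantomScene-class].
#' @return A configuration list suitable for [makeScene()] and YAML
#'   serialization.
#' @export
sceneConfig <- function(scene) {
  list(
    field_size_um = scene@fieldSizeUm,
    pixel_spacing_um = scene@pixelSpacingUm,
    psf_fwhm_um = scene@psfFwhmUm,
    noise_snr_db = if (is.finite(scene@noiseSnrDb)) scene@noiseSnrDb else "none",
    vessels = lapply(scene@vessels, function(v) list(
      id = v@id,
      centerline = list(x_um = as.numeric(v@centerline[, 1]),
                        y_um = as.numeric(v@centerline[, 2])),
      diameter_um = v@diameterUm, peak_speed_mm_s = v@peakSpeedMmS,
      so2 = v@so2, vessel_class = v@vesselClass, region = v@region,
      chb_g_per_L = v@chbGPerL))
  )
}

## Grid of pixel-center coordinates (um). Rows = y, columns = x.
.sceneGrid <- function(scene) {
  nC <- as.integer(round(scene@fieldSizeUm[1] / scene@pixelSpacingUm[1]))
  nR <- as.integer(round(scene@fieldSizeUm[2] / scene@pixelSpacingUm[2]))
  list(nR = nR, nC = nC,
       x = (seq_len(nC) - 0.5) * scene@pixelSpacingUm[1],
       y = (seq_len(nR) - 0.5) * scene@pixelSpacingUm[2])
}

## Distance from every pixel center to a polyline (vectorized over segments).
.distToPolyline <- function(X, Y, poly) {
  d2 <- rep(Inf, length(X))
  for (i in seq_len(nrow(poly) - 1)) {
    p <- poly[i, ]; q <- poly[i + 1, ]
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(X)) else
      pmin(1, pmax(0, ((X - p[1]) * vx + (Y - p[2]) * vy) / L2))
    d2 <- pmin(d2, (X - (p[1] + t * vx))^2 + (Y - (p[2] + t * vy))^2)
  }
  sqrt(d2)
}

#' Rasterize the ground truth of a phantom scene
#'
#' Converts the vector ground truth to per-pixel maps on the scene grid:
#' the vessel label (0 = background; ties between overlapping vessels go to
#' the vessel whose wall is nearest), the saturation map and the hemoglobin
#' concentration map. Used both by the forward render and by recovery tests
#' needing a ground-truth mask.
#'
#' @param scene a [PhantomScene-class].
#' @return A list with integer matrix `label` and numeric matrices `so2`
#'   and `chb` (0 / NA outside vessels), all rows = y, columns = x.
#' @export
rasterizeScene <- function(scene) {
  g <- .sceneGrid(scene)
  X <- rep(g$x, each = g$nR)
  Y <- rep(g$y, times = g$nC)
  n <- length(X)
  label <- integer(n)
  bestSigned <- rep(Inf, n)
  for (k in seq_along(scene@vessels)) {
    v <- scene@vessels[[k]]
    s <- .distToPolyline(X, Y, v@centerline) - v@diameterUm / 2
    upd <- s <= 0 & s < bestSigned
    label[upd] <- k
    bestSigned[upd] <- s[upd]
  }
  so2 <- chb <- rep(NA_real_, n)
  inV <- label > 0L
  so2[inV] <- vapply(scene@vessels, function(v) v@so2, numeric(1))[label[inV]]
  chb[inV] <- vapply(scene@vessels, function(v) v@chbGPerL, numeric(1))[label[inV]]
  list(label = matrix(label, g$nR, g$nC),
       so2 = matrix(so2, g$nR, g$nC),
       chb = matrix(chb, g$nR, g$nC))
}

#' Padded region of interest around one phantom vessel
#'
#' Bounding box of the vessel (centerline plus radius) in pixel coordinates,
#' expanded by a padding factor about its center — the "region slightly
#' larger than the vessel of interest" handed to [segmentVessel()].
#'
#' @param scene a [PhantomScene-class].
#' @param vesselIndex index of the vessel in `sceneVessels(scene)`.
#' @param pad fractional enlargement of the bounding box (default 0.2, i.e.
#'   a 1.2x box).
#' @return Integer ROI `c(r0, r1, c0, c1)`, half-open and 0-based, clipped
#'   to the scene grid.
#' @export
sceneVesselRoi <- function(scene, vesselIndex, pad = 0.2) {
  v <- scene@vessels[[vesselIndex]]
  g <- .sceneGrid(scene)
  r <- v@diameterUm / 2
  xr <- range(v@centerline[, 1]) + c(-r, r)
  yr <- range(v@centerline[, 2]) + c(-r, r)
  xr <- xr + c(-1, 1) * pad / 2 * diff(xr)
  yr <- yr + c(-1, 1) * pad / 2 * diff(yr)
  c0 <- max(0L, as.integer(floor(xr[1] / scene@pixelSpacingUm[1])))
  c1 <- min(g$nC, as.integer(ceiling(xr[2] / scene@pixelSpacingUm[1])))
  r0 <- max(0L, as.integer(floor(yr[1] / scene@pixelSpacingUm[2])))
  r1 <- min(g$nR, as.integer(ceiling(yr[2] / scene@pixelSpacingUm[2])))
  c(r0, r1, c0, c1)
}
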