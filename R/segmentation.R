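#' @include AllClasses.R
NULL

#' Otsu threshold on a 256-bin histogram
#'
#' Threshold maximizing the between-class variance over a 256-bin histogram
#' of min-max-normalized values, as used to remove background pixels around
#' a vessel of interest. Among tied maximizers the lowest bin edge is
#' returned. The threshold is returned on the original value scale;
#' foreground is `value > threshold`.
#'
#' @param values numeric vector or matrix of nonnegative samples with at
#'   least two distinct values.
#' @return Single numeric threshold.
#' @examples
#' otsuThreshold(c(rep(0, 4), rep(255, 4)))
#' @export
otsuThreshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  vmin <- min(v); vmax <- max(v)
  if (length(v) < 2L || vmax == vmin) stop("degenerate histogram")
  bins <- pmin(floor((v - vmin) / (vmax - vmin) * 256) + 1L, 256L)
  p <- tabulate(bins, nbins = 256L) / length(v)
  mids <- (seq_len(256L) - 0.5) / 256
  w0 <- cumsum(p)[1:255]
  mu <- cumsum(p * mids)
  muT <- mu[256]
  mu0c <- mu[1:255]
  denom <- w0 * (1 - w0)
  sigmaB <- ifelse(denom > 0, (muT * w0 - mu0c)^2 / denom, -Inf)
  k <- which.max(sigmaB)           # first (lowest) maximizer on ties
  vmin + (k / 256) * (vmax - vmin)
}

## 8- (or 4-) connected component labelling by flood fill.
.labelComponents <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  queue <- integer(sum(mask))
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      idx <- queue[head]; head <- head + 1L
      r <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          idx2 <- (c2 - 1L) * nr + r2
          if (mask[idx2] && lab[idx2] == 0L) {
            lab[idx2] <- cur
            tail <- tail + 1L
            queue[tail] <- idx2
          }
        }
      }
    }
  }
  lab
}

#' Segment one vessel inside a region of interest
#'
#' The released single-vessel segmentation recipe: restrict the amplitude
#' map to a region slightly larger than the vessel of interest, remove
#' background pixels with Otsu's threshold, then remove isolated or
#' spurious fragments — 8-connected components smaller than
#' `minFragmentPx` — keeping in any case the largest component.
#'
#' @param map an [AmplitudeMap-class].
#' @param roi integer `c(r0, r1, c0, c1)`, half-open 0-based rectangle
#'   inside the map.
#' @param minFragmentPx components smaller than this many pixels are
#'   discarded (default 10).
#' @return A [VesselMask-class].
#' @examples
#' scn <- makeScene(defaultSceneConfig(noiseSnrDb = 30), seed = 2)
#' img <- renderDualWavelength(scn, hbExtinctionTable())
#' m <- segmentVessel(channelMap(img, 532), sceneVesselRoi(scn, 1))
#' @export
segmentVessel <- function(map, roi, minFragmentPx = 10L) {
  vals <- mapValues(map)
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] < 0L || roi[3] < 0L ||
      roi[2] > nrow(vals) || roi[4] > ncol(vals) ||
      roi[1] >= roi[2] || roi[3] >= roi[4])
    stop("roi must be a nonempty half-open rectangle inside the map")
  sub <- vals[(roi[1] + 1L):roi[2], (roi[3] + 1L):roi[4], drop = FALSE]
  thr <- otsuThreshold(sub)            # errors on a constant ROI
  fg <- sub > thr
  if (!any(fg)) stop("empty foreground after thresholding")
  lab <- .labelComponents(fg, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minFragmentPx)
  if (!length(keep) || !(which.max(sizes) %in% keep))
    keep <- union(keep, which.max(sizes))   # largest component always kept
  fg <- matrix(lab %in% keep & lab > 0L, nrow(sub), ncol(sub))
  full <- matrix(FALSE, nrow(vals), ncol(vals))
  full[(roi[1] + 1L):roi[2], (roi[3] + 1L):roi[4]] <- fg
  new("VesselMask", pixels = full, roi = roi,
      pixelSpacingUm = pixelSpacing(map))
}

## Zhang-Suen thinning to a 1-px skeleton.
.zhangSuen <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okR <- rs >= 1L & rs <= nr; okC <- cs >= 1L & cs <= nc
    out[okR, okC] <- x[rs[okR], cs[okC]]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- sh(m, -1, 0); p3 <- sh(m, -1, 1); p4 <- sh(m, 0, 1)
      p5 <- sh(m, 1, 1); p6 <- sh(m, 1, 0); p7 <- sh(m, 1, -1)
      p8 <- sh(m, 0, -1); p9 <- sh(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nr, nc)
      for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
      cond <- m & B >= 2 & B <= 6 & A == 1
      if (step == 1) cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Centerline of a vessel mask
#'
#' Morphological skeleton (Zhang-Suen thinning) pruned to its longest
#' geodesic path, returned as an ordered end-to-end pixel path. The path
#' defines the vascular axis along which the peak flow speed applies and
#' the local directions used by [vesselDiameter()].
#'
#' @param mask a [VesselMask-class] or logical matrix with >= 3 pixels.
#' @return Integer matrix with columns `row`, `col` (1-based pixel
#'   indices), ordered from one end of the vessel to the other.
#' @export
vesselCenterline <- function(mask) {
  px <- if (is(mask, "VesselMask")) maskPixels(mask) else mask
  if (sum(px) < 3L) stop("mask of fewer than 3 pixels has no centerline")
  sk <- .zhangSuen(px)
  pts <- which(sk, arr.ind = TRUE)
  if (nrow(pts) == 1L) return(matrix(pts, 1L, 2L, dimnames = list(NULL, c("row", "col"))))
  idx <- seq_len(nrow(pts))
  key <- paste(pts[, 1], pts[, 2])
  lookup <- stats::setNames(idx, key)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- lookup[paste(pts[, 1] + dr, pts[, 2] + dc)]
    ok <- !is.na(nb)
    from <- c(from, idx[ok]); to <- c(to, nb[ok])
    w <- c(w, rep(sqrt(dr^2 + dc^2), sum(ok)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE, vertices = data.frame(name = idx))
  g <- igraph::simplify(g, edge.attr.comb = "first")
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  d <- igraph::distances(g, v = main, to = main)
  far <- arrayInd(which.max(d), dim(d))
  path <- igraph::shortest_paths(
    g, from = main[far[1]], to = main[far[2]], output = "vpath")$vpath[[1]]
  ord <- as.integer(igraph::V(g)$name[as.integer(path)])
  out <- pts[ord, , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Vessel diameter from perpendicular mask chords
#'
#' At every interior centerline point (excluding two points at each end)
#' the chord of the mask perpendicular to the local path direction is
#' measured by sub-pixel marching; the diameter is the mean chord length
#' converted to micrometres through the pixel spacing.
#'
#' @param mask a [VesselMask-class] or logical matrix.
#' @param path centerline from [vesselCenterline()]; at least 5 points.
#' @param pixelSpacingUm micrometres per pixel `c(x, y)`; taken from the
#'   mask when it is a [VesselMask-class].
#' @return Diameter in micrometres.
#' @export
vesselDiameter <- function(mask, path, pixelSpacingUm = NULL) {
  px <- if (is(mask, "VesselMask")) maskPixels(mask) else mask
  if (is.null(pixelSpacingUm)) {
    if (!is(mask, "VesselMask")) stop("pixelSpacingUm required for a plain matrix")
    pixelSpacingUm <- pixelSpacing(mask)
  }
  if (length(pixelSpacingUm) == 1L) pixelSpacingUm <- rep(pixelSpacingUm, 2L)
  n <- nrow(path)
  if (is.null(n) || n < 5L) stop("centerline path too short (need >= 5 points)")
  nr <- nrow(px); nc <- ncol(px)
  spx <- pixelSpacingUm[1]; spy <- pixelSpacingUm[2]
  stepUm <- 0.25 * min(pixelSpacingUm)
  maxT <- sqrt((nr * spy)^2 + (nc * spx)^2)
  inside <- function(xu, yu) {
    r <- round(yu / spy + 0.5); cc <- round(xu / spx + 0.5)
    r >= 1 && r <= nr && cc >= 1 && cc <= nc && px[r, cc]
  }
  march <- function(x0, y0, ux, uy) {
    t <- 0
    while (t + stepUm <= maxT &&
           inside(x0 + (t + stepUm) * ux, y0 + (t + stepUm) * uy))
      t <- t + stepUm
    t + stepUm / 2
  }
  chords <- vapply(3:(n - 2), function(i) {
    dy <- (path[i + 2, 1] - path[i - 2, 1]) * spy
    dx <- (path[i + 2, 2] - path[i - 2, 2]) * spx
    L <- sqrt(dx^2 + dy^2)
    if (L == 0) return(NA_real_)
    ux <- -dy / L; uy <- dx / L            # unit normal in um space
    x0 <- (path[i, 2] - 0.5) * spx
    y0 <- (path[i, 1] - 0.5) * spy
    march(x0, y0, ux, uy) + march(x0, y0, -ux, -uy)
  }, numeric(1))
  mean(chords, na.rm = TRUE)
}
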