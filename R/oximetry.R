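#' @include extinction.R
NULL

#' Dual-wavelength linear spectral unmixing
#'
#' Solves, per pixel, the 2x2 linear system
#' `amplitude(lambda) = c_HbO2 * eps_HbO2(lambda) + c_Hb * eps_Hb(lambda)`
#' for the two hemoglobin species, then forms the oxygen saturation
#' `sO2 = c_HbO2 / (c_HbO2 + c_Hb)` and the relative total hemoglobin
#' `rel_chb = c_HbO2 + c_Hb`. Negative unmixed concentrations (possible
#' under noise) are clipped to zero before forming the ratio, so `sO2` is
#' always in `[0, 1]`; `rel_chb` is clipped at zero.
#'
#' Scalar inputs with both amplitudes zero raise a `"no signal"` error;
#' for vector/matrix inputs such pixels yield `NA`.
#'
#' @param a532,a558 nonnegative amplitudes (scalars, vectors or matrices of
#'   identical shape) at the two wavelengths.
#' @param ext an [ExtinctionTable-class] containing both wavelengths.
#' @param wavelengthsNm the wavelength pair (default 532/558 nm), matching
#'   the order of the amplitude arguments.
#' @return List with elements `so2` and `relChb`, shaped like the input.
#' @examples
#' ext <- hbExtinctionTable()
#' unmix(ext@epsOxy[1], ext@epsOxy[2], ext)$so2   # pure HbO2: 1
#' @export
unmix <- function(a532, a558, ext, wavelengthsNm = c(532, 558)) {
  E <- .extMatrix(ext, wavelengthsNm)
  if (any(a532 < 0, na.rm = TRUE) || any(a558 < 0, na.rm = TRUE))
    stop("amplitudes must be nonnegative")
  scalarIn <- length(a532) == 1L && length(a558) == 1L
  zero <- a532 == 0 & a558 == 0
  if (scalarIn && isTRUE(zero)) stop("no signal")
  Ei <- solve(E)
  oxy <- Ei[1, 1] * a532 + Ei[1, 2] * a558
  deoxy <- Ei[2, 1] * a532 + Ei[2, 2] * a558
  oxy <- pmax(oxy, 0)
  deoxy <- pmax(deoxy, 0)
  tot <- oxy + deoxy
  so2 <- ifelse(tot > 0, oxy / tot, NA_real_)
  so2[zero] <- NA_real_
  tot[zero] <- NA_real_
  if (is.matrix(a532)) { dim(so2) <- dim(a532); dim(tot) <- dim(a532) }
  list(so2 = pmin(pmax(so2, 0), 1), relChb = tot)
}

#' Per-pixel sO2 and relative C_Hb maps
#'
#' Applies [unmix()] to every pixel of a dual-wavelength image. Pixels with
#' no signal in either channel are `NA`.
#'
#' @param img a [DualWavelengthImage-class].
#' @param ext an [ExtinctionTable-class].
#' @return List with matrices `so2` and `relChb`.
#' @export
so2Map <- function(img, ext) {
  unmix(img@channels[[1]], img@channels[[2]], ext, wavelengths(img))
}

#' Per-vessel oxygen saturation
#'
#' Amplitude-weighted mean of the per-pixel saturation over the vessel
#' mask, weighting by the 532 nm amplitude so that bright (well-determined)
#' pixels dominate. The result lies in `[0, 1]`.
#'
#' @param img a [DualWavelengthImage-class].
#' @param mask a [VesselMask-class] on the same grid.
#' @param ext an [ExtinctionTable-class].
#' @return Single numeric sO2.
#' @export
vesselSo2 <- function(img, mask, ext) {
  px <- maskPixels(mask)
  if (!identical(dim(px), dim(img@channels[[1]])))
    stop("mask and image grids differ")
  if (!any(px)) stop("empty mask")
  m <- so2Map(img, ext)
  so2 <- m$so2[px]
  w <- img@channels[[1]][px]
  ok <- !is.na(so2) & w > 0
  if (!any(ok)) stop("no signal in any mask pixel")
  sum(w[ok] * so2[ok]) / sum(w[ok])
}

#' Classify vessels as arteries or veins
#'
#' Threshold mode labels a vessel an artery iff its sO2 is at least
#' `arterySo2Min` (default 0.8 — a heuristic placeholder; anatomical or
#' ground-truth labels are preferred where available). Labels mode passes
#' user labels through unchanged.
#'
#' @param vessels data.frame with at least an `so2` column (threshold mode).
#' @param method `"threshold"` or `"labels"`.
#' @param arterySo2Min saturation cut for threshold mode, in (0, 1).
#' @param labels character vector of `"artery"`/`"vein"` for labels mode.
#' @return `vessels` with a `vessel_class` column.
#' @export
classifyVessels <- function(vessels, method = c("threshold", "labels"),
                            arterySo2Min = 0.8, labels = NULL) {
  method <- tryCatch(match.arg(method), error = function(e)
    stop("unknown classification method"))
  if (method == "threshold") {
    if (!is.numeric(arterySo2Min) || arterySo2Min <= 0 || arterySo2Min >= 1)
      stop("arterySo2Min must lie in (0, 1)")
    vessels$vessel_class <- ifelse(vessels$so2 >= arterySo2Min, "artery", "vein")
  } else {
    if (is.null(labels) || length(labels) != nrow(vessels))
      stop("labels mode requires one label per vessel")
    vessels$vessel_class <- labels
  }
  vessels
}
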