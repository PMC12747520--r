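#' @include AllClasses.R
NULL

#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "PhantomScene", function(x) x@pixelSpacingUm)
#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "AmplitudeMap", function(x) x@pixelSpacingUm)
#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "DualWavelengthImage", function(x) x@pixelSpacingUm)
#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "VesselMask", function(x) x@pixelSpacingUm)

#' @rdname mapValues
#' @export
setMethod("mapValues", "AmplitudeMap", function(x) x@values)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "AmplitudeMap", function(x) x@wavelengthNm)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "DualWavelengthImage", function(x) x@wavelengthsNm)

#' @rdname sceneVessels
#' @export
setMethod("sceneVessels", "PhantomScene", function(x) x@vessels)

#' @rdname ensembleLines
#' @export
setMethod("ensembleLines", "AlineEnsemble", function(x) x@lines)

#' @rdname traceTime
#' @export
setMethod("traceTime", "RespiroTrace", function(x) x@timeS)
#' @rdname traceTime
#' @export
setMethod("traceTime", "FluoroTrace", function(x) x@timeS)

#' @rdname traceValues
#' @export
setMethod("traceValues", "RespiroTrace", function(x) x@o2NmolPerMl)
#' @rdname traceValues
#' @export
setMethod("traceValues", "FluoroTrace", function(x) x@fluorescenceAu)

#' @rdname traceEvents
#' @export
setMethod("traceEvents", "RespiroTrace", function(x) x@events)
#' @rdname traceEvents
#' @export
setMethod("traceEvents", "FluoroTrace", function(x) x@events)

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "RespiroTrace", function(x) x@truth)
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "FluoroTrace", function(x) x@truth)
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "AlineEnsemble", function(x) x@truth)

#' @rdname maskPixels
#' @export
setMethod("maskPixels", "VesselMask", function(x) x@pixels)
#' @rdname maskRoi
#' @export
setMethod("maskRoi", "VesselMask", function(x) x@roi)

## show methods -------------------------------------------------------------

setMethod("show", "VesselSpec", function(object) {
  cat(sprintf("VesselSpec '%s' (%s, %s): d = %.1f um, v = %.2f mm/s, sO2 = %.2f, C_Hb = %.0f g/L\n",
              object@id, object@vesselClass, object@region, object@diameterUm,
              object@peakSpeedMmS, object@so2, object@chbGPerL))
})

setMethod("show", "PhantomScene", function(object) {
  cat(sprintf("PhantomScene: %.0f x %.0f um field, %.3g x %.3g um pixels, %d vessels\n",
              object@fieldSizeUm[1], object@fieldSizeUm[2],
              object@pixelSpacingUm[1], object@pixelSpacingUm[2],
              length(object@vessels)))
  cat(sprintf("  PSF FWHM %.1f um, SNR %s dB, seed %d%s\n", object@psfFwhmUm,
              ifelse(is.finite(object@noiseSnrDb),
                     format(object@noiseSnrDb), "Inf (noise-free)"),
              object@seed,
              if (isTRUE(object@overlapFlag)) " [overlapping vessels]" else ""))
  for (v in object@vessels) show(v)
})

setMethod("show", "AmplitudeMap", function(object) {
  cat(sprintf("AmplitudeMap %d x %d px @ %g nm, spacing (%g, %g) um, range [%.3g, %.3g]\n",
              nrow(object@values), ncol(object@values), object@wavelengthNm,
              object@pixelSpacingUm[1], object@pixelSpacingUm[2],
              min(object@values), max(object@values)))
})

setMethod("show", "DualWavelengthImage", function(object) {
  cat(sprintf("DualWavelengthImage %d x %d px, wavelengths %g / %g nm, spacing (%g, %g) um\n",
              nrow(object@channels[[1]]), ncol(object@channels[[1]]),
              object@wavelengthsNm[1], object@wavelengthsNm[2],
              object@pixelSpacingUm[1], object@pixelSpacingUm[2]))
})

setMethod("show", "AlineEnsemble", function(object) {
  cat(sprintf("AlineEnsemble: %d lines x %d samples, dt = %g s\n",
              nrow(object@lines), ncol(object@lines), object@dtS))
})

setMethod("show", "VesselMask", function(object) {
  cat(sprintf("VesselMask: %d px in ROI [%d, %d) x [%d, %d) of a %d x %d map\n",
              sum(object@pixels), object@roi[1], object@roi[2],
              object@roi[3], object@roi[4],
              nrow(object@pixels), ncol(object@pixels)))
})

setMethod("show", "RespiroTrace", function(object) {
  cat(sprintf("RespiroTrace: %d samples over %.0f s, %.3g mg protein in %.2g mL\n",
              length(object@timeS), max(object@timeS), object@proteinMg,
              object@chamberMl))
  if (nrow(object@events))
    cat("  events:", paste(sprintf("%s@%gs", object@events$label,
                                   object@events$time_s), collapse = ", "), "\n")
})

setMethod("show", "FluoroTrace", function(object) {
  cat(sprintf("FluoroTrace (%s): %d samples over %.0f s\n", object@kind,
              length(object@timeS), max(object@timeS)))
  if (nrow(object@events))
    cat("  events:", paste(sprintf("%s@%gs", object@events$label,
                                   object@events$time_s), collapse = ", "), "\n")
})

setMethod("show", "ExtinctionTable", function(object) {
  cat("ExtinctionTable (cm^-1 M^-1):\n")
  print(data.frame(wavelength_nm = object@wavelengthsNm,
                   eps_HbO2 = object@epsOxy, eps_Hb = object@epsDeoxy),
        row.names = FALSE)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: slope %.4g a.u./nmol, intercept %.4g a.u., R^2 = %.4f (n = %d)\n",
              object@slopeAuPerNmol, object@interceptAu, object@r2,
              length(object@additionsNmol)))
})

setMethod("show", "RegionHemodynamics", function(object) {
  cat(sprintf("RegionHemodynamics (%s): CBF %.2f mL/100g/min, OEF %.3f, CMRO2 %.3f mL O2/100g/min\n",
              object@region, object@cbfMl100gMin, object@oef,
              object@cmro2Ml100gMin))
  cat(sprintf("  saO2 %.3f, svO2 %.3f, C_Hb %.1f g/L, %d arteries / %d veins%s\n",
              object@saO2, object@svO2, object@chbGPerL, object@nArteries,
              object@nVeins,
              if (length(object@flags)) paste0(" [", paste(object@flags, collapse = "; "), "]") else ""))
})
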