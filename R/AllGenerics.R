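#' @include AllGenerics.R
NULL

#' Pixel spacing of a gridded object
#'
#' Returns the physical pixel spacing, in micrometres, as a length-2 numeric
#' vector `c(x, y)`.
#'
#' @param x A [PhantomScene-class], [AmplitudeMap-class],
#'   [DualWavelengthImage-class] or [VesselMask-class] object.
#' @return Numeric vector of length 2 (micrometres per pixel in x and y).
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' Grid values of a map-like object
#'
#' @param x An [AmplitudeMap-class] object.
#' @return A numeric matrix (rows = y, columns = x).
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Wavelengths carried by an imaging object
#'
#' @param x An [AmplitudeMap-class] or [DualWavelengthImage-class] object.
#' @return Numeric vector of wavelengths in nanometres.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Vessels of a phantom scene
#'
#' @param x A [PhantomScene-class] object.
#' @return A list of [VesselSpec-class] objects.
#' @export
setGeneric("sceneVessels", function(x) standardGeneric("sceneVessels"))

#' A-line matrix of an ensemble
#'
#' @param x An [AlineEnsemble-class] object.
#' @return Numeric matrix, one A-line per row.
#' @export
setGeneric("ensembleLines", function(x) standardGeneric("ensembleLines"))

#' Time axis of an instrument trace
#'
#' @param x A [RespiroTrace-class] or [FluoroTrace-class] object.
#' @return Numeric vector of times in seconds.
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' Measured values of an instrument trace
#'
#' @param x A [RespiroTrace-class] (O2 concentration, nmol/mL) or
#'   [FluoroTrace-class] (fluorescence, a.u.) object.
#' @return Numeric vector aligned with [traceTime()].
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' Event annotations of an instrument trace
#'
#' @param x A [RespiroTrace-class] or [FluoroTrace-class] object.
#' @return A `data.frame` with columns `time_s` and `label`.
#' @export
setGeneric("traceEvents", function(x) standardGeneric("traceEvents"))

#' Ground-truth metadata of a synthetic object
#'
#' Synthetic generators record their generating parameters so that recovery
#' tests can compare estimates against truth.
#'
#' @param x A synthetic trace or ensemble object.
#' @return A named list of generating parameters (empty for real data).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Foreground pixels of a vessel mask
#'
#' @param x A [VesselMask-class] object.
#' @return Logical matrix with the dimensions of the source amplitude map.
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' Region of interest of a vessel mask
#'
#' @param x A [VesselMask-class] object.
#' @return Integer vector `c(r0, r1, c0, c1)`, a half-open 0-based rectangle
#'   `[r0, r1) x [c0, c1)`.
#' @export
setGeneric("maskRoi", function(x) standardGeneric("maskRoi"))
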