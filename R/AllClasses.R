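#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Phantom scene
## ---------------------------------------------------------------------------

#' VesselSpec: ground-truth description of one vessel
#'
#' A single vessel of a synthetic phantom scene: its centerline polyline in
#' scene coordinates (micrometres), geometric diameter, peak axial flow
#' speed, hemoglobin oxygen saturation, arterial/venous class, hemicortical
#' region and total hemoglobin concentration.
#'
#' @slot id character(1), vessel label.
#' @slot centerline numeric matrix with columns `x_um`, `y_um` (>= 2 rows).
#' @slot diameterUm positive vessel diameter, micrometres.
#' @slot peakSpeedMmS peak flow speed along the vascular axis, mm/s (>= 0).
#' @slot so2 hemoglobin oxygen saturation, fraction in \[0, 1\].
#' @slot vesselClass `"artery"` or `"vein"`.
#' @slot region `"ipsilateral"` or `"contralateral"`.
#' @slot chbGPerL total hemoglobin concentration, g/L (> 0).
#' @seealso [vesselSpec()], [makeScene()]
#' @export
setClass("VesselSpec", representation(
  id = "character", centerline = "matrix", diameterUm = "numeric",
  peakSpeedMmS = "numeric", so2 = "numeric", vesselClass = "character",
  region = "character", chbGPerL = "numeric"
))

setValidity("VesselSpec", function(object) {
  msg <- character()
  if (ncol(object@centerline) != 2L || nrow(object@centerline) < 2L)
    msg <- c(msg, "centerline must be a matrix with 2 columns and >= 2 rows")
  if (!all(is.finite(object@centerline)))
    msg <- c(msg, "centerline must be finite")
  if (length(object@diameterUm) != 1L || object@diameterUm <= 0)
    msg <- c(msg, "diameterUm must be a single positive number")
  if (length(object@peakSpeedMmS) != 1L || object@peakSpeedMmS < 0)
    msg <- c(msg, "peakSpeedMmS must be >= 0")
  if (length(object@so2) != 1L || object@so2 < 0 || object@so2 > 1)
    msg <- c(msg, "so2 must lie in [0, 1]")
  if (!object@vesselClass %in% c("artery", "vein"))
    msg <- c(msg, "vesselClass must be 'artery' or 'vein'")
  if (!object@region %in% c("ipsilateral", "contralateral"))
    msg <- c(msg, "region must be 'ipsilateral' or 'contralateral'")
  if (length(object@chbGPerL) != 1L || object@chbGPerL <= 0)
    msg <- c(msg, "chbGPerL must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a VesselSpec
#'
#' @param id vessel label.
#' @param centerline two-column matrix (x_um, y_um) describing the vessel
#'   axis as a polyline in scene coordinates.
#' @param diameterUm vessel diameter in micrometres.
#' @param peakSpeedMmS peak flow speed along the axis, mm/s.
#' @param so2 hemoglobin oxygen saturation, in \[0, 1\].
#' @param vesselClass `"artery"` or `"vein"`.
#' @param region `"ipsilateral"` or `"contralateral"`.
#' @param chbGPerL total hemoglobin concentration, g/L.
#' @return A [VesselSpec-class] object.
#' @examples
#' v <- vesselSpec("a1", cbind(c(50, 450), c(100, 100)), diameterUm = 60,
#'                 peakSpeedMmS = 3, so2 = 0.95, vesselClass = "artery")
#' @export
vesselSpec <- function(id, centerline, diameterUm, peakSpeedMmS, so2,
                       vesselClass, region = "ipsilateral", chbGPerL = 100) {
  centerline <- as.matrix(centerline)
  storage.mode(centerline) <- "double"
  colnames(centerline) <- c("x_um", "y_um")
  new("VesselSpec", id = as.character(id), centerline = centerline,
      diameterUm = as.numeric(diameterUm),
      peakSpeedMmS = as.numeric(peakSpeedMmS), so2 = as.numeric(so2),
      vesselClass = vesselClass, region = region,
      chbGPerL = as.numeric(chbGPerL))
}

#' PhantomScene: ground-truth synthetic vessel network
#'
#' Container for a synthetic imaging scene: field extents and pixel spacing,
#' a list of [VesselSpec-class] vessels, the optical blur width, the additive
#' noise level and the seed that fully determines any stochastic rendering.
#' The scene is the oracle for all downstream recovery tests.
#'
#' @slot fieldSizeUm numeric(2), field extents `c(x, y)` in micrometres.
#' @slot pixelSpacingUm numeric(2), pixel spacing `c(x, y)` in micrometres.
#' @slot vessels list of [VesselSpec-class].
#' @slot noiseSnrDb single numeric; `Inf` means noise-free.
#' @slot psfFwhmUm Gaussian point-spread-function FWHM in micrometres (>= 0).
#' @slot seed integer seed governing rendering noise.
#' @slot overlapFlag logical; `TRUE` if any two centerlines approach closer
#'   than the sum of vessel radii.
#' @export
setClass("PhantomScene", representation(
  fieldSizeUm = "numeric", pixelSpacingUm = "numeric", vessels = "list",
  noiseSnrDb = "numeric", psfFwhmUm = "numeric", seed = "integer",
  overlapFlag = "logical"
))

setValidity("PhantomScene", function(object) {
  msg <- character()
  if (length(object@fieldSizeUm) != 2L || any(object@fieldSizeUm <= 0))
    msg <- c(msg, "fieldSizeUm must be two positive numbers")
  if (length(object@pixelSpacingUm) != 2L || any(object@pixelSpacingUm <= 0))
    msg <- c(msg, "pixelSpacingUm must be two positive numbers")
  if (length(object@psfFwhmUm) != 1L || object@psfFwhmUm < 0)
    msg <- c(msg, "psfFwhmUm must be >= 0")
  for (v in object@vessels) {
    if (!is(v, "VesselSpec")) { msg <- c(msg, "vessels must be VesselSpec"); break }
    r <- v@diameterUm / 2
    if (any(v@centerline[, 1] - r < 0) || any(v@centerline[, 1] + r > object@fieldSizeUm[1]) ||
        any(v@centerline[, 2] - r < 0) || any(v@centerline[, 2] + r > object@fieldSizeUm[2]))
      msg <- c(msg, sprintf("vessel '%s' extends outside the field", v@id))
    if (v@diameterUm <= 2 * max(object@pixelSpacingUm))
      msg <- c(msg, sprintf("vessel '%s' is narrower than 2 pixels and not renderable", v@id))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Imaging containers
## ---------------------------------------------------------------------------

#' AmplitudeMap: projected photoacoustic amplitude image
#'
#' A 2-D nonnegative amplitude grid at one optical wavelength, as produced by
#' taking the peak Hilbert envelope of each A-line ([amplitudeMap()]) or by
#' the synthetic forward model.
#'
#' @slot values numeric matrix, rows = y, columns = x; all values >= 0.
#' @slot pixelSpacingUm numeric(2), micrometres per pixel `c(x, y)`.
#' @slot wavelengthNm numeric(1), optical wavelength in nanometres.
#' @export
setClass("AmplitudeMap", representation(
  values = "matrix", pixelSpacingUm = "numeric", wavelengthNm = "numeric"
))

setValidity("AmplitudeMap", function(object) {
  msg <- character()
  if (!is.numeric(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be a finite numeric matrix")
  else if (any(object@values < 0))
    msg <- c(msg, "amplitude values must be nonnegative")
  if (length(object@pixelSpacingUm) != 2L || any(object@pixelSpacingUm <= 0))
    msg <- c(msg, "pixelSpacingUm must be two positive numbers")
  if (length(msg)) msg else TRUE
})

#' Construct an AmplitudeMap
#'
#' @param values nonnegative numeric matrix (rows = y, columns = x).
#' @param pixelSpacingUm pixel spacing in micrometres, length 1 (isotropic)
#'   or 2 `c(x, y)`.
#' @param wavelengthNm optical wavelength in nanometres.
#' @return An [AmplitudeMap-class] object.
#' @export
amplitudeMapFromMatrix <- function(values, pixelSpacingUm, wavelengthNm) {
  if (length(pixelSpacingUm) == 1L) pixelSpacingUm <- rep(pixelSpacingUm, 2L)
  new("AmplitudeMap", values = values, pixelSpacingUm = as.numeric(pixelSpacingUm),
      wavelengthNm = as.numeric(wavelengthNm))
}

#' DualWavelengthImage: co-registered 532/558 nm amplitude maps
#'
#' Two co-registered nonnegative amplitude channels acquired (or rendered) at
#' the two excitation wavelengths used for spectroscopic oximetry.
#'
#' @slot channels list of two numeric matrices of identical dimension.
#' @slot wavelengthsNm numeric(2), channel wavelengths in nanometres.
#' @slot pixelSpacingUm numeric(2), micrometres per pixel `c(x, y)`.
#' @export
setClass("DualWavelengthImage", representation(
  channels = "list", wavelengthsNm = "numeric", pixelSpacingUm = "numeric"
))

setValidity("DualWavelengthImage", function(object) {
  msg <- character()
  if (length(object@channels) != 2L)
    msg <- c(msg, "exactly two channels required")
  else {
    d1 <- dim(object@channels[[1]]); d2 <- dim(object@channels[[2]])
    if (!identical(d1, d2)) msg <- c(msg, "channels must have identical shape")
    if (any(vapply(object@channels, function(m) any(m < 0), logical(1))))
      msg <- c(msg, "amplitudes must be nonnegative")
  }
  if (length(object@wavelengthsNm) != 2L)
    msg <- c(msg, "two wavelengths required")
  if (length(msg)) msg else TRUE
})

#' Extract one wavelength channel as an AmplitudeMap
#'
#' @param img a [DualWavelengthImage-class].
#' @param wavelengthNm which channel to extract, in nanometres.
#' @return An [AmplitudeMap-class].
#' @export
channelMap <- function(img, wavelengthNm) {
  i <- match(wavelengthNm, img@wavelengthsNm)
  if (is.na(i))
    stop("wavelength ", wavelengthNm, " nm not present in image")
  amplitudeMapFromMatrix(img@channels[[i]], img@pixelSpacingUm, wavelengthNm)
}

#' AlineEnsemble: repeated A-lines at a fixed location
#'
#' A matrix of A-line signals acquired at one vessel location at a fixed
#' laser repetition interval. Inter-line decorrelation encodes flow speed.
#'
#' @slot lines numeric matrix, `n_lines x n_samples`, one A-line per row.
#' @slot dtS repetition interval between consecutive lines, seconds.
#' @slot truth list of generating parameters when synthetic, else empty.
#' @export
setClass("AlineEnsemble", representation(
  lines = "matrix", dtS = "numeric", truth = "list"
))

setValidity("AlineEnsemble", function(object) {
  msg <- character()
  if (nrow(object@lines) < 16L)
    msg <- c(msg, "at least 16 A-lines required")
  if (length(object@dtS) != 1L || object@dtS <= 0)
    msg <- c(msg, "dtS must be a single positive number")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Vessel mask
## ---------------------------------------------------------------------------

#' VesselMask: segmented foreground of one vessel
#'
#' Foreground pixels of a single segmented vessel within a rectangular region
#' of interest of an amplitude map. Coordinates are 0-based and the ROI is a
#' half-open rectangle `[r0, r1) x [c0, c1)` in (row, column) order.
#'
#' @slot pixels logical matrix with the dimensions of the source map; `TRUE`
#'   marks vessel foreground. All `TRUE` pixels lie inside the ROI.
#' @slot roi integer(4), `c(r0, r1, c0, c1)` half-open, 0-based.
#' @slot pixelSpacingUm numeric(2), micrometres per pixel `c(x, y)`.
#' @export
setClass("VesselMask", representation(
  pixels = "matrix", roi = "integer", pixelSpacingUm = "numeric"
))

setValidity("VesselMask", function(object) {
  msg <- character()
  if (!is.logical(object@pixels))
    msg <- c(msg, "pixels must be a logical matrix")
  if (length(object@roi) != 4L)
    msg <- c(msg, "roi must be c(r0, r1, c0, c1)")
  else {
    r <- object@roi
    if (r[1] < 0 || r[3] < 0 || r[2] > nrow(object@pixels) || r[4] > ncol(object@pixels) ||
        r[1] >= r[2] || r[3] >= r[4])
      msg <- c(msg, "roi must be a nonempty rectangle inside the map")
    else {
      idx <- which(object@pixels, arr.ind = TRUE)
      if (nrow(idx) == 0L)
        msg <- c(msg, "mask must be nonempty")
      else if (any(idx[, 1] <= r[1]) || any(idx[, 1] > r[2]) ||
               any(idx[, 2] <= r[3]) || any(idx[, 2] > r[4]))
        msg <- c(msg, "mask pixels must lie inside the roi")
    }
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Instrument traces
## ---------------------------------------------------------------------------

.checkEvents <- function(events) {
  if (!is.data.frame(events) || !all(c("time_s", "label") %in% names(events)))
    return("events must be a data.frame with columns time_s and label")
  if (is.unsorted(events$time_s, strictly = TRUE) && nrow(events) > 1)
    return("event times must be strictly increasing")
  NULL
}

#' RespiroTrace: Clark-electrode oxygen concentration trace
#'
#' A timestamped chamber O2 concentration recording from a Clark-type
#' electrode, with labeled addition events (`substrate`, `ADP`, `DNP`, and
#' optionally `adp_exhausted` when the State 3 to State 4 transition was
#' annotated by the operator) plus the protein load and chamber volume needed
#' to express respiration rates per mg mitochondrial protein.
#'
#' @slot timeS numeric, strictly increasing time in seconds.
#' @slot o2NmolPerMl numeric, chamber O2 concentration, nmol/mL.
#' @slot events data.frame with columns `time_s`, `label`.
#' @slot proteinMg mitochondrial protein in the chamber, mg (> 0).
#' @slot chamberMl chamber volume, mL (> 0).
#' @slot truth list of generating parameters when synthetic, else empty.
#' @export
setClass("RespiroTrace", representation(
  timeS = "numeric", o2NmolPerMl = "numeric", events = "data.frame",
  proteinMg = "numeric", chamberMl = "numeric", truth = "list"
))

setValidity("RespiroTrace", function(object) {
  msg <- character()
  if (length(object@timeS) != length(object@o2NmolPerMl))
    msg <- c(msg, "timeS and o2NmolPerMl must have equal length")
  if (is.unsorted(object@timeS, strictly = TRUE))
    msg <- c(msg, "timeS must be strictly increasing")
  if (object@proteinMg <= 0) msg <- c(msg, "proteinMg must be positive")
  if (object@chamberMl <= 0) msg <- c(msg, "chamberMl must be positive")
  e <- .checkEvents(object@events)
  if (!is.null(e)) msg <- c(msg, e)
  if (length(msg)) msg else TRUE
})

#' FluoroTrace: fluorometer kinetic trace
#'
#' A timestamped fluorescence recording from one of the three mitochondrial
#' assays: Amplex UltraRed / HRP H2O2 detection (`"amplex"`; rotenone and
#' antimycin A additions), MitoSOX Red superoxide detection (`"mitosox"`;
#' no required additions) or rhodamine-123 membrane-potential quenching
#' (`"rh123"`; oxidizable substrate then CCCP).
#'
#' @slot kind `"amplex"`, `"mitosox"` or `"rh123"`.
#' @slot timeS numeric, strictly increasing time in seconds.
#' @slot fluorescenceAu numeric, fluorescence in arbitrary units.
#' @slot events data.frame with columns `time_s`, `label`.
#' @slot truth list of generating parameters when synthetic, else empty.
#' @export
setClass("FluoroTrace", representation(
  kind = "character", timeS = "numeric", fluorescenceAu = "numeric",
  events = "data.frame", truth = "list"
))

setValidity("FluoroTrace", function(object) {
  msg <- character()
  if (!object@kind %in% c("amplex", "mitosox", "rh123"))
    msg <- c(msg, "kind must be one of amplex, mitosox, rh123")
  if (length(object@timeS) != length(object@fluorescenceAu))
    msg <- c(msg, "timeS and fluorescenceAu must have equal length")
  if (is.unsorted(object@timeS, strictly = TRUE))
    msg <- c(msg, "timeS must be strictly increasing")
  e <- .checkEvents(object@events)
  if (!is.null(e)) msg <- c(msg, e)
  labs <- object@events$label
  if (object@kind == "amplex" && !all(c("rotenone", "antimycin") %in% labs))
    msg <- c(msg, "amplex trace requires rotenone and antimycin events")
  if (object@kind == "rh123" && !"substrate" %in% labs)
    msg <- c(msg, "rh123 trace requires a substrate event")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Spectral / calibration / config value classes
## ---------------------------------------------------------------------------

#' ExtinctionTable: hemoglobin molar extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the imaging
#' wavelengths, used by the linear spectral unmixing. Any pair of listed
#' wavelengths must form an invertible 2x2 system.
#'
#' @slot wavelengthsNm numeric, wavelengths in nanometres.
#' @slot epsOxy numeric, HbO2 molar extinction (cm^-1 M^-1), > 0.
#' @slot epsDeoxy numeric, Hb molar extinction (cm^-1 M^-1), > 0.
#' @seealso [hbExtinctionTable()]
#' @export
setClass("ExtinctionTable", representation(
  wavelengthsNm = "numeric", epsOxy = "numeric", epsDeoxy = "numeric"
))

setValidity("ExtinctionTable", function(object) {
  msg <- character()
  n <- length(object@wavelengthsNm)
  if (length(object@epsOxy) != n || length(object@epsDeoxy) != n)
    msg <- c(msg, "extinction vectors must match wavelengths in length")
  if (any(object@epsOxy <= 0) || any(object@epsDeoxy <= 0))
    msg <- c(msg, "all extinction coefficients must be positive")
  if (n >= 2 && !length(msg)) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      det2 <- object@epsOxy[i] * object@epsDeoxy[j] -
        object@epsOxy[j] * object@epsDeoxy[i]
      if (abs(det2) < .Machine$double.eps * 100)
        msg <- c(msg, sprintf("wavelength pair (%g, %g) is singular",
                              object@wavelengthsNm[i], object@wavelengthsNm[j]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' FlowCalibration: correlation flowmetry calibration
#'
#' Relates the decorrelation time `tau_c` of an A-line ensemble to the peak
#' flow speed through `v = kFlow / tau_c`. The constant is
#' instrument-specific and supplied by configuration.
#'
#' @slot kFlow calibration constant, mm/s * s (> 0).
#' @slot maxLagS maximum lag used when fitting the decorrelation curve, s.
#' @export
setClass("FlowCalibration", representation(
  kFlow = "numeric", maxLagS = "numeric"
))

setValidity("FlowCalibration", function(object) {
  msg <- character()
  if (length(object@kFlow) != 1L || object@kFlow <= 0)
    msg <- c(msg, "kFlow must be a single positive number")
  if (length(object@maxLagS) != 1L || object@maxLagS <= 0)
    msg <- c(msg, "maxLagS must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a FlowCalibration
#'
#' @param kFlow calibration constant (mm/s * s); the default 0.002 maps a
#'   decorrelation time of 2 ms to a peak speed of 1 mm/s.
#' @param maxLagS fitting horizon in seconds.
#' @return A [FlowCalibration-class] object.
#' @export
flowCalibration <- function(kFlow = 0.002, maxLagS = 0.004) {
  new("FlowCalibration", kFlow = as.numeric(kFlow), maxLagS = as.numeric(maxLagS))
}

#' MetabolismConfig: constants for regional oxygen metabolism
#'
#' @slot xi oxygen-binding capacity of hemoglobin, L O2 per gram hemoglobin
#'   (default 0.014).
#' @slot regionMassG mass of the imaged hemicortical region, grams.
#' @export
setClass("MetabolismConfig", representation(
  xi = "numeric", regionMassG = "numeric"
))

setValidity("MetabolismConfig", function(object) {
  msg <- character()
  if (length(object@xi) != 1L || object@xi <= 0)
    msg <- c(msg, "xi must be a single positive number")
  if (length(object@regionMassG) != 1L || object@regionMassG <= 0)
    msg <- c(msg, "regionMassG must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolismConfig
#'
#' @param xi oxygen-binding capacity of hemoglobin, L O2/g (default 0.014).
#' @param regionMassG mass of the imaged region in grams; the default 0.002 g
#'   stands for one neonatal hemicortical imaging region.
#' @return A [MetabolismConfig-class] object.
#' @export
metabolismConfig <- function(xi = 0.014, regionMassG = 0.002) {
  new("MetabolismConfig", xi = as.numeric(xi), regionMassG = as.numeric(regionMassG))
}

#' CalibrationCurve: H2O2 fluorescence calibration
#'
#' Ordinary least-squares line relating fluorescence increments to known
#' H2O2 additions, used to convert Amplex UltraRed fluorescence slopes into
#' absolute H2O2 emission rates.
#'
#' @slot additionsNmol known H2O2 additions, nmol.
#' @slot responsesAu fluorescence increments, a.u.
#' @slot slopeAuPerNmol fitted slope, a.u./nmol.
#' @slot interceptAu fitted intercept, a.u.
#' @slot r2 coefficient of determination.
#' @seealso [h2o2Calibration()]
#' @export
setClass("CalibrationCurve", representation(
  additionsNmol = "numeric", responsesAu = "numeric",
  slopeAuPerNmol = "numeric", interceptAu = "numeric", r2 = "numeric"
))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@additionsNmol) < 3L)
    msg <- c(msg, "at least 3 calibration additions required")
  if (length(object@additionsNmol) != length(object@responsesAu))
    msg <- c(msg, "additions and responses must have equal length")
  if (length(msg)) msg else TRUE
})

#' RegionHemodynamics: per-region oxygen metabolism summary
#'
#' Regional cerebral blood flow, oxygen extraction fraction and cerebral
#' metabolic rate of oxygen for one hemicortex, together with the arterial
#' and venous saturations and hemoglobin concentration they were derived
#' from. A `sv > sa` inconsistency is flagged, never silently clipped.
#'
#' @slot region `"ipsilateral"` or `"contralateral"`.
#' @slot cbfMl100gMin regional CBF, mL/100 g/min.
#' @slot oef oxygen extraction fraction.
#' @slot cmro2Ml100gMin CMRO2, mL O2/100 g/min.
#' @slot saO2 flow-weighted arterial sO2.
#' @slot svO2 flow-weighted venous sO2.
#' @slot chbGPerL flow-weighted hemoglobin concentration, g/L.
#' @slot nArteries,nVeins vessel counts.
#' @slot flags character vector of quality flags (e.g. `"negative OEF"`).
#' @export
setClass("RegionHemodynamics", representation(
  region = "character", cbfMl100gMin = "numeric", oef = "numeric",
  cmro2Ml100gMin = "numeric", saO2 = "numeric", svO2 = "numeric",
  chbGPerL = "numeric", nArteries = "integer", nVeins = "integer",
  flags = "character"
))
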