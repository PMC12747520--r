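#' @include AllClasses.R
NULL

#' Volumetric blood flow of one vessel
#'
#' Volumetric flux `pi * v * d^2 / 8` of a parabolic (Poiseuille) velocity
#' profile: mean speed `v / 2` times lumen area `pi * d^2 / 4`, where `v`
#' is the peak speed along the vascular axis and `d` the vessel diameter.
#' The factor 8 is the product of these two halves — it is not a typo to
#' "fix". Returned in microlitres per minute.
#'
#' @param peakSpeedMmS peak axial flow speed, mm/s (>= 0).
#' @param diameterUm vessel diameter, micrometres (> 0).
#' @return Flow in uL/min.
#' @examples
#' vesselFlow(1, 100)   # 0.2356 uL/min
#' @export
vesselFlow <- function(peakSpeedMmS, diameterUm) {
  if (any(peakSpeedMmS < 0)) stop("peak speed must be >= 0")
  if (any(diameterUm <= 0)) stop("diameter must be positive")
  ## (mm/s -> um/s: x1000); um^3/s -> uL/min: x60 / 1e9
  pi * (peakSpeedMmS * 1000) * diameterUm^2 / 8 * 60 / 1e9
}

.vesselTable <- function(vessels) {
  if (is.data.frame(vessels)) return(vessels)
  do.call(rbind, lapply(vessels, function(v) {
    if (is(v, "VesselSpec"))
      data.frame(id = v@id, diameter_um = v@diameterUm,
                 peak_speed_mm_s = v@peakSpeedMmS, so2 = v@so2,
                 vessel_class = v@vesselClass, region = v@region,
                 chb_g_per_L = v@chbGPerL, stringsAsFactors = FALSE)
    else as.data.frame(v, stringsAsFactors = FALSE)
  }))
}

#' Regional cerebral blood flow from feeding arteries
#'
#' Sum of the volumetric flows of the feeding arteries, normalized by the
#' mass of the imaged region: `CBF = sum(flow) / regionMassG * 100`, in
#' mL/100 g/min.
#'
#' @param arteries data.frame (or list of [VesselSpec-class]) with columns
#'   `peak_speed_mm_s` and `diameter_um`; at least one artery.
#' @param cfg a [MetabolismConfig-class].
#' @return CBF in mL/100 g/min.
#' @examples
#' a <- data.frame(peak_speed_mm_s = c(1, 1), diameter_um = c(100, 141.42))
#' regionCbf(a, metabolismConfig(regionMassG = 0.002))
#' @export
regionCbf <- function(arteries, cfg) {
  a <- .vesselTable(arteries)
  if (is.null(a) || nrow(a) == 0L) stop("at least one feeding artery required")
  flowsUl <- vesselFlow(a$peak_speed_mm_s, a$diameter_um)
  sum(flowsUl) / 1000 / cfg@regionMassG * 100
}

#' Regional oxygen extraction fraction
#'
#' Arterial and venous saturations are aggregated over the feeding arteries
#' and draining veins (flow-weighted by default, mirroring mass balance;
#' uniform weighting available for sensitivity checks), then
#' `OEF = (saO2 - svO2) / saO2`. A venous saturation exceeding the arterial
#' one yields a flagged, unclipped negative OEF.
#'
#' @param arteries,veins data.frames (or lists of [VesselSpec-class]) with
#'   `so2` set and, for flow weighting, `peak_speed_mm_s` and `diameter_um`.
#' @param weighting `"flow"` or `"uniform"`.
#' @return List with `oef`, `saO2`, `svO2` and a character vector `flags`.
#' @examples
#' regionOef(data.frame(so2 = 0.96, peak_speed_mm_s = 2, diameter_um = 60),
#'           data.frame(so2 = 0.72, peak_speed_mm_s = 1, diameter_um = 80))
#' @export
regionOef <- function(arteries, veins, weighting = c("flow", "uniform")) {
  weighting <- match.arg(weighting)
  a <- .vesselTable(arteries); v <- .vesselTable(veins)
  if (is.null(a) || nrow(a) == 0L || is.null(v) || nrow(v) == 0L)
    stop("at least one artery and one vein required")
  if (anyNA(a$so2) || anyNA(v$so2)) stop("all vessels must have so2 set")
  wmean <- function(tb) {
    w <- if (weighting == "flow")
      vesselFlow(tb$peak_speed_mm_s, tb$diameter_um) else rep(1, nrow(tb))
    if (sum(w) == 0) w <- rep(1, nrow(tb))    # all-static vessels
    sum(w * tb$so2) / sum(w)
  }
  saO2 <- wmean(a); svO2 <- wmean(v)
  if (saO2 == 0) stop("arterial sO2 is zero; OEF undefined")
  flags <- character(0)
  if (svO2 > saO2) flags <- "negative OEF"
  list(oef = (saO2 - svO2) / saO2, saO2 = saO2, svO2 = svO2, flags = flags)
}

#' Regional cerebral metabolic rate of oxygen
#'
#' `CMRO2 = xi * C_Hb * saO2 * OEF * CBF`. With `xi` in L O2 per gram
#' hemoglobin and `C_Hb` in g/L blood, the product `xi * C_Hb` is the
#' oxygen content of fully saturated blood in mL O2 per mL blood, so the
#' result carries CBF's mL/100 g/min scale as mL O2/100 g/min.
#'
#' @param cbf regional CBF, mL/100 g/min.
#' @param oef oxygen extraction fraction.
#' @param saO2 arterial oxygen saturation.
#' @param chbGPerL total hemoglobin concentration, g/L.
#' @param cfg a [MetabolismConfig-class] (provides `xi`).
#' @return CMRO2 in mL O2/100 g/min.
#' @examples
#' regionCmro2(30, 0.3, 0.9, 100, metabolismConfig())   # 11.34
#' @export
regionCmro2 <- function(cbf, oef, saO2, chbGPerL, cfg) {
  if (any(c(cbf, oef, saO2, chbGPerL) < 0))
    stop("all CMRO2 factors must be >= 0")
  cfg@xi * chbGPerL * saO2 * oef * cbf
}

#' Full per-region hemodynamics from measured vessels
#'
#' Composes [regionCbf()], [regionOef()] and [regionCmro2()] for one
#' hemicortical region from a table of measured vessels, flow-weighting the
#' hemoglobin concentration over the feeding arteries.
#'
#' @param vessels data.frame with columns `diameter_um`, `peak_speed_mm_s`,
#'   `so2`, `vessel_class`, `chb_g_per_L` (or a list of
#'   [VesselSpec-class]).
#' @param cfg a [MetabolismConfig-class].
#' @param region region label for the result.
#' @param weighting saturation weighting, see [regionOef()].
#' @return A [RegionHemodynamics-class].
#' @examples
#' scn <- makeScene(defaultSceneConfig(), seed = 1)
#' regionHemodynamics(sceneVessels(scn), metabolismConfig())
#' @export
regionHemodynamics <- function(vessels, cfg, region = "ipsilateral",
                               weighting = "flow") {
  tb <- .vesselTable(vessels)
  art <- tb[tb$vessel_class == "artery", , drop = FALSE]
  vn <- tb[tb$vessel_class == "vein", , drop = FALSE]
  cbf <- regionCbf(art, cfg)
  ox <- regionOef(art, vn, weighting)
  wa <- vesselFlow(art$peak_speed_mm_s, art$diameter_um)
  if (sum(wa) == 0) wa <- rep(1, nrow(art))
  chb <- if ("chb_g_per_L" %in% names(art)) sum(wa * art$chb_g_per_L) / sum(wa)
         else NA_real_
  cmro2 <- regionCmro2(cbf, max(ox$oef, 0), ox$saO2, chb, cfg)
  new("RegionHemodynamics", region = region, cbfMl100gMin = cbf,
      oef = ox$oef, cmro2Ml100gMin = cmro2, saO2 = ox$saO2, svO2 = ox$svO2,
      chbGPerL = chb, nArteries = nrow(art), nVeins = nrow(vn),
      flags = ox$flags)
}

#' Percentage of baseline, rounded half-up
#'
#' `round_half_up(100 * value / baseline)` as an integer percent — the
#' convention behind narrative statements like "86% of the baseline".
#'
#' @param value measured value.
#' @param baseline baseline value (> 0).
#' @return Integer percent.
#' @examples
#' baselinePercent(33.18, 38.37)   # 86
#' baselinePercent(22.65, 38.37)   # 59
#' @export
baselinePercent <- function(value, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  as.integer(floor(100 * value / baseline + 0.5))
}
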