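#' @include synthRender.R
NULL

#' Quantify every vessel of a rendered phantom scene
#'
#' End-to-end single-vessel quantification: render the dual-wavelength
#' image, segment each vessel inside its padded ROI, measure diameter from
#' perpendicular mask chords, saturation by amplitude-weighted spectral
#' unmixing, hemoglobin concentration from the unmixed total (scaled by the
#' instrument calibration `kChb`), and peak flow speed from a synthetic
#' A-line ensemble of the vessel. Vessel classes are taken from the scene's
#' ground-truth labels (threshold classification is available separately
#' via [classifyVessels()]).
#'
#' @param scene a [PhantomScene-class].
#' @param ext an [ExtinctionTable-class].
#' @param cal a [FlowCalibration-class].
#' @param kChb concentration calibration, g/L per relative-concentration
#'   unit. The default inverts the render's default gain, standing for a
#'   calibrated instrument.
#' @param dtS,nLines A-line ensemble parameters (see
#'   [renderAlineEnsemble()]).
#' @param ensembleSnrDb noise level of the A-line ensembles; defaults to
#'   the scene's SNR.
#' @param minFragmentPx,pad segmentation parameters (see
#'   [segmentVessel()] and [sceneVesselRoi()]).
#' @return data.frame with one row per vessel: `id`, `diameter_um`,
#'   `peak_speed_mm_s`, `so2`, `chb_g_per_L`, `vessel_class`, `region`.
#' @examples
#' scn <- makeScene(defaultSceneConfig(), seed = 1)
#' tab <- quantifyScene(scn)
#' regionHemodynamics(tab, metabolismConfig())
#' @export
quantifyScene <- function(scene, ext = hbExtinctionTable(),
                          cal = flowCalibration(), kChb = NULL,
                          dtS = 1e-4, nLines = 100L,
                          ensembleSnrDb = scene@noiseSnrDb,
                          minFragmentPx = 10L, pad = 0.2) {
  E <- .extMatrix(ext, c(532, 558))
  if (is.null(kChb)) kChb <- sum(E[1, ]) / 2       # inverse of default gain
  img <- renderDualWavelength(scene, ext)
  a532 <- channelMap(img, 532)
  sm <- so2Map(img, ext)
  rows <- lapply(seq_along(scene@vessels), function(i) {
    v <- scene@vessels[[i]]
    msk <- segmentVessel(a532, sceneVesselRoi(scene, i, pad), minFragmentPx)
    path <- vesselCenterline(msk)
    dia <- vesselDiameter(msk, path)
    so2 <- vesselSo2(img, msk, ext)
    px <- maskPixels(msk)
    w <- img@channels[[1]][px]
    chb <- kChb * sum(w * sm$relChb[px], na.rm = TRUE) / sum(w)
    ens <- renderAlineEnsemble(v, dtS, nLines, cal,
                               seed = scene@seed + 7919L * i,
                               snrDb = ensembleSnrDb)
    sp <- as.numeric(ensembleSpeed(ens, cal))
    data.frame(id = v@id, diameter_um = dia, peak_speed_mm_s = sp,
               so2 = so2, chb_g_per_L = chb, vessel_class = v@vesselClass,
               region = v@region, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
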