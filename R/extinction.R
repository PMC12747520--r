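#' @include AllClasses.R
NULL

#' Default hemoglobin extinction table for 532/558 nm oximetry
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the two
#' excitation wavelengths of the dual-wavelength design: 532 nm (the pump
#' line, close to a hemoglobin isosbestic point, so its amplitude tracks
#' total hemoglobin concentration) and 558 nm (the stimulated-Raman-shifted
#' line, where deoxyhemoglobin absorbs substantially more than
#' oxyhemoglobin, providing the saturation contrast).
#'
#' The shipped values are approximate figures in the spirit of the standard
#' tabulated hemoglobin absorption spectra and are configuration inputs, not
#' measurements: replace them with your preferred compilation via the
#' arguments. All phantom-recovery workflows use one table for both the
#' forward render and the inversion, so recovered saturations do not depend
#' on the compilation chosen.
#'
#' @param wavelengthsNm wavelengths in nanometres.
#' @param epsOxy HbO2 molar extinction at those wavelengths (cm^-1 M^-1).
#' @param epsDeoxy Hb molar extinction at those wavelengths (cm^-1 M^-1).
#' @return An [ExtinctionTable-class] object.
#' @examples
#' ext <- hbExtinctionTable()
#' ext
#' @export
hbExtinctionTable <- function(wavelengthsNm = c(532, 558),
                              epsOxy = c(44500, 28000),
                              epsDeoxy = c(41000, 52000)) {
  new("ExtinctionTable", wavelengthsNm = as.numeric(wavelengthsNm),
      epsOxy = as.numeric(epsOxy), epsDeoxy = as.numeric(epsDeoxy))
}

## 2x2 extinction matrix for a wavelength pair; rows = wavelengths,
## columns = (HbO2, Hb)
.extMatrix <- function(ext, wl) {
  i <- match(wl, ext@wavelengthsNm)
  if (anyNA(i))
    stop("wavelength(s) ", paste(wl[is.na(i)], collapse = ", "),
         " nm missing from extinction table")
  E <- cbind(ext@epsOxy[i], ext@epsDeoxy[i])
  if (abs(det(E)) < .Machine$double.eps * 100)
    stop("extinction system is singular for wavelengths ",
         paste(wl, collapse = ", "))
  E
}
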