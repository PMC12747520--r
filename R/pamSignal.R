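#' @include AllClasses.R
NULL

#' Hilbert envelope of an A-line
#'
#' Magnitude of the analytic signal, computed in the frequency domain
#' (positive frequencies doubled, negative zeroed). This is the standard
#' envelope detector for photoacoustic A-line signals; the result is
#' nonnegative and has the length of the input. Values within about one
#' carrier period of either end carry the usual analytic-signal edge
#' artifact and should not be relied upon.
#'
#' @param x numeric vector, length >= 8, finite values.
#' @return Nonnegative numeric vector of the same length.
#' @examples
#' t <- seq(0, 1, length.out = 256)
#' env <- envelope(sin(2 * pi * 40 * t))
#' @export
envelope <- function(x) {
  if (!is.numeric(x) || length(x) < 8L) stop("A-line must be numeric, length >= 8")
  if (any(!is.finite(x))) stop("A-line must be finite")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Project an A-line raster to an amplitude map
#'
#' Computes the Hilbert envelope of every A-line in a rectangular raster and
#' takes its peak, the standard maximum-amplitude projection that turns a
#' volumetric PAM scan into the 2-D vascular map used by segmentation.
#'
#' @param scan 3-D numeric array `n_rows x n_cols x n_samples`: one A-line
#'   per raster position.
#' @param wavelengthNm optical wavelength of the scan, nanometres.
#' @param pixelSpacingUm pixel spacing in micrometres (length 1 or 2).
#' @return An [AmplitudeMap-class].
#' @export
amplitudeMap <- function(scan, wavelengthNm, pixelSpacingUm) {
  if (!is.array(scan) || length(dim(scan)) != 3L)
    stop("scan must be a 3-D array (rows x cols x samples); ragged rasters are not supported")
  d <- dim(scan)
  if (d[3] < 8L) stop("A-lines must have length >= 8")
  flat <- matrix(scan, d[1] * d[2], d[3])       # one A-line per row
  n <- d[3]
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  F <- stats::mvfft(t(flat)) * h
  env <- Mod(stats::mvfft(F, inverse = TRUE) / n)
  vals <- matrix(apply(env, 2L, max), d[1], d[2])
  amplitudeMapFromMatrix(vals, pixelSpacingUm, wavelengthNm)
}

#' Relative hemoglobin-concentration map from the 532 nm channel
#'
#' The statistical channel of the multi-parametric analysis: at the
#' near-isosbestic 532 nm wavelength the amplitude tracks total hemoglobin
#' regardless of saturation, so a single user-supplied calibration constant
#' converts amplitude to concentration, `C_Hb = kChb * amplitude`, clipped
#' at zero. The calibration is a configuration input (e.g. from one pixel
#' of known concentration), not computed by the package.
#'
#' @param isoMap an [AmplitudeMap-class] taken at the near-isosbestic
#'   wavelength (532 nm).
#' @param kChb calibration constant, g/L per amplitude unit (> 0).
#' @return Numeric matrix of hemoglobin concentration in g/L.
#' @export
chbMap <- function(isoMap, kChb) {
  if (!is(isoMap, "AmplitudeMap")) stop("isoMap must be an AmplitudeMap")
  if (length(kChb) != 1L || !is.finite(kChb) || kChb <= 0)
    stop("kChb must be a single positive number")
  pmax(kChb * mapValues(isoMap), 0)
}
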