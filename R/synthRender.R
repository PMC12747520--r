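#' @include synthScene.R
NULL

## Separable Gaussian blur with zero padding outside the field (the
## background carries no absorber). sigmaPx may differ per axis.
.gaussBlur <- function(m, sigmaPx) {
  blur1 <- function(mat, sigma, along) {
    if (sigma <= 0) return(mat)
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    k <- k / sum(k)
    out <- matrix(0, nrow(mat), ncol(mat))
    for (j in seq(-r, r)) {
      w <- k[j + r + 1L]
      if (along == "row") {            # shift across rows (y)
        src <- seq_len(nrow(mat)) + j
        ok <- src >= 1L & src <= nrow(mat)
        out[ok, ] <- out[ok, ] + w * mat[src[ok], ]
      } else {                         # shift across columns (x)
        src <- seq_len(ncol(mat)) + j
        ok <- src >= 1L & src <= ncol(mat)
        out[, ok] <- out[, ok] + w * mat[, src[ok]]
      }
    }
    out
  }
  m <- blur1(m, sigmaPx[2], "row")
  blur1(m, sigmaPx[1], "col")
}

#' Render the dual-wavelength forward model of a phantom scene
#'
#' Forward optical model of the spectroscopic channel: at every pixel the
#' photoacoustic amplitude at wavelength lambda is
#' `gain * C_Hb * (sO2 * eps_HbO2(lambda) + (1 - sO2) * eps_Hb(lambda))`,
#' blurred by a Gaussian point-spread function of the scene's FWHM and
#' perturbed by additive Gaussian noise at the scene's SNR (in dB, relative
#' to the peak noiseless amplitude; negative values are clipped to zero).
#' A noiseless render is exactly invertible by [unmix()] with the same
#' extinction table.
#'
#' @param scene a [PhantomScene-class].
#' @param ext an [ExtinctionTable-class] containing both wavelengths.
#' @param wavelengthsNm the two wavelengths to render (default 532/558 nm).
#' @param seed seed for the noise draw; defaults to the scene seed.
#' @param gain scalar instrument gain (a.u. per g/L per unit extinction
#'   mixture). The default `2 / (eps_HbO2 + eps_Hb)` at the first wavelength
#'   makes vessel amplitudes of order `C_Hb`.
#' @return A [DualWavelengthImage-class].
#' @examples
#' scn <- makeScene(defaultSceneConfig(noiseSnrDb = Inf), seed = 1)
#' img <- renderDualWavelength(scn, hbExtinctionTable())
#' @export
renderDualWavelength <- function(scene, ext, wavelengthsNm = c(532, 558),
                                 seed = scene@seed, gain = NULL) {
  E <- .extMatrix(ext, wavelengthsNm)   # errors if a wavelength is missing
  if (is.null(gain)) gain <- 2 / sum(E[1, ])
  ras <- rasterizeScene(scene)
  inV <- ras$label > 0L
  chb <- ifelse(inV, ras$chb, 0)
  so2 <- ifelse(inV, ras$so2, 0)
  sigmaPx <- scene@psfFwhmUm / 2.354820045 / scene@pixelSpacingUm
  channels <- lapply(1:2, function(i) {
    amp <- gain * chb * (so2 * E[i, 1] + (1 - so2) * E[i, 2])
    .gaussBlur(amp, sigmaPx)
  })
  if (is.finite(scene@noiseSnrDb)) {
    sd <- max(unlist(lapply(channels, max))) / 10^(scene@noiseSnrDb / 20)
    channels <- .withSeed(seed, lapply(channels, function(m)
      pmax(m + matrix(stats::rnorm(length(m), sd = sd), nrow(m), ncol(m)), 0)))
  }
  new("DualWavelengthImage", channels = channels,
      wavelengthsNm = as.numeric(wavelengthsNm),
      pixelSpacingUm = scene@pixelSpacingUm)
}

#' Render an A-line ensemble with flow-encoded decorrelation
#'
#' Forward model of the correlation channel. An ensemble of `nLines`
#' A-lines is constructed so that the zero-normalized correlation between
#' lines separated by lag `tau` is exactly
#' `exp(-(tau / tau_c)^2)` with `tau_c = kFlow / v` for peak speed `v > 0`;
#' a static vessel (`v = 0`) yields identical lines. The construction is
#' exact, not asymptotic: the line matrix is a correlation-shaping transform
#' of an orthonormal zero-mean basis, so the empirical Pearson correlations
#' reproduce the Gaussian decay to numerical precision before noise is
#' added. Additive Gaussian noise at `snrDb` (relative to the line RMS)
#' models detection noise.
#'
#' @param vessel a [VesselSpec-class], or a single nonnegative peak speed
#'   in mm/s.
#' @param dtS laser repetition interval in seconds (> 0).
#' @param nLines number of A-lines (>= 16).
#' @param cal a [FlowCalibration-class].
#' @param seed integer seed; the ensemble is a pure function of
#'   `(arguments, seed)`.
#' @param nSamples samples per A-line (must exceed `nLines`).
#' @param snrDb additive noise level in dB; `Inf` (default) is noise-free.
#' @return An [AlineEnsemble-class] whose `truth` records the generating
#'   speed and decorrelation time.
#' @examples
#' ens <- renderAlineEnsemble(1.0, dtS = 1e-4, nLines = 64,
#'                            cal = flowCalibration(), seed = 3)
#' @export
renderAlineEnsemble <- function(vessel, dtS, nLines, cal, seed,
                                nSamples = 256L, snrDb = Inf) {
  v <- if (is(vessel, "VesselSpec")) vessel@peakSpeedMmS else as.numeric(vessel)
  if (length(dtS) != 1L || !is.finite(dtS) || dtS <= 0)
    stop("dtS must be a single positive number")
  if (nLines < 16L) stop("at least 16 A-lines required")
  if (nSamples <= nLines)
    stop("nSamples must exceed nLines for an exact correlation construction")
  if (v < 0) stop("peak speed must be >= 0")
  tauC <- if (v > 0) cal@kFlow / v else Inf
  lines <- .withSeed(seed, {
    if (v == 0) {
      base <- stats::rnorm(nSamples)
      L <- matrix(rep(base, each = nLines), nLines, nSamples)
    } else {
      lagGrid <- abs(outer(seq_len(nLines), seq_len(nLines), "-")) * dtS
      R <- exp(-(lagGrid / tauC)^2)
      eg <- eigen(R, symmetric = TRUE)
      Lh <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
      G <- matrix(stats::rnorm(nSamples * nLines), nSamples, nLines)
      G <- sweep(G, 2L, colMeans(G))          # columns orthogonal to 1
      Q <- qr.Q(qr(G))                        # orthonormal, zero-mean columns
      L <- Lh %*% t(Q)
    }
    if (is.finite(snrDb)) {
      sd <- sqrt(mean(L^2)) / 10^(snrDb / 20)
      L <- L + matrix(stats::rnorm(length(L), sd = sd), nrow(L), ncol(L))
    }
    L
  })
  new("AlineEnsemble", lines = lines, dtS = as.numeric(dtS),
      truth = list(peak_speed_mm_s = v, tau_c_s = tauC, k_flow = cal@kFlow,
                   snr_db = snrDb, seed = as.integer(seed)))
}
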