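#' @include AllClasses.R
NULL

#' Decorrelation curve of an A-line ensemble
#'
#' For every lag `l * dt` up to `maxLag`, the mean zero-normalized
#' (Pearson) cross-correlation coefficient over all line pairs separated by
#' that lag. Lag 0 is 1 by construction. Flow moves scatterers between
#' laser shots, so faster flow decorrelates the ensemble at shorter lags.
#'
#' @param e an [AlineEnsemble-class].
#' @param maxLag largest lag in line counts (default `n_lines / 4`, so that
#'   every lag still averages many pairs).
#' @return List with numeric vectors `lagsS` and `correlation`.
#' @export
decorrelationCurve <- function(e, maxLag = NULL) {
  L <- ensembleLines(e)
  n <- nrow(L)
  if (is.null(maxLag)) maxLag <- max(4L, floor(n / 4))
  maxLag <- min(maxLag, n - 2L)
  sds <- apply(L, 1L, stats::sd)
  if (any(sds == 0)) stop("zero-variance A-line in ensemble")
  C <- stats::cor(t(L))
  corr <- vapply(0:maxLag, function(l) {
    if (l == 0L) return(1)
    i <- seq_len(n - l)
    mean(C[cbind(i, i + l)])
  }, numeric(1))
  list(lagsS = (0:maxLag) * e@dtS, correlation = corr)
}

#' Fit peak flow speed from a decorrelation curve
#'
#' Least-squares fit of the single-parameter Gaussian decay
#' `rho(tau) = a * exp(-(tau / tau_c)^2)` over lags below the calibration's
#' fitting horizon, followed by the linear speed map
#' `v = kFlow / tau_c`. The amplitude `a` absorbs the uniform correlation
#' attenuation that detection noise causes at all nonzero lags; on
#' noiseless data it fits to 1 and the decay parameter is recovered
#' exactly. The fit is initialized deterministically from the
#' log-linearized model (no random restarts). When no decorrelation is
#' detectable — fitted `tau_c` beyond 10x the largest usable lag — a speed
#' of 0 is returned rather than a divergent estimate.
#'
#' @param lagsS numeric vector of lags in seconds (lag 0 allowed; it is
#'   excluded from the fit).
#' @param correlation corresponding mean correlation coefficients.
#' @param cal a [FlowCalibration-class].
#' @return Peak speed in mm/s, with attributes `tauCS` (fitted
#'   decorrelation time, seconds) and `fitRmse`.
#' @examples
#' cal <- flowCalibration(kFlow = 0.002)
#' tau <- (1:10) * 1e-4
#' fitSpeed(tau, exp(-(tau / 0.002)^2), cal)     # 1 mm/s
#' @export
fitSpeed <- function(lagsS, correlation, cal) {
  keep <- lagsS > 0 & lagsS <= cal@maxLagS & is.finite(correlation)
  tau <- lagsS[keep]; rho <- correlation[keep]
  if (length(tau) < 4L)
    stop("need at least 4 nonzero lags within the fitting horizon")
  maxLagUsed <- max(tau)
  pos <- rho > 0.05
  noFlow <- function() {
    out <- 0
    attr(out, "tauCS") <- Inf
    attr(out, "fitRmse") <- sqrt(mean((rho - 1)^2))
    out
  }
  if (sum(pos) < 3L) pos <- rho > 0            # heavily decorrelated input
  if (sum(pos) < 3L) stop("fit failure: fewer than 3 usable correlation points")
  ## log-linearization: -log(rho) = -log(a) + tau^2 / tauC^2
  lf <- stats::lm(I(-log(rho[pos])) ~ I(tau[pos]^2))
  b <- stats::coef(lf)[[2]]
  tauC0 <- if (b > 0) 1 / sqrt(b) else Inf
  if (!is.finite(tauC0) || tauC0 > 10 * maxLagUsed) return(noFlow())
  a0 <- min(max(exp(-stats::coef(lf)[[1]]), 0.2), 1.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(rho ~ a * exp(-(tau / tc)^2),
                      start = list(a = a0, tc = tauC0),
                      lower = c(1e-3, 1e-12), upper = c(2, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit failure (non-convergent): ", conditionMessage(e),
           sprintf(" [init a=%.3g, tauC=%.3g s, %d points]",
                   a0, tauC0, length(tau))))
  tauC <- stats::coef(fit)[["tc"]]
  if (tauC > 10 * maxLagUsed) return(noFlow())
  out <- cal@kFlow / tauC
  attr(out, "tauCS") <- tauC
  attr(out, "fitRmse") <- sqrt(mean(stats::residuals(fit)^2))
  out
}

#' Peak flow speed of one vessel from its A-line ensemble
#'
#' Convenience composition of [decorrelationCurve()] and [fitSpeed()].
#'
#' @param e an [AlineEnsemble-class].
#' @param cal a [FlowCalibration-class].
#' @return Peak speed in mm/s (see [fitSpeed()] for attributes).
#' @export
ensembleSpeed <- function(e, cal) {
  dc <- decorrelationCurve(e)
  fitSpeed(dc$lagsS, dc$correlation, cal)
}
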