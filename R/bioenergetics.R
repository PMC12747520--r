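#' @include AllClasses.R
NULL

.eventTime <- function(trace, label) {
  ev <- traceEvents(trace)
  i <- which(ev$label == label)
  if (!length(i)) NA_real_ else ev$time_s[i[1]]
}

## OLS slope + SSE over index range via running sums (exact, O(1) per split).
.cumFit <- function(t, y) {
  list(sx = cumsum(t), sy = cumsum(y), sxx = cumsum(t * t),
       sxy = cumsum(t * y), syy = cumsum(y * y))
}
.sseRange <- function(cs, i, j) {      # SSE of OLS line on samples i..j
  n <- j - i + 1
  at <- function(v) v[j] - if (i > 1) v[i - 1] else 0
  sx <- at(cs$sx); sy <- at(cs$sy); sxx <- at(cs$sxx)
  sxy <- at(cs$sxy); syy <- at(cs$syy)
  vt <- sxx - sx^2 / n
  cv <- sxy - sx * sy / n
  (syy - sy^2 / n) - if (vt > 0) cv^2 / vt else 0
}

#' Label respiration-state windows of a Clark-electrode trace
#'
#' Splits the trace into the classical respiration states: `State2` after
#' substrate, `State3` (ADP-stimulated phosphorylating respiration) after
#' the ADP addition, `State4` (resting) after ADP exhaustion, and
#' `Uncoupled` after the protonophore (DNP). Windows start `bufferS`
#' seconds after their event to skip mixing/settling transients. The
#' State 3 to State 4 boundary is taken from an `adp_exhausted` annotation
#' when present; otherwise it is detected as the best two-segment linear
#' changepoint of O2 vs time between the ADP addition and the next event —
#' the point of the largest drop in consumption slope magnitude. Without an
#' ADP event only a basal window is returned.
#'
#' @param trace a [RespiroTrace-class].
#' @param bufferS settling time excluded after each event, seconds.
#' @return data.frame with columns `state`, `start_s`, `end_s` (half-open
#'   windows).
#' @examples
#' tr <- synthRespiroTrace(respiroParams())
#' segmentStates(tr)
#' @export
segmentStates <- function(trace, bufferS = 10) {
  stopifnot(bufferS >= 0)
  t <- traceTime(trace)
  y <- traceValues(trace)
  tEnd <- max(t) + (t[2] - t[1])
  tSub <- .eventTime(trace, "substrate")
  tAdp <- .eventTime(trace, "ADP")
  tDnp <- .eventTime(trace, "DNP")
  tExh <- .eventTime(trace, "adp_exhausted")
  checkWin <- function(w) {
    if (sum(t >= w$start_s & t < w$end_s) < 3L)
      stop(sprintf("window '%s' has fewer than 3 samples", w$state))
    w
  }
  if (is.na(tAdp)) {
    start <- if (is.na(tSub)) bufferS else tSub + bufferS
    return(checkWin(data.frame(state = "basal", start_s = start, end_s = tEnd)))
  }
  out <- list()
  if (!is.na(tSub))
    out$s2 <- data.frame(state = "State2", start_s = tSub + bufferS, end_s = tAdp)
  nextEv <- if (!is.na(tDnp)) tDnp else tEnd
  if (is.na(tExh)) {
    ## changepoint: minimal two-segment SSE over the post-ADP stretch
    idx <- which(t >= tAdp + bufferS & t < nextEv)
    if (length(idx) < 6L) stop("post-ADP window too short for changepoint detection")
    cs <- .cumFit(t[idx], y[idx])
    m <- length(idx)
    splits <- 3:(m - 3)
    sse <- vapply(splits, function(k)
      .sseRange(cs, 1L, k) + .sseRange(cs, k + 1L, m), numeric(1))
    tExh <- t[idx[splits[which.min(sse)]]]
  }
  out$s3 <- data.frame(state = "State3", start_s = tAdp + bufferS, end_s = tExh)
  out$s4 <- data.frame(state = "State4", start_s = tExh + bufferS, end_s = nextEv)
  if (!is.na(tDnp))
    out$un <- data.frame(state = "Uncoupled", start_s = tDnp + bufferS, end_s = tEnd)
  do.call(rbind, lapply(out, checkWin))
}

#' Oxygen consumption rate over a trace window
#'
#' Least-squares slope of chamber O2 concentration over the window,
#' converted to the conventional per-protein rate:
#' `OCR = -slope (nmol/mL/min) * chamberMl / proteinMg`, in nmol O2 per mg
#' mitochondrial protein per minute. A rising O2 trend (negative
#' consumption) is reported as 0 with attribute `flag = "rising O2"`.
#'
#' @param trace a [RespiroTrace-class].
#' @param window numeric `c(start_s, end_s)` or a one-row window from
#'   [segmentStates()].
#' @return OCR in nmol O2/mg/min.
#' @examples
#' tr <- synthRespiroTrace(respiroParams(annotateExhaustion = TRUE))
#' w <- segmentStates(tr)
#' ocr(tr, w[w$state == "State3", ])
#' @export
ocr <- function(trace, window) {
  if (is.data.frame(window)) window <- c(window$start_s[1], window$end_s[1])
  t <- traceTime(trace); y <- traceValues(trace)
  sel <- t >= window[1] & t < window[2]
  if (sum(sel) < 3L) stop("degenerate window: fewer than 3 samples")
  slopePerMin <- unname(stats::coef(stats::lm(y[sel] ~ t[sel]))[2]) * 60
  out <- -slopePerMin * trace@chamberMl / trace@proteinMg
  if (out < 0) {
    out <- 0
    attr(out, "flag") <- "rising O2"
  }
  out
}

#' Respiratory control ratio
#'
#' Ratio of the State 3 (ADP-stimulated) to the State 4 (resting)
#' respiration rate; the classical index of oxidative-phosphorylation
#' coupling.
#'
#' @param state3Ocr,state4Ocr OCRs in nmol O2/mg/min; `state4Ocr` > 0.
#' @return Dimensionless ratio.
#' @examples
#' rcr(100, 25)   # 4
#' @export
rcr <- function(state3Ocr, state4Ocr) {
  if (state4Ocr <= 0) stop("State 4 OCR must be positive")
  as.numeric(state3Ocr) / as.numeric(state4Ocr)
}

#' H2O2 fluorescence calibration curve
#'
#' Ordinary least-squares line (with intercept, absorbing dye background)
#' of fluorescence response against sequential known H2O2 additions.
#'
#' @param additionsNmol known H2O2 amounts, nmol; >= 3 distinct values.
#' @param responsesAu fluorescence increments, a.u.
#' @return A [CalibrationCurve-class].
#' @examples
#' h2o2Calibration(c(0.1, 0.2, 0.4), c(10, 20, 40))
#' @export
h2o2Calibration <- function(additionsNmol, responsesAu) {
  if (length(additionsNmol) < 3L || length(responsesAu) != length(additionsNmol))
    stop("at least 3 paired calibration additions required")
  if (stats::sd(additionsNmol) == 0) stop("calibration additions have zero variance")
  fit <- stats::lm(responsesAu ~ additionsNmol)
  sst <- sum((responsesAu - mean(responsesAu))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  new("CalibrationCurve", additionsNmol = as.numeric(additionsNmol),
      responsesAu = as.numeric(responsesAu),
      slopeAuPerNmol = unname(stats::coef(fit)[2]),
      interceptAu = unname(stats::coef(fit)[1]), r2 = r2)
}

#' Calibrated H2O2 emission rate from an Amplex trace
#'
#' Least-squares fluorescence slope over the pre-rotenone recording window,
#' converted through the calibration slope and protein mass:
#' `rate = slope (a.u./min) / slopeAuPerNmol / proteinMg`, in
#' nmol H2O2/mg/min.
#'
#' @param trace a [FluoroTrace-class] of kind `"amplex"`.
#' @param cal a [CalibrationCurve-class] with positive slope.
#' @param proteinMg mitochondrial protein in the cuvette, mg.
#' @return Emission rate in nmol H2O2/mg/min.
#' @export
h2o2Rate <- function(trace, cal, proteinMg) {
  if (trace@kind != "amplex") stop("h2o2Rate requires an amplex trace")
  if (cal@slopeAuPerNmol <= 0) stop("calibration slope must be positive")
  stopifnot(proteinMg > 0)
  tRot <- .eventTime(trace, "rotenone")
  if (is.na(tRot)) stop("missing rotenone event")
  t <- traceTime(trace); y <- traceValues(trace)
  sel <- t < tRot
  if (sum(sel) < 3L) stop("pre-rotenone segment has fewer than 3 samples")
  slopeAuMin <- unname(stats::coef(stats::lm(y[sel] ~ t[sel]))[2]) * 60
  slopeAuMin / cal@slopeAuPerNmol / proteinMg
}

#' Initial MitoSOX superoxide rate
#'
#' Least-squares fluorescence slope over the initial window (default
#' 300 s), in a.u./min — the initial linear increase rate used because the
#' kinetics saturate later in the recording.
#'
#' @param trace a [FluoroTrace-class] of kind `"mitosox"`.
#' @param windowS initial window length, seconds.
#' @return Rate in a.u./min.
#' @export
mitosoxRate <- function(trace, windowS = 300) {
  if (trace@kind != "mitosox") stop("mitosoxRate requires a mitosox trace")
  t <- traceTime(trace); y <- traceValues(trace)
  if (windowS > max(t)) stop("window longer than trace")
  sel <- t <= windowS
  if (sum(sel) < 3L) stop("window has fewer than 3 samples")
  unname(stats::coef(stats::lm(y[sel] ~ t[sel]))[2]) * 60
}

#' RH-123 quench depth and CCCP release
#'
#' Membrane-potential read-outs from a rhodamine-123 quenching trace:
#' `deltaF` is the mean of the 300 s baseline minus the post-substrate
#' quenched plateau (estimated as the mean of the last third of the
#' segment, robust to the settling transient); `cccpRelease` is the
#' post-CCCP plateau minus the quenched plateau when a CCCP event is
#' present (`NA` otherwise).
#'
#' @param trace a [FluoroTrace-class] of kind `"rh123"` whose substrate
#'   event falls at or after 300 s.
#' @return List with `deltaFAu` and `cccpReleaseAu`.
#' @examples
#' rh123Delta(synthFluoroTrace(fluoroParams("rh123")))
#' @export
rh123Delta <- function(trace) {
  if (trace@kind != "rh123") stop("rh123Delta requires an rh123 trace")
  t <- traceTime(trace); y <- traceValues(trace)
  tSub <- .eventTime(trace, "substrate")
  if (is.na(tSub) || tSub < 300 || max(t) < 300)
    stop("baseline shorter than 300 s")
  tCccp <- .eventTime(trace, "cccp")
  segEnd <- if (is.na(tCccp)) max(t) + (t[2] - t[1]) else tCccp
  baseline <- mean(y[t < 300])
  lastThird <- function(a, b) {
    sel <- t >= a + 2 / 3 * (b - a) & t < b
    if (sum(sel) < 3L) stop("plateau segment too short")
    mean(y[sel])
  }
  quench <- lastThird(tSub, segEnd)
  release <- if (is.na(tCccp)) NA_real_
             else lastThird(tCccp, max(t) + (t[2] - t[1])) - quench
  list(deltaFAu = baseline - quench, cccpReleaseAu = release)
}

#' One-call bioenergetics summary of a respirometry trace
#'
#' Runs [segmentStates()] and [ocr()] over the detected windows and forms
#' the respiratory control ratio.
#'
#' @param trace a [RespiroTrace-class].
#' @param bufferS settling buffer passed to [segmentStates()].
#' @return List with `state3Ocr`, `state4Ocr`, `uncoupledOcr` (NA when no
#'   DNP event) and `rcr`.
#' @export
ocrSummary <- function(trace, bufferS = 10) {
  w <- segmentStates(trace, bufferS)
  get <- function(st) {
    i <- which(w$state == st)
    if (!length(i)) NA_real_ else as.numeric(ocr(trace, w[i, ]))
  }
  s3 <- get("State3"); s4 <- get("State4")
  list(state3Ocr = s3, state4Ocr = s4, uncoupledOcr = get("Uncoupled"),
       rcr = if (!is.na(s3) && !is.na(s4) && s4 > 0) s3 / s4 else NA_real_)
}
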