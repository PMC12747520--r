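#' @include synthScene.R
NULL

#' Parameters for a synthetic Clark-electrode respirometry trace
#'
#' Defaults mirror the standard isolated-brain-mitochondria protocol:
#' 0.05 mg mitochondrial protein in a 0.5 mL chamber near air saturation,
#' substrate addition, ADP addition initiating State 3 phosphorylating
#' respiration, spontaneous transition to State 4 once ADP is exhausted,
#' and a protonophore (DNP) addition initiating uncoupled respiration.
#' Default segment slopes give a respiratory control ratio of 4 (State 3
#' -10 vs State 4 -2.5 nmol/mL/min).
#'
#' @param proteinMg mitochondrial protein, mg.
#' @param chamberMl chamber volume, mL.
#' @param o2Start starting O2 concentration, nmol/mL.
#' @param slopes named numeric vector of chamber O2 slopes in nmol/mL/min
#'   for segments `basal`, `state2`, `state3`, `state4`, `uncoupled`
#'   (negative = consumption).
#' @param eventTimesS named numeric vector with strictly increasing times
#'   (seconds) for `substrate`, `ADP`, `DNP`.
#' @param state3DurationS seconds from ADP addition to ADP exhaustion.
#' @param durationS,dtS trace length and sampling interval, seconds.
#' @param noiseSd additive Gaussian noise on O2, nmol/mL.
#' @param seed integer seed for the noise draw.
#' @param annotateExhaustion if `TRUE`, add an explicit `adp_exhausted`
#'   event (otherwise the State 3/4 boundary must be detected).
#' @return A validated parameter list for [synthRespiroTrace()].
#' @export
respiroParams <- function(proteinMg = 0.05, chamberMl = 0.5, o2Start = 220,
                          slopes = c(basal = -1, state2 = -3, state3 = -10,
                                     state4 = -2.5, uncoupled = -9),
                          eventTimesS = c(substrate = 60, ADP = 200, DNP = 500),
                          state3DurationS = 150, durationS = 650, dtS = 1,
                          noiseSd = 0, seed = 1L,
                          annotateExhaustion = FALSE) {
  stopifnot(proteinMg > 0, chamberMl > 0, noiseSd >= 0, dtS > 0)
  need <- c("basal", "state2", "state3", "state4", "uncoupled")
  if (!all(need %in% names(slopes)))
    stop("slopes must name: ", paste(need, collapse = ", "))
  if (!all(c("substrate", "ADP", "DNP") %in% names(eventTimesS)))
    stop("eventTimesS must name substrate, ADP, DNP")
  et <- eventTimesS[c("substrate", "ADP", "DNP")]
  if (is.unsorted(et, strictly = TRUE))
    stop("event times must be strictly increasing")
  if (abs(slopes[["state3"]]) < abs(slopes[["state4"]]))
    stop("State 3 slope magnitude must be >= State 4 slope magnitude")
  exhaust <- et[["ADP"]] + state3DurationS
  if (exhaust >= et[["DNP"]])
    stop("ADP exhaustion must precede the DNP addition")
  list(proteinMg = proteinMg, chamberMl = chamberMl, o2Start = o2Start,
       slopes = slopes, eventTimesS = et, state3DurationS = state3DurationS,
       durationS = durationS, dtS = dtS, noiseSd = noiseSd,
       seed = as.integer(seed), annotateExhaustion = isTRUE(annotateExhaustion))
}

#' Synthesize a Clark-electrode O2 trace
#'
#' Piecewise-linear chamber O2 concentration with slope changes exactly at
#' the protocol events (and at ADP exhaustion), plus optional additive
#' Gaussian noise. The generating slopes, the exhaustion time and the
#' implied per-state oxygen consumption rates are recorded in the trace's
#' ground truth.
#'
#' @param params a list from [respiroParams()].
#' @return A [RespiroTrace-class].
#' @examples
#' tr <- synthRespiroTrace(respiroParams(noiseSd = 0.5, seed = 3))
#' @export
synthRespiroTrace <- function(params) {
  p <- params
  brk <- c(0, p$eventTimesS[["substrate"]], p$eventTimesS[["ADP"]],
           p$eventTimesS[["ADP"]] + p$state3DurationS,
           p$eventTimesS[["DNP"]], p$durationS)
  slp <- p$slopes[c("basal", "state2", "state3", "state4", "uncoupled")] / 60
  t <- seq(0, p$durationS, by = p$dtS)
  o2 <- rep(p$o2Start, length(t))
  for (i in seq_along(slp)) {
    dur <- pmin(pmax(t - brk[i], 0), brk[i + 1] - brk[i])
    o2 <- o2 + slp[[i]] * dur
  }
  if (min(o2) < 0) stop("chamber anoxia: O2 driven below 0 before trace end")
  if (p$noiseSd > 0)
    o2 <- .withSeed(p$seed, o2 + stats::rnorm(length(o2), sd = p$noiseSd))
  ev <- data.frame(time_s = unname(p$eventTimesS),
                   label = names(p$eventTimesS), stringsAsFactors = FALSE)
  if (p$annotateExhaustion)
    ev <- rbind(ev, data.frame(time_s = brk[4], label = "adp_exhausted"))
  ev <- ev[order(ev$time_s), , drop = FALSE]
  ocrOf <- function(s) -s * p$chamberMl / p$proteinMg
  new("RespiroTrace", timeS = t, o2NmolPerMl = o2, events = ev,
      proteinMg = p$proteinMg, chamberMl = p$chamberMl,
      truth = list(slopes_nmol_ml_min = p$slopes,
                   adp_exhausted_s = brk[4],
                   ocr_nmol_mg_min = c(state3 = ocrOf(p$slopes[["state3"]]),
                                       state4 = ocrOf(p$slopes[["state4"]]),
                                       uncoupled = ocrOf(p$slopes[["uncoupled"]])),
                   rcr = p$slopes[["state3"]] / p$slopes[["state4"]]))
}

#' Parameters for a synthetic fluorometer trace
#'
#' Event structure follows the assay protocols: Amplex UltraRed records
#' 400 s of baseline H2O2 emission before rotenone, then antimycin A after
#' another 200 s; MitoSOX fluorescence rises linearly before kinetics
#' saturate (default 1500 s); RH-123 records a 300 s baseline, quenches on
#' substrate addition and is released by CCCP.
#'
#' @param kind `"amplex"`, `"mitosox"` or `"rh123"`.
#' @param baselineLevel starting fluorescence, a.u.
#' @param ratesAuS named slopes in a.u./s — amplex: `pre`, `rotenone`,
#'   `antimycin`; mitosox: `initial`.
#' @param plateausAu named levels in a.u. — rh123: `quench`, `recovery`.
#' @param eventTimesS named event times, seconds — amplex: `rotenone`,
#'   `antimycin`; rh123: `substrate` and optional `cccp`.
#' @param saturationTimeS mitosox only: end of the linear regime, seconds.
#' @param settleTauS rh123 only: exponential settling time constant after
#'   each addition, seconds.
#' @param durationS,dtS trace length and sampling interval, seconds.
#' @param noiseSd additive Gaussian noise, a.u.
#' @param seed integer seed for the noise draw.
#' @return A validated parameter list for [synthFluoroTrace()].
#' @export
fluoroParams <- function(kind = c("amplex", "mitosox", "rh123"),
                         baselineLevel = NULL, ratesAuS = NULL,
                         plateausAu = NULL, eventTimesS = NULL,
                         saturationTimeS = 1500, settleTauS = 8,
                         durationS = NULL, dtS = 1, noiseSd = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(noiseSd >= 0, dtS > 0)
  if (kind == "amplex") {
    if (is.null(baselineLevel)) baselineLevel <- 20
    if (is.null(ratesAuS)) ratesAuS <- c(pre = 50 / 60, rotenone = 1.5, antimycin = 0.2)
    if (is.null(eventTimesS)) eventTimesS <- c(rotenone = 400, antimycin = 600)
    if (is.null(durationS)) durationS <- 900
    if (!all(c("rotenone", "antimycin") %in% names(eventTimesS)) ||
        eventTimesS[["rotenone"]] >= eventTimesS[["antimycin"]])
      stop("amplex requires a rotenone event followed by an antimycin event")
    if (!all(c("pre", "rotenone", "antimycin") %in% names(ratesAuS)))
      stop("amplex ratesAuS must name pre, rotenone, antimycin")
  } else if (kind == "mitosox") {
    if (is.null(baselineLevel)) baselineLevel <- 50
    if (is.null(ratesAuS)) ratesAuS <- c(initial = 5)
    if (is.null(eventTimesS)) eventTimesS <- numeric(0)
    if (is.null(durationS)) durationS <- 1800
    if (length(eventTimesS))
      stop("mitosox traces carry no addition events")
    if (!"initial" %in% names(ratesAuS)) stop("mitosox ratesAuS must name initial")
    stopifnot(saturationTimeS > 0)
  } else {
    if (is.null(baselineLevel)) baselineLevel <- 100
    if (is.null(plateausAu)) plateausAu <- c(quench = 60, recovery = 95)
    if (is.null(eventTimesS)) eventTimesS <- c(substrate = 320, cccp = 700)
    if (is.null(durationS)) durationS <- 1000
    if (!"substrate" %in% names(eventTimesS) || eventTimesS[["substrate"]] < 300)
      stop("rh123 requires a substrate event at or after the 300 s baseline")
    if (!"quench" %in% names(plateausAu))
      stop("rh123 plateausAu must name quench (and recovery when CCCP present)")
    if ("cccp" %in% names(eventTimesS)) {
      if (eventTimesS[["cccp"]] <= eventTimesS[["substrate"]])
        stop("cccp must follow substrate")
      if (!"recovery" %in% names(plateausAu))
        stop("rh123 with CCCP requires a recovery plateau")
    }
  }
  list(kind = kind, baselineLevel = baselineLevel, ratesAuS = ratesAuS,
       plateausAu = plateausAu, eventTimesS = eventTimesS,
       saturationTimeS = saturationTimeS, settleTauS = settleTauS,
       durationS = durationS, dtS = dtS, noiseSd = noiseSd,
       seed = as.integer(seed))
}

#' Synthesize a fluorometer kinetic trace
#'
#' Kind-specific shapes: `amplex` is piecewise linear with rate changes at
#' the rotenone and antimycin A additions; `mitosox` rises linearly at the
#' initial rate until `saturationTimeS`, then saturates exponentially;
#' `rh123` steps between plateaus (baseline, substrate-quenched, post-CCCP
#' release) with a short exponential settling transient. Generating values
#' are recorded in the trace's ground truth.
#'
#' @param params a list from [fluoroParams()].
#' @return A [FluoroTrace-class].
#' @examples
#' tr <- synthFluoroTrace(fluoroParams("rh123"))
#' @export
synthFluoroTrace <- function(params) {
  p <- params
  t <- seq(0, p$durationS, by = p$dtS)
  truth <- list(kind = p$kind)
  if (p$kind == "amplex") {
    brk <- c(0, p$eventTimesS[["rotenone"]], p$eventTimesS[["antimycin"]], p$durationS)
    rates <- p$ratesAuS[c("pre", "rotenone", "antimycin")]
    f <- rep(p$baselineLevel, length(t))
    for (i in seq_along(rates))
      f <- f + rates[[i]] * pmin(pmax(t - brk[i], 0), brk[i + 1] - brk[i])
    truth$rates_au_s <- rates
    truth$pre_rotenone_slope_au_min <- rates[["pre"]] * 60
  } else if (p$kind == "mitosox") {
    r <- p$ratesAuS[["initial"]]
    ts <- p$saturationTimeS
    tau <- ts / 5                       # smooth post-saturation rollover
    f <- ifelse(t <= ts, p$baselineLevel + r * t,
                p$baselineLevel + r * ts + r * tau * (1 - exp(-(t - ts) / tau)))
    truth$initial_rate_au_s <- r
    truth$initial_rate_au_min <- r * 60
    truth$saturation_time_s <- ts
  } else {
    tSub <- p$eventTimesS[["substrate"]]
    tCccp <- if ("cccp" %in% names(p$eventTimesS)) p$eventTimesS[["cccp"]] else Inf
    q <- p$plateausAu[["quench"]]
    f <- rep(p$baselineLevel, length(t))
    after <- t >= tSub
    f[after] <- q + (p$baselineLevel - q) * exp(-(t[after] - tSub) / p$settleTauS)
    if (is.finite(tCccp)) {
      rec <- p$plateausAu[["recovery"]]
      atC <- q + (p$baselineLevel - q) * exp(-(tCccp - tSub) / p$settleTauS)
      after <- t >= tCccp
      f[after] <- rec + (atC - rec) * exp(-(t[after] - tCccp) / p$settleTauS)
      truth$cccp_release_au <- rec - q
    }
    truth$delta_f_au <- p$baselineLevel - q
  }
  if (p$noiseSd > 0)
    f <- .withSeed(p$seed, f + stats::rnorm(length(f), sd = p$noiseSd))
  ev <- if (length(p$eventTimesS))
    data.frame(time_s = unname(p$eventTimesS), label = names(p$eventTimesS),
               stringsAsFactors = FALSE)
  else data.frame(time_s = numeric(0), label = character(0))
  ev <- ev[order(ev$time_s), , drop = FALSE]
  new("FluoroTrace", kind = p$kind, timeS = t, fluorescenceAu = f,
      events = ev, truth = truth)
}
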