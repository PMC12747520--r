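#' @include AllClasses.R
NULL

#' Write / read an amplitude map as 32-bit TIFF
#'
#' Values are stored normalized to their maximum (TIFF float convention);
#' the scale, wavelength and pixel spacing go into a plain-text sidecar
#' (`<file>.meta`, `key=value` lines) so the round trip restores physical
#' units.
#'
#' @param map an [AmplitudeMap-class].
#' @param file path to a `.tif` file.
#' @return `writeAmplitudeMap` returns `file` invisibly;
#'   `readAmplitudeMap` returns an [AmplitudeMap-class].
#' @export
writeAmplitudeMap <- function(map, file) {
  v <- mapValues(map)
  mx <- max(v, 1e-300)
  tiff::writeTIFF(v / mx, file, bits.per.sample = 32L)
  writeLines(sprintf(c("max=%.17g", "wavelength_nm=%g", "spacing_x_um=%g",
                       "spacing_y_um=%g"),
                     c(mx, map@wavelengthNm, map@pixelSpacingUm)),
             paste0(file, ".meta"))
  invisible(file)
}

#' @rdname writeAmplitudeMap
#' @export
readAmplitudeMap <- function(file) {
  img <- tiff::readTIFF(file)
  kv <- strsplit(readLines(paste0(file, ".meta")), "=")
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                          vapply(kv, `[`, character(1), 1))
  amplitudeMapFromMatrix(img * vals[["max"]],
                         c(vals[["spacing_x_um"]], vals[["spacing_y_um"]]),
                         vals[["wavelength_nm"]])
}

#' Write / read an instrument trace as annotated CSV
#'
#' Columns `time_s`, `value`, `event` (empty where no event falls on that
#' sample); trace-level metadata (kind, protein, chamber volume) go into
#' `# key=value` header comments. Events whose time matches no sample are
#' attached to the nearest sample.
#'
#' @param trace a [RespiroTrace-class] or [FluoroTrace-class].
#' @param file path to a `.csv` file.
#' @return `writeTrace` returns `file` invisibly; `readTrace` returns the
#'   reconstructed trace object.
#' @export
writeTrace <- function(trace, file) {
  t <- traceTime(trace); v <- traceValues(trace)
  ev <- traceEvents(trace)
  evCol <- character(length(t))
  for (i in seq_len(nrow(ev)))
    evCol[which.min(abs(t - ev$time_s[i]))] <- ev$label[i]
  hdr <- if (is(trace, "RespiroTrace"))
    c("# type=respiro", sprintf("# protein_mg=%g", trace@proteinMg),
      sprintf("# chamber_ml=%g", trace@chamberMl))
  else c("# type=fluoro", sprintf("# kind=%s", trace@kind))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(time_s = t, value = v, event = evCol),
                   con, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTrace
#' @export
readTrace <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        stringsAsFactors = FALSE)
  df$event[is.na(df$event)] <- ""
  ev <- df[df$event != "", c("time_s", "event")]
  events <- data.frame(time_s = ev$time_s, label = ev$event,
                       stringsAsFactors = FALSE)
  if (identical(meta$type, "respiro"))
    new("RespiroTrace", timeS = df$time_s, o2NmolPerMl = df$value,
        events = events, proteinMg = as.numeric(meta$protein_mg),
        chamberMl = as.numeric(meta$chamber_ml), truth = list())
  else
    new("FluoroTrace", kind = meta$kind, timeS = df$time_s,
        fluorescenceAu = df$value, events = events, truth = list())
}

#' Write / read a phantom scene configuration as YAML
#'
#' Serializes [sceneConfig()] (plus the scene seed) so that
#' `readScene(writeScene(x, f))` reproduces `x` exactly.
#'
#' @param scene a [PhantomScene-class].
#' @param file path to a `.yaml` file.
#' @return `writeScene` returns `file` invisibly; `readScene` the rebuilt
#'   [PhantomScene-class].
#' @export
writeScene <- function(scene, file) {
  cfg <- sceneConfig(scene)
  cfg$seed <- scene@seed
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' @rdname writeScene
#' @export
readScene <- function(file) {
  cfg <- yaml::read_yaml(file)
  seed <- cfg$seed
  cfg$seed <- NULL
  makeScene(cfg, seed = seed)
}

#' Write / read an A-line ensemble as CSV
#'
#' One A-line per row; the repetition interval is kept in a `# dt_s=`
#' header comment.
#'
#' @param e an [AlineEnsemble-class].
#' @param file path to a `.csv` file.
#' @return `writeAlineEnsemble` returns `file` invisibly;
#'   `readAlineEnsemble` an [AlineEnsemble-class].
#' @export
writeAlineEnsemble <- function(e, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_s=%.17g", e@dtS), con)
  utils::write.table(ensembleLines(e), con, row.names = FALSE,
                     col.names = FALSE, sep = ",")
  invisible(file)
}

#' @rdname writeAlineEnsemble
#' @export
readAlineEnsemble <- function(file) {
  lines <- readLines(file)
  dt <- as.numeric(sub("^# dt_s=", "", lines[1]))
  m <- as.matrix(utils::read.csv(textConnection(lines[-1]), header = FALSE))
  dimnames(m) <- NULL
  new("AlineEnsemble", lines = m, dtS = dt, truth = list())
}

#' Per-vessel measurement table as CSV
#'
#' @param vessels data.frame of per-vessel measurements.
#' @param file path to a `.csv` file.
#' @return `file`, invisibly.
#' @export
writeVesselTable <- function(vessels, file) {
  utils::write.csv(vessels, file, row.names = FALSE)
  invisible(file)
}
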