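#' Read an MS run from mzML, mzXML or the JSON fixture format
#'
#' mzML/mzXML files are parsed with the \pkg{mzR} backend; centroided
#' peaks are assumed (profile data is not resampled). The JSON fixture
#' format (see [writeSpectraJSON()]) is a fast plain-text alternative for
#' tests and small synthetic datasets.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mzML"`, `"mzXML"` or `"json"`.
#' @param msLevel Optional integer; keep only spectra at this MS level.
#' @return A [SpectraRun-class]. A run with zero MS2 spectra triggers a
#'   warning.
#' @export
readSpectra <- function(path, format = c("auto", "mzML", "mzXML", "json"),
                        msLevel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mzml = "mzML", mzxml = "mzXML", json = "json",
      stop("cannot infer format from extension '", ext, "' of ", path))
  }
  run <- if (format == "json") .readSpectraJSON(path) else .readSpectraMzR(path)
  if (!is.null(msLevel)) {
    keep <- vapply(run@spectra, function(s) s@msLevel %in% msLevel, logical(1))
    run <- SpectraRun(run@runId, run@spectra[keep])
  }
  lv <- msLevelCounts(run)
  if (!("2" %in% names(lv)))
    warning("run '", run@runId, "' contains no MS2 spectra")
  run
}

.readSpectraMzR <- function(path) {
  handle <- tryCatch(mzR::openMSfile(path),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  rid <- tools::file_path_sans_ext(basename(path))
  n <- nrow(hdr)
  if (n == 0L) return(SpectraRun(rid, list()))
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  specs <- lapply(seq_len(n), function(i) {
    p <- pk[[i]]
    chg <- hdr$precursorCharge[i]
    pmz <- hdr$precursorMZ[i]
    Spectrum(rid, hdr$acquisitionNum[i],
             mz = p[, 1L], intensity = p[, 2L],
             msLevel = hdr$msLevel[i],
             precursorMz = if (!is.na(pmz) && pmz > 0) pmz else NA_real_,
             precursorCharge = if (!is.na(chg) && chg > 0)
               as.integer(chg) else NA_integer_,
             retentionTime = hdr$retentionTime[i])
  })
  SpectraRun(rid, specs)
}

.readSpectraJSON <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$runId) || is.null(doc$spectra))
    stop("malformed spectra JSON (need runId and spectra): ", path)
  specs <- lapply(doc$spectra, function(s)
    Spectrum(doc$runId, s$scan,
             mz = as.numeric(unlist(s$mz)),
             intensity = as.numeric(unlist(s$intensity)),
             msLevel = if (is.null(s$msLevel)) 2L else s$msLevel,
             precursorMz = if (is.null(s$precursorMz)) NA_real_
               else s$precursorMz,
             precursorCharge = if (is.null(s$precursorCharge)) NA_integer_
               else s$precursorCharge,
             retentionTime = if (is.null(s$retentionTime)) NA_real_
               else s$retentionTime))
  SpectraRun(doc$runId, specs)
}

#' Write a run in the JSON fixture format
#'
#' Plain-text schema: `{"runId": ..., "spectra": [{"scan", "msLevel",
#' "precursorMz", "precursorCharge", "retentionTime", "mz": [...],
#' "intensity": [...]}, ...]}`. Full double precision is preserved.
#'
#' @param run A [SpectraRun-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSpectraJSON <- function(run, path) {
  stopifnot(is(run, "SpectraRun"))
  doc <- list(
    runId = run@runId,
    spectra = lapply(run@spectra, function(s) list(
      scan = s@scanNumber, msLevel = s@msLevel,
      precursorMz = s@precursorMz, precursorCharge = s@precursorCharge,
      retentionTime = s@retentionTime,
      mz = s@mz, intensity = s@intensity))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a run as mzML
#'
#' Uses the \pkg{mzR} writer; peak arrays are stored at 64-bit precision
#' so a round trip through [readSpectra()] reproduces the in-memory run.
#'
#' @param run A [SpectraRun-class].
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
writeSpectraMzML <- function(run, path) {
  stopifnot(is(run, "SpectraRun"))
  n <- length(run@spectra)
  if (n == 0L) stop("cannot write an empty run as mzML")
  pk <- lapply(run@spectra, peakMatrix)
  num <- function(f, d = NA_real_)
    vapply(run@spectra, function(s) {
      v <- f(s); if (is.na(v)) d else as.numeric(v)
    }, numeric(1))
  pmz <- num(function(s) s@precursorMz, 0)
  hdr <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = vapply(run@spectra, function(s) s@scanNumber, integer(1)),
    msLevel = vapply(run@spectra, function(s) s@msLevel, integer(1)),
    polarity = 1L,
    peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(pk, function(p) sum(p[, 2L]), numeric(1)),
    retentionTime = num(function(s) s@retentionTime, 0),
    basePeakMZ = vapply(pk, function(p)
      if (nrow(p) > 0L) p[which.max(p[, 2L]), 1L] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(p)
      if (nrow(p) > 0L) max(p[, 2L]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p)
      if (nrow(p) > 0L) min(p[, 1L]) else 0, numeric(1)),
    highMZ = vapply(pk, function(p)
      if (nrow(p) > 0L) max(p[, 1L]) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = pmz,
    precursorCharge = vapply(run@spectra, function(s)
      if (is.na(s@precursorCharge)) 0L else s@precursorCharge, integer(1)),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0,
    filterString = "",
    spectrumId = sprintf("scan=%d",
      vapply(run@spectra, function(s) s@scanNumber, integer(1))),
    centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = pmz,
    isolationWindowLowerOffset = 1.5, isolationWindowUpperOffset = 1.5,
    scanWindowLowerLimit = 100, scanWindowUpperLimit = 2000,
    stringsAsFactors = FALSE
  )
  if (file.exists(path)) unlink(path)
  mzR::writeMSData(object = pk, file = path, header = hdr,
                   outformat = "mzml")
  invisible(path)
}

#' Peaks within an m/z window
#'
#' All peaks with `|mz - center| <= half-width`, bounds inclusive, found
#' by binary search over the sorted peak vector.
#'
#' @param s A [Spectrum-class].
#' @param center Centre m/z.
#' @param tol Positive tolerance.
#' @param unit `"Da"` or `"ppm"`.
#' @return Two-column matrix (`mz`, `intensity`), possibly with 0 rows.
#' @export
peaksInWindow <- function(s, center, tol, unit = c("Da", "ppm")) {
  stopifnot(is(s, "Spectrum"))
  w <- toleranceWindow(center, tol, match.arg(unit))
  if (length(s@mz) == 0L)
    return(cbind(mz = numeric(0), intensity = numeric(0)))
  lo <- findInterval(w[[1L]], s@mz, left.open = TRUE) + 1L
  hi <- findInterval(w[[2L]], s@mz)
  if (lo > hi) return(cbind(mz = numeric(0), intensity = numeric(0)))
  cbind(mz = s@mz[lo:hi], intensity = s@intensity[lo:hi])
}
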