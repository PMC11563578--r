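#' Spectrum: a single MS2 (or MS1) scan
#'
#' Holds the centroided peak list of one scan together with its precursor
#' metadata. Peaks are kept sorted ascending by m/z; windowed queries use
#' binary search on that order.
#'
#' @slot runId character run identifier.
#' @slot scanNumber integer scan number, unique within a run.
#' @slot msLevel integer MS level (2 for fragment spectra).
#' @slot precursorMz numeric precursor m/z (`NA` if absent).
#' @slot precursorCharge integer precursor charge (`NA` if absent).
#' @slot retentionTime numeric retention time in seconds (`NA` if absent).
#' @slot mz numeric peak m/z values, sorted ascending.
#' @slot intensity numeric peak intensities, parallel to `mz`.
#'
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    runId = "character",
    scanNumber = "integer",
    msLevel = "integer",
    precursorMz = "numeric",
    precursorCharge = "integer",
    retentionTime = "numeric",
    mz = "numeric",
    intensity = "numeric"
  ),
  prototype(
    runId = "run", scanNumber = 0L, msLevel = 2L,
    precursorMz = NA_real_, precursorCharge = NA_integer_,
    retentionTime = NA_real_, mz = numeric(0), intensity = numeric(0)
  )
)

setValidity("Spectrum", function(object) {
  msgs <- character(0)
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity must have equal length")
  if (is.unsorted(object@mz))
    msgs <- c(msgs, "peaks must be sorted ascending by m/z")
  if (any(object@intensity < 0))
    msgs <- c(msgs, "intensities must be >= 0")
  if (any(object@mz <= 0))
    msgs <- c(msgs, "m/z values must be > 0")
  if (length(msgs) > 0L) msgs else TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted by m/z on construction.
#'
#' @param runId Run identifier.
#' @param scanNumber Integer scan number.
#' @param mz,intensity Parallel numeric peak vectors.
#' @param msLevel MS level (default 2).
#' @param precursorMz,precursorCharge,retentionTime Optional precursor
#'   m/z, charge and retention time (seconds).
#' @return A [Spectrum-class] object.
#' @examples
#' Spectrum("r", 1L, mz = c(126.1277, 500.2), intensity = c(1e4, 2e3))
#' @export
Spectrum <- function(runId, scanNumber, mz = numeric(0),
                     intensity = numeric(0), msLevel = 2L,
                     precursorMz = NA_real_, precursorCharge = NA_integer_,
                     retentionTime = NA_real_) {
  o <- order(mz)
  new("Spectrum",
      runId = as.character(runId), scanNumber = as.integer(scanNumber),
      msLevel = as.integer(msLevel), precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      retentionTime = as.numeric(retentionTime),
      mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
}

#' SpectraRun: an ordered collection of spectra from one run
#'
#' Spectra are stored (and iterated) in scan-number order; scan numbers
#' are unique within the run.
#'
#' @slot runId character run identifier.
#' @slot spectra list of [Spectrum-class] objects sorted by scan number.
#'
#' @exportClass SpectraRun
setClass("SpectraRun",
  representation(runId = "character", spectra = "list"),
  prototype(runId = "run", spectra = list())
)

setValidity("SpectraRun", function(object) {
  ok <- vapply(object@spectra, is, logical(1), class2 = "Spectrum")
  if (!all(ok)) return("all elements must be Spectrum objects")
  sc <- vapply(object@spectra, function(s) s@scanNumber, integer(1))
  if (anyDuplicated(sc)) return("scan numbers must be unique within a run")
  if (is.unsorted(sc)) return("spectra must be ordered by scan number")
  TRUE
})

#' Construct a SpectraRun
#'
#' @param runId Run identifier.
#' @param spectra List of [Spectrum-class] objects (sorted on construction).
#' @return A [SpectraRun-class] object.
#' @export
SpectraRun <- function(runId, spectra = list()) {
  sc <- vapply(spectra, function(s) s@scanNumber, integer(1))
  new("SpectraRun", runId = as.character(runId),
      spectra = spectra[order(sc)])
}

#' StructureModel: chains, residues and atom coordinates
#'
#' A flat atom table (one row per atom) from a PDB or mmCIF file; altloc
#' duplicates resolved to the highest-occupancy conformer and only the
#' first model of multi-model files retained.
#'
#' @slot structureId character identifier (file stem or PDB id).
#' @slot atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#'
#' @exportClass StructureModel
setClass("StructureModel",
  representation(structureId = "character", atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@atoms) > 0L &&
      !all(is.finite(object@atoms$x) & is.finite(object@atoms$y) &
           is.finite(object@atoms$z)))
    return("atom coordinates must be finite")
  TRUE
})

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum", sprintf("%s scan %d (MS%d), %d peaks",
      object@runId, object@scanNumber, object@msLevel,
      length(object@mz)))
  if (!is.na(object@precursorMz))
    cat(sprintf(", precursor %.4f", object@precursorMz))
  cat("\n")
})

setMethod("show", "SpectraRun", function(object) {
  lv <- msLevelCounts(object)
  cat(sprintf("SpectraRun '%s': %d spectra", object@runId,
              length(object@spectra)))
  if (length(lv) > 0L)
    cat(" (", paste(sprintf("MS%s: %d", names(lv), lv), collapse = ", "),
        ")", sep = "")
  cat("\n")
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel '%s': %d atoms, %d chains, %d residues\n",
              object@structureId, nrow(a), length(unique(a$chain)),
              nrow(unique(a[, c("chain", "resno")]))))
})

#' @describeIn SpectraRun-class number of spectra in the run
#' @param x A `SpectraRun`.
#' @export
setMethod("length", "SpectraRun", function(x) length(x@spectra))

#' Accessors for spectra containers
#'
#' `runId` returns the run identifier; `spectra` the list of spectra;
#' `scanNumbers` the ordered scan numbers; `msLevelCounts` a table of
#' spectrum counts by MS level; `peakMatrix` the two-column peak matrix
#' of one spectrum; `getSpectrum` a spectrum by scan number.
#'
#' @param object A [SpectraRun-class] or [Spectrum-class] object.
#' @name spectra-accessors
NULL

#' @rdname spectra-accessors
#' @export
setGeneric("runId", function(object) standardGeneric("runId"))
#' @rdname spectra-accessors
#' @export
setMethod("runId", "SpectraRun", function(object) object@runId)
#' @rdname spectra-accessors
#' @export
setMethod("runId", "Spectrum", function(object) object@runId)

#' @rdname spectra-accessors
#' @export
setGeneric("spectra", function(object) standardGeneric("spectra"))
#' @rdname spectra-accessors
#' @export
setMethod("spectra", "SpectraRun", function(object) object@spectra)

#' @rdname spectra-accessors
#' @export
setGeneric("scanNumbers", function(object) standardGeneric("scanNumbers"))
#' @rdname spectra-accessors
#' @export
setMethod("scanNumbers", "SpectraRun", function(object)
  vapply(object@spectra, function(s) s@scanNumber, integer(1)))

#' @rdname spectra-accessors
#' @export
setGeneric("msLevelCounts", function(object) standardGeneric("msLevelCounts"))
#' @rdname spectra-accessors
#' @export
setMethod("msLevelCounts", "SpectraRun", function(object) {
  lv <- vapply(object@spectra, function(s) s@msLevel, integer(1))
  if (length(lv) == 0L) return(integer(0))
  tab <- table(lv)
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname spectra-accessors
#' @export
setGeneric("peakMatrix", function(object) standardGeneric("peakMatrix"))
#' @rdname spectra-accessors
#' @export
setMethod("peakMatrix", "Spectrum", function(object)
  cbind(mz = object@mz, intensity = object@intensity))

#' @rdname spectra-accessors
#' @param scan Integer scan number.
#' @export
getSpectrum <- function(object, scan) {
  stopifnot(is(object, "SpectraRun"))
  i <- match(as.integer(scan), scanNumbers(object))
  if (is.na(i)) stop("no spectrum with scan number ", scan,
                     " in run '", object@runId, "'")
  object@spectra[[i]]
}

#' @describeIn SpectraRun-class extract the i-th spectrum (scan order)
#' @param i Index in scan order.
#' @param j,... Unused.
#' @export
setMethod("[[", "SpectraRun", function(x, i, j, ...) x@spectra[[i]])
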