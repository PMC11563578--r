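#' Theoretical b/y fragment ladder of a peptide
#'
#' Generates `b_i` and `y_i` for `i = 1..n-1` at the requested charge
#' states. Modification masses are supplied as a per-residue vector of
#' mass additions; for a crosslinked peptide the partner chain (peptide
#' mass plus crosslink delta) is simply a large fixed modification on the
#' linked residue, since the Qlinker backbone is not MS-cleavable.
#'
#' @param sequence Peptide sequence (uppercase letters).
#' @param modMasses Numeric vector of per-position mass additions (Da),
#'   length `nchar(sequence)`, or `NULL` for none.
#' @param charges Integer vector of fragment charge states.
#' @return data.frame with columns `series` (`"b"`/`"y"`), `index`,
#'   `charge`, `label` and `mz`.
#' @examples
#' theoreticalFragments("PEPTIDE", charges = 1L)
#' @export
theoreticalFragments <- function(sequence, modMasses = NULL, charges = 1:2) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L)
  aa <- strsplit(sequence, "")[[1L]]
  masses <- aminoAcidMasses()
  if (!all(aa %in% names(masses)))
    stop("unknown residue(s) in sequence: ",
         paste(setdiff(aa, names(masses)), collapse = ", "))
  n <- length(aa)
  res <- masses[aa]
  if (!is.null(modMasses)) {
    stopifnot(length(modMasses) == n)
    res <- res + modMasses
  }
  if (n == 1L)
    return(data.frame(series = character(0), index = integer(0),
                      charge = integer(0), label = character(0),
                      mz = numeric(0), stringsAsFactors = FALSE))
  water <- monoisotopicMass(composition(H = 2, O = 1))
  proton <- PHYSICAL_CONSTANTS[["proton"]]
  bNeutral <- cumsum(res)[seq_len(n - 1L)]
  suffix <- rev(cumsum(rev(res)))          # suffix[i] = sum res[i..n]
  yNeutral <- rev(suffix[2:n]) + water     # y_k = suffix[n-k+1] + water
  out <- do.call(rbind, lapply(as.integer(charges), function(z) {
    data.frame(
      series = rep(c("b", "y"), each = n - 1L),
      index = rep(seq_len(n - 1L), 2L),
      charge = z,
      mz = (c(bNeutral, yNeutral) + z * proton) / z,
      stringsAsFactors = FALSE)
  }))
  out$label <- sprintf("%s%d^%d", out$series, out$index, out$charge)
  out[, c("series", "index", "charge", "label", "mz")]
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus one water plus any modification deltas.
#'
#' @param sequence Peptide sequence.
#' @param modMass Total modification mass to add (Da).
#' @return Mass in Da.
#' @export
peptideMass <- function(sequence, modMass = 0) {
  aa <- strsplit(sequence, "")[[1L]]
  masses <- aminoAcidMasses()
  if (!all(aa %in% names(masses)))
    stop("unknown residue(s) in sequence: ",
         paste(setdiff(aa, names(masses)), collapse = ", "))
  sum(masses[aa]) + monoisotopicMass(composition(H = 2, O = 1)) + modMass
}

#' Theoretical fragments for an identification
#'
#' Builds the annotated fragment ladders for the peptide(s) of one
#' identification row. Monolinked peptides carry the monolink delta on
#' the linked residue; each chain of a crosslink carries the crosslink
#' delta plus the full mass of the partner peptide on its linked residue.
#'
#' @param id One-row identification data.frame (see
#'   [readIdentifications()]).
#' @param charges Fragment charge states (default 1-2).
#' @return data.frame as [theoreticalFragments()] plus a `peptide` column
#'   (`"A"`/`"B"`).
#' @export
fragmentsForId <- function(id, charges = 1:2) {
  stopifnot(is.data.frame(id), nrow(id) == 1L)
  qd <- qlinkerDeltas()
  ladder <- function(seqs, link, delta, tag) {
    mods <- numeric(nchar(seqs))
    mods[link] <- delta
    fr <- theoreticalFragments(seqs, mods, charges)
    if (nrow(fr) > 0L) fr$peptide <- tag
    fr
  }
  if (id$type == "mono") {
    out <- ladder(id$pepA, id$linkA, qd["monolink", "deltaMass"], "A")
  } else {
    xl <- qd["crosslink", "deltaMass"]
    partnerA <- peptideMass(id$pepB) + xl
    partnerB <- peptideMass(id$pepA) + xl
    out <- rbind(ladder(id$pepA, id$linkA, partnerA, "A"),
                 ladder(id$pepB, id$linkB, partnerB, "B"))
  }
  rownames(out) <- NULL
  out
}

#' Validate an identified spectrum by fragment annotation
#'
#' Implements the manual-evaluation rule used for crosslink spectra: the
#' match is accepted when every peptide shows at least `minRun`
#' consecutive b ions or `minRun` consecutive y ions, and the majority
#' (strictly more than `majorityThreshold`) of the observed ion intensity
#' is accounted for by annotated fragments (reporter-ion peaks count as
#' accounted for).
#'
#' @param id One-row identification data.frame.
#' @param s The matching [Spectrum-class] (same run and scan).
#' @param fragTolPpm Fragment match tolerance in ppm (default 20).
#' @param charges Fragment charge states to consider.
#' @param minRun Minimum consecutive-ion run per peptide (default 4).
#' @param majorityThreshold Minimum annotated intensity fraction
#'   (default 0.5).
#' @return A list with `perPeptide` (data.frame: `peptide`, `bRun`,
#'   `yRun`), `annotatedFraction` and `pass`.
#' @export
validateSpectrum <- function(id, s, fragTolPpm = 20, charges = 1:2,
                             minRun = 4L, majorityThreshold = 0.5) {
  stopifnot(is(s, "Spectrum"))
  if (!is.na(id$scan) && id$scan != s@scanNumber)
    stop("identification (scan ", id$scan, ") and spectrum (scan ",
         s@scanNumber, ") refer to different scans")
  fr <- fragmentsForId(id, charges)
  annotated <- rep(FALSE, length(s@mz))
  matched <- rep(FALSE, nrow(fr))
  for (i in seq_len(nrow(fr))) {
    w <- toleranceWindow(fr$mz[i], fragTolPpm, "ppm")
    hit <- s@mz >= w[[1L]] & s@mz <= w[[2L]]
    if (any(hit)) {
      matched[i] <- TRUE
      annotated <- annotated | hit
    }
  }
  for (rmz in reporterMz()) {
    w <- toleranceWindow(rmz, 0.005, "Da")
    annotated <- annotated | (s@mz >= w[[1L]] & s@mz <= w[[2L]])
  }
  longestRun <- function(idx, nmax) {
    if (length(idx) == 0L) return(0L)
    present <- seq_len(nmax) %in% idx
    r <- rle(present)
    runs <- r$lengths[r$values]
    if (length(runs) == 0L) 0L else max(runs)
  }
  perPep <- do.call(rbind, lapply(unique(fr$peptide), function(p) {
    sub <- fr[fr$peptide == p, , drop = FALSE]
    nmax <- max(sub$index)
    bIdx <- unique(sub$index[sub$series == "b" & matched[fr$peptide == p]])
    yIdx <- unique(sub$index[sub$series == "y" & matched[fr$peptide == p]])
    data.frame(peptide = p, bRun = longestRun(bIdx, nmax),
               yRun = longestRun(yIdx, nmax), stringsAsFactors = FALSE)
  }))
  totInt <- sum(s@intensity)
  frac <- if (totInt > 0) sum(s@intensity[annotated]) / totInt else 0
  pass <- all(pmax(perPep$bRun, perPep$yRun) >= minRun) &&
    frac > majorityThreshold
  list(perPeptide = perPep, annotatedFraction = frac, pass = pass)
}
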