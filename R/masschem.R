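#' @import methods
NULL

## Monoisotopic atomic masses (Da), IUPAC/CODATA values to >= 7 decimals.
## Heavy isotopes are distinct symbols ("13C", "2H", "15N", "18O").
.ATOMIC_MASS <- c(
  H     = 1.00782503207,
  "2H"  = 2.01410177785,
  C     = 12.0,
  "13C" = 13.00335483507,
  N     = 14.00307400443,
  "15N" = 15.00010889888,
  O     = 15.99491461957,
  "18O" = 17.99915961286,
  S     = 31.97207117440,
  P     = 30.97376199842,
  Na    = 22.98976928200
)

#' Physical constants used in m/z arithmetic
#'
#' Monoisotopic proton and electron masses (Da). All m/z computation in the
#' package is routed through [ionMz()] using these constants.
#'
#' @format Named numeric vector with elements `proton` and `electron`.
#' @export
PHYSICAL_CONSTANTS <- c(proton = 1.007276466621, electron = 0.000548579909)

#' Construct an elemental composition
#'
#' A composition is a named integer vector of element counts. Heavy isotopes
#' are distinct symbols: `"13C"` is carbon-13, so the 127-channel reporter
#' cation is `composition("13C" = 1, C = 7, H = 16, N = 1)`.
#'
#' @param ... Named integer counts, or a single named vector.
#' @return Named integer vector of class `ElementComposition`.
#' @examples
#' composition(H = 2, O = 1)              # water
#' composition(C = 8, H = 16, N = 1)      # reporter cation skeleton
#' @export
composition <- function(...) {
  args <- list(...)
  x <- if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1L]])))
    args[[1L]] else unlist(args)
  if (length(x) == 0L) {
    out <- integer(0)
    class(out) <- "ElementComposition"
    return(out)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all composition entries must be named element symbols")
  unknown <- setdiff(names(x), names(.ATOMIC_MASS))
  if (length(unknown) > 0L)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(x < 0) || any(x != round(x)))
    stop("element counts must be non-negative integers")
  out <- vapply(split(as.integer(x), names(x)), sum, integer(1))
  out <- out[out > 0L]
  class(out) <- "ElementComposition"
  out
}

#' Parse a molecular formula string
#'
#' Understands plain formulas (`"C8H16N"`) with optional heavy-isotope
#' prefixes written inline (`"13C1C7H16N"` or `"(13C)C14H26N2O5"`).
#'
#' @param formula Character scalar.
#' @return An `ElementComposition`.
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[()\\s]", "", formula, perl = TRUE)
  m <- gregexpr("(13C|15N|18O|2H|[A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1L]]
  toks <- regmatches(s, list(m))[[1L]]
  if (sum(nchar(toks)) != nchar(s))
    stop("cannot parse formula: ", formula)
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^(13C|15N|18O|2H|[A-Z][a-z]?)", "", toks)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  names(cnt) <- sym
  composition(cnt)
}

#' Add or subtract elemental compositions
#'
#' Element-wise arithmetic; subtraction that would drive any count negative
#' is an error (a molecule cannot lose atoms it does not have).
#'
#' @param a,b `ElementComposition` objects.
#' @return An `ElementComposition`.
#' @export
addComposition <- function(a, b) {
  x <- c(unclass(a), unclass(b))
  composition(x)
}

#' @rdname addComposition
#' @export
subtractComposition <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  res <- a
  for (el in names(b)) {
    have <- if (el %in% names(res)) res[[el]] else 0L
    if (have < b[[el]])
      stop("subtraction would give negative count for element ", el)
    res[el] <- have - b[[el]]
  }
  composition(res[res > 0L])
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times the monoisotopic atomic mass.
#'
#' @param comp An `ElementComposition`, or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(composition(H = 2, O = 1)) # 18.010565
#' @export
monoisotopicMass <- function(comp) {
  if (is.character(comp)) comp <- parseFormula(comp)
  if (length(comp) == 0L) return(0)
  unknown <- setdiff(names(comp), names(.ATOMIC_MASS))
  if (length(unknown) > 0L)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(.ATOMIC_MASS[names(comp)] * as.numeric(comp))
}

#' m/z of an ion
#'
#' For protonated species the observed m/z is `(M + z * m_proton) / z`;
#' for an intrinsic cation (the charge is carried by the composition
#' itself, e.g. an iminium reporter ion) it is `(M - z * m_electron) / z`.
#'
#' @param comp Neutral composition (protonated species) or cation
#'   composition (intrinsic), as `ElementComposition` or formula string.
#' @param charge Positive integer charge state.
#' @param protonated Logical; `TRUE` adds protons, `FALSE` removes electrons.
#' @return m/z value.
#' @examples
#' ionMz(composition(H = 2, O = 1), 1, protonated = TRUE)        # 19.018390
#' ionMz(composition(C = 8, H = 16, N = 1), 1, protonated = FALSE) # 126.127726
#' @export
ionMz <- function(comp, charge = 1L, protonated = TRUE) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("charge must be a positive integer")
  m <- monoisotopicMass(comp)
  if (protonated)
    (m + charge * PHYSICAL_CONSTANTS[["proton"]]) / charge
  else
    (m - charge * PHYSICAL_CONSTANTS[["electron"]]) / charge
}

## Reporter cation compositions: the 126 channel is the all-12C
## 1-imino-2,6-dimethylpiperidin-1-ium cation C8H16N+ (the 13C of that
## reagent stays on the balance arm); the 127 channel carries one 13C.
.REPORTER_COMP <- list(
  "126" = composition(C = 8, H = 16, N = 1),
  "127" = composition("13C" = 1, C = 7, H = 16, N = 1)
)

#' Reporter channel definitions
#'
#' The two Qlinker reporter channels: ion composition, theoretical m/z at
#' charge 1 (intrinsic cation) and the isotope-purity column describing how
#' each channel's true signal distributes over the observed channels.
#'
#' @return A data.frame with one row per channel: `label`, `formula`,
#'   `mz`, `purityOwn`, `purityOther`.
#' @examples
#' reporterChannels()
#' @export
reporterChannels <- function() {
  M <- defaultPurityMatrix()
  data.frame(
    label = c(126L, 127L),
    formula = c("C8H16N", "(13C)C7H16N"),
    mz = c(ionMz(.REPORTER_COMP[["126"]], 1L, protonated = FALSE),
           ionMz(.REPORTER_COMP[["127"]], 1L, protonated = FALSE)),
    purityOwn = diag(M),
    purityOther = c(M[2L, 1L], M[1L, 2L]),
    stringsAsFactors = FALSE
  )
}

#' Theoretical reporter m/z values
#'
#' @return Named numeric vector (`"126"`, `"127"`) of theoretical 1+ m/z.
#' @export
reporterMz <- function() {
  c("126" = ionMz(.REPORTER_COMP[["126"]], 1L, protonated = FALSE),
    "127" = ionMz(.REPORTER_COMP[["127"]], 1L, protonated = FALSE))
}

#' Default 2x2 isotope purity matrix
#'
#' Column j gives the fractional distribution of channel j's true signal
#' across the observed channels (rows = observed 126, 127). These are the
#' reagent-lot values used throughout; supply your own matrix to
#' [correctImpurity()] for a different lot.
#'
#' @return 2x2 numeric matrix with dimnames `observed` x `true`.
#' @export
defaultPurityMatrix <- function() {
  matrix(c(0.90754, 0.09246, 0.01, 0.90724), nrow = 2L,
         dimnames = list(observed = c("126", "127"), true = c("126", "127")))
}

## Residue elemental compositions (residue = amino acid minus water).
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Monoisotopic residue masses
#'
#' Masses of the 20 standard amino acid residues, derived from their
#' elemental compositions. Peptide neutral mass = sum of residue masses
#' plus one water.
#'
#' @return Named numeric vector, residue letter to monoisotopic mass (Da).
#' @export
aminoAcidMasses <- function() {
  vapply(.RESIDUE_FORMULA, monoisotopicMass, numeric(1))
}

#' b1+ fragment ion m/z of a residue
#'
#' The singly charged N-terminal fragment containing only the first
#' residue: residue monoisotopic mass plus one proton. Leucine/isoleucine
#' give 114.09, asparagine 115.05 and aspartate 116.03; these sit close to
#' the reporter region and motivate reporter masses above 126.
#'
#' @param residue Single amino acid letter.
#' @return m/z value.
#' @examples
#' b1IonMz("L") # 114.09
#' @export
b1IonMz <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L)
  if (!residue %in% names(.RESIDUE_FORMULA))
    stop("unknown residue: ", residue)
  aminoAcidMasses()[[residue]] + PHYSICAL_CONSTANTS[["proton"]]
}

#' Qlinker modification mass deltas
#'
#' The crosslink delta is the mass added across a pair of crosslinked
#' lysines: the labeled diacid C15H26N2O5 (one carbon as 13C) minus two
#' waters (two amide bonds formed). The monolink delta (one arm
#' hydrolyzed) is the crosslink delta plus one water. Hydrolysis
#' stoichiometry forces monolink - crosslink = mass(H2O) exactly.
#'
#' @return A data.frame with columns `name`, `deltaMass`, `specificity`,
#'   `category`, rows `crosslink` and `monolink`.
#' @examples
#' round(qlinkerDeltas()$deltaMass, 4) # 279.1664, 297.1770
#' @export
qlinkerDeltas <- function() {
  diacid <- composition("13C" = 1, C = 14, H = 26, N = 2, O = 5)
  water <- composition(H = 2, O = 1)
  xl <- monoisotopicMass(diacid) - 2 * monoisotopicMass(water)
  data.frame(
    name = c("Qlinker-crosslink", "Qlinker-monolink"),
    deltaMass = c(xl, xl + monoisotopicMass(water)),
    specificity = c("K", "K"),
    category = c("crosslink", "monolink"),
    row.names = c("crosslink", "monolink"),
    stringsAsFactors = FALSE
  )
}

#' Standard peptide modifications
#'
#' The fixed/variable modification masses used by the default search
#' configuration, each derived from its elemental composition.
#'
#' @return data.frame with columns `name`, `deltaMass`, `specificity`,
#'   `category`.
#' @export
standardModifications <- function() {
  water <- monoisotopicMass(composition(H = 2, O = 1))
  ammonia <- monoisotopicMass(composition(N = 1, H = 3))
  data.frame(
    name = c("carbamidomethyl", "oxidation", "pyro-glu", "pyro-gln"),
    deltaMass = c(monoisotopicMass(composition(C = 2, H = 3, N = 1, O = 1)),
                  monoisotopicMass(composition(O = 1)),
                  -water, -ammonia),
    specificity = c("C", "M", "E@Nterm", "Q@Nterm"),
    category = "standard",
    stringsAsFactors = FALSE
  )
}

#' m/z tolerance window
#'
#' Symmetric window around a centre m/z. For `unit = "ppm"` the half-width
#' is `center * tol * 1e-6`; for `unit = "Da"` it is `tol` itself. The
#' default extraction tolerance of 0.005 Da corresponds to about 40 ppm at
#' the reporter m/z.
#'
#' @param center Centre m/z.
#' @param tol Positive tolerance value.
#' @param unit `"Da"` or `"ppm"`.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' toleranceWindow(126.127726, 0.005, "Da")
#' toleranceWindow(100, 10, "ppm")
#' @export
toleranceWindow <- function(center, tol, unit = c("Da", "ppm")) {
  unit <- match.arg(unit)
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop("tolerance must be a positive number")
  half <- if (unit == "Da") tol else center * tol * 1e-6
  c(low = center - half, high = center + half)
}

#' Machine-readable table of package mass constants
#'
#' All named mass constants with their compositions, for documentation and
#' fixture generation. Optionally written as TSV.
#'
#' @param file Optional path; when given the table is written as TSV.
#' @return data.frame with columns `name`, `formula`, `value`, `unit`
#'   (invisibly when `file` is given).
#' @export
massConstantsTable <- function(file = NULL) {
  qd <- qlinkerDeltas()
  rp <- reporterMz()
  tab <- data.frame(
    name = c("proton", "electron", "water", "reporter126", "reporter127",
             "qlinker_crosslink", "qlinker_monolink",
             "b1_L", "b1_N", "b1_D"),
    formula = c("", "", "H2O", "C8H16N+", "(13C)C7H16N+",
                "(13C)C14H26N2O5 - 2 H2O", "(13C)C14H26N2O5 - H2O",
                "C6H11NO + H+", "C4H6N2O2 + H+", "C4H5NO3 + H+"),
    value = c(PHYSICAL_CONSTANTS[["proton"]], PHYSICAL_CONSTANTS[["electron"]],
              monoisotopicMass(composition(H = 2, O = 1)),
              rp[["126"]], rp[["127"]],
              qd["crosslink", "deltaMass"], qd["monolink", "deltaMass"],
              b1IonMz("L"), b1IonMz("N"), b1IonMz("D")),
    unit = c("Da", "Da", "Da", "m/z", "m/z", "Da", "Da", "m/z", "m/z", "m/z"),
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
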