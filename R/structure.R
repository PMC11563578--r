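#' Load a structure from PDB or mmCIF
#'
#' Parses the file with \pkg{bio3d}; only the first model of multi-model
#' files is retained and altloc duplicates are resolved to the
#' highest-occupancy conformer.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param structureId Identifier stored in the model (default: file
#'   stem).
#' @return A [StructureModel-class].
#' @export
loadStructure <- function(path, format = c("auto", "pdb", "cif"),
                          structureId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE,
                                         verbose = FALSE)
    else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE),
    error = function(e) stop("failed to parse structure '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty structure: ", path)
  a <- a[a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  a$chain[is.na(a$chain)] <- " "
  if (is.null(a$o)) a$o <- 1
  a$o[is.na(a$o)] <- 1
  ## altloc resolution: keep the highest-occupancy copy of each atom
  keykey <- paste(a$chain, a$resno, a$elety, sep = "\r")
  ord <- order(keykey, -a$o)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(keykey[ord]), , drop = FALSE]
  a <- a[order(a$chain, a$resno), , drop = FALSE]
  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      resid = a$resid, elety = a$elety,
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  atoms <- atoms[is.finite(atoms$x) & is.finite(atoms$y) &
                   is.finite(atoms$z), , drop = FALSE]
  rownames(atoms) <- NULL
  if (is.null(structureId))
    structureId <- tools::file_path_sans_ext(basename(path))
  new("StructureModel", structureId = structureId, atoms = atoms)
}

#' Construct a StructureModel from an atom table
#'
#' For programmatic/toy structures: supply the flat atom data.frame
#' directly.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z`.
#' @param structureId Identifier.
#' @return A [StructureModel-class].
#' @export
StructureModel <- function(atoms, structureId = "model") {
  atoms$resno <- as.integer(atoms$resno)
  new("StructureModel", structureId = structureId,
      atoms = as.data.frame(atoms, stringsAsFactors = FALSE))
}

.findAtom <- function(m, chain, resno, atom) {
  a <- m@atoms
  i <- which(a$chain == chain & a$resno == as.integer(resno) &
               a$elety == atom)
  if (length(i) == 0L) return(NULL)
  unlist(a[i[1L], c("x", "y", "z")])
}

#' Euclidean distance between two atoms
#'
#' @param m A [StructureModel-class].
#' @param a,b Atom selectors: `c(chain, resno, atomName)` (character
#'   vectors of length 3).
#' @return Distance in Angstrom, or `NA` with a warning naming the
#'   missing atom.
#' @examples
#' toy <- StructureModel(data.frame(
#'   chain = "A", resno = c(1, 2), resid = "GLY", elety = "CA",
#'   x = c(0, 3), y = c(0, 4), z = 0))
#' atomDistance(toy, c("A", 1, "CA"), c("A", 2, "CA")) # 5
#' @export
atomDistance <- function(m, a, b) {
  stopifnot(is(m, "StructureModel"), length(a) == 3L, length(b) == 3L)
  pa <- .findAtom(m, a[[1L]], a[[2L]], a[[3L]])
  pb <- .findAtom(m, b[[1L]], b[[2L]], b[[3L]])
  if (is.null(pa) || is.null(pb)) {
    missing <- c(if (is.null(pa)) paste(a, collapse = ":"),
                 if (is.null(pb)) paste(b, collapse = ":"))
    warning("atom(s) not found in structure '", m@structureId, "': ",
            paste(missing, collapse = ", "))
    return(NA_real_)
  }
  sqrt(sum((pa - pb)^2))
}

#' Check a crosslink site pair against a distance restraint
#'
#' Computes the C-alpha to C-alpha distance of the two linked residues
#' and compares it with the maximum crosslinkable distance. Amine
#' -reactive crosslinkers of this spacer length (~10 A extended) can link
#' lysines whose C-alpha atoms are up to about 30 A apart, so distances
#' beyond `maxDist` flag likely conformational differences or
#' false-positive identifications.
#'
#' @param key Crosslink site key (`"protA:resA--protB:resB"`), or a
#'   one-row identification data.frame of type `"xl"`.
#' @param m A [StructureModel-class].
#' @param chainMap Named character vector mapping protein names (as used
#'   in site keys) to chain identifiers.
#' @param maxDist Maximum allowed C-alpha distance in Angstrom
#'   (default 30).
#' @return data.frame: `siteKey`, `distance`, `maxAllowed`, `verdict` in
#'   `{satisfied, violated, unmappable}`.
#' @export
checkCrosslink <- function(key, m, chainMap, maxDist = 30) {
  if (is.data.frame(key)) key <- key$siteKey
  out <- do.call(rbind, lapply(key, function(k) {
    parts <- strsplit(k, "--", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("not a crosslink site key: ", k)
    site <- function(p) {
      prot <- sub(":[0-9]+$", "", p)
      res <- as.integer(sub("^.*:", "", p))
      if (!prot %in% names(chainMap))
        return(NULL)
      list(chain = chainMap[[prot]], res = res)
    }
    s1 <- site(parts[1L]); s2 <- site(parts[2L])
    if (is.null(s1) || is.null(s2))
      return(data.frame(siteKey = k, distance = NA_real_,
                        maxAllowed = maxDist, verdict = "unmappable",
                        stringsAsFactors = FALSE))
    d <- suppressWarnings(
      atomDistance(m, c(s1$chain, s1$res, "CA"), c(s2$chain, s2$res, "CA")))
    verdict <- if (is.na(d)) "unmappable"
      else if (d > maxDist) "violated" else "satisfied"
    data.frame(siteKey = k, distance = d, maxAllowed = maxDist,
               verdict = verdict, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detect salt bridges to a lysine side chain
#'
#' Finds all aspartate OD1/OD2 and glutamate OE1/OE2 oxygens within
#' `cutoff` of the lysine side-chain nitrogen (NZ), sorted by distance.
#' An engaged epsilon-amine reacts poorly with NHS esters, so a salt
#' bridge here suppresses Qlinker modification of the residue.
#'
#' @param m A [StructureModel-class].
#' @param lys `c(chain, resno)` of the lysine.
#' @param cutoff N-O distance cutoff in Angstrom (default 4.0).
#' @return data.frame of partners: `chain`, `resno`, `resid`, `atom`,
#'   `distance`; zero rows when none. `NULL` with a warning when the NZ
#'   atom is absent.
#' @export
detectSaltBridges <- function(m, lys, cutoff = 4.0) {
  stopifnot(is(m, "StructureModel"), length(lys) == 2L)
  nz <- .findAtom(m, lys[[1L]], lys[[2L]], "NZ")
  if (is.null(nz)) {
    warning("lysine side-chain nitrogen ", lys[[1L]], ":", lys[[2L]],
            ":NZ not found in structure '", m@structureId, "'")
    return(NULL)
  }
  a <- m@atoms
  acidic <- (a$resid == "ASP" & a$elety %in% c("OD1", "OD2")) |
    (a$resid == "GLU" & a$elety %in% c("OE1", "OE2"))
  cand <- a[acidic, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), atom = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  d <- sqrt((cand$x - nz[[1L]])^2 + (cand$y - nz[[2L]])^2 +
              (cand$z - nz[[3L]])^2)
  keep <- d <= cutoff
  out <- data.frame(chain = cand$chain[keep], resno = cand$resno[keep],
                    resid = cand$resid[keep], atom = cand$elety[keep],
                    distance = d[keep], stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
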