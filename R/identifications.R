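## Unified identification model: one data.frame row per identified
## spectrum, columns:
##   run, scan, type ("mono"|"xl"), pepA, linkA, protA, resA,
##   pepB, linkB, protB, resB, score, engine, decoy, ambiguous, siteKey
.ID_COLS <- c("run", "scan", "type", "pepA", "linkA", "protA", "resA",
              "pepB", "linkB", "protB", "resB", "score", "engine", "decoy")

.emptyIds <- function() {
  df <- data.frame(run = character(0), scan = integer(0), type = character(0),
    pepA = character(0), linkA = integer(0), protA = character(0),
    resA = integer(0), pepB = character(0), linkB = integer(0),
    protB = character(0), resB = integer(0), score = numeric(0),
    engine = character(0), decoy = logical(0), ambiguous = logical(0),
    siteKey = character(0), stringsAsFactors = FALSE)
  df
}

#' Canonical site key for monolinks and crosslinks
#'
#' A monolink site is one `(protein, residue)`; a crosslink site is an
#' unordered pair, stored in canonical order (lexicographic by protein
#' name, ties broken by residue number), so swapping the alpha and beta
#' peptides yields the same key.
#'
#' @param protA,resA First protein name and residue number.
#' @param protB,resB Second protein/residue (`NA` for monolinks).
#' @return Character vector of keys, `"prot:res"` or
#'   `"protA:resA--protB:resB"`.
#' @examples
#' siteKey("Rpb7", 23, "Rpb4", 80) # "Rpb4:80--Rpb7:23"
#' siteKey("MBP", 313)
#' @export
siteKey <- function(protA, resA, protB = NA, resB = NA) {
  protA <- as.character(protA); protB <- as.character(protB)
  resA <- as.integer(resA); resB <- as.integer(resB)
  n <- max(length(protA), length(protB))
  protA <- rep_len(protA, n); protB <- rep_len(protB, n)
  resA <- rep_len(resA, n); resB <- rep_len(resB, n)
  if (any(is.na(protA) | is.na(resA)))
    stop("protA/resA must be non-missing")
  mono <- is.na(protB) | is.na(resB)
  swap <- !mono & (protB < protA | (protB == protA & resB < resA))
  pa <- ifelse(swap, protB, protA); ra <- ifelse(swap, resB, resA)
  pb <- ifelse(swap, protA, protB); rb <- ifelse(swap, resA, resB)
  ifelse(mono, sprintf("%s:%d", protA, resA),
         sprintf("%s:%d--%s:%d", pa, ra, pb, rb))
}

#' Link class of an identification or site key
#'
#' `monolink` for single sites, `intralink` when both crosslinked residues
#' are in the same protein, `interlink` otherwise.
#'
#' @param key Character vector of site keys (see [siteKey()]).
#' @return Character vector in `{monolink, intralink, interlink}`.
#' @export
linkClass <- function(key) {
  xl <- grepl("--", key, fixed = TRUE)
  out <- ifelse(xl, "interlink", "monolink")
  if (any(xl)) {
    parts <- strsplit(key[xl], "--", fixed = TRUE)
    sameProt <- vapply(parts, function(p) {
      a <- sub(":[0-9]+$", "", p[1L]); b <- sub(":[0-9]+$", "", p[2L])
      a == b
    }, logical(1))
    out[xl][sameProt] <- "intralink"
  }
  out
}

.finishIds <- function(df) {
  df$ambiguous <- if (nrow(df)) FALSE else logical(0)
  df$siteKey <- if (nrow(df))
    siteKey(df$protA, df$resA, df$protB, df$resB) else character(0)
  rownames(df) <- NULL
  df
}

.checkLinkPositions <- function(df, path) {
  bad <- rep(FALSE, nrow(df))
  bad <- bad | is.na(df$linkA) | df$linkA < 1L |
    df$linkA > nchar(df$pepA)
  isXl <- df$type == "xl"
  bad[isXl] <- bad[isXl] | is.na(df$linkB[isXl]) |
    df$linkB[isXl] < 1L | df$linkB[isXl] > nchar(df$pepB[isXl])
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable link positions in '",
            path, "' (rows ", paste(which(bad), collapse = ", "),
            ") were rejected")
  }
  list(ids = df[!bad, , drop = FALSE],
       rejected = data.frame(row = which(bad)))
}

#' Read identifications from search-engine output
#'
#' Two dialects are supported. The interchange TSV is this package's own
#' format with header columns `run, scan, type, pepA, linkA, protA, resA,
#' pepB, linkB, protB, resB, score, engine, decoy` (`type` is `mono` or
#' `xl`; B-columns empty for monolinks). The `plink2_csv` dialect reads
#' pLink2-style CSV with `Title` (dta-style `run.scan.scan.charge`),
#' `Peptide` (`SEQA(posA)-SEQB(posB)` or `SEQ(pos)`), `Proteins`
#' (`NameA(resA)-NameB(resB)/`) and `Score` columns.
#'
#' Rows whose link position falls outside the peptide are rejected with a
#' warning naming the row numbers; parsing continues. Decoy rows are
#' flagged, not dropped.
#'
#' @param path File path.
#' @param dialect `"interchange_tsv"` or `"plink2_csv"`.
#' @return Identification data.frame (may have zero rows); the rejected
#'   row report is attached as attribute `"rejected"`.
#' @export
readIdentifications <- function(path,
                                dialect = c("interchange_tsv", "plink2_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- switch(dialect,
    interchange_tsv = .readInterchangeTsv(path),
    plink2_csv = .readPlink2Csv(path))
  chk <- .checkLinkPositions(df, path)
  out <- .finishIds(chk$ids)
  attr(out, "rejected") <- chk$rejected
  out
}

.readInterchangeTsv <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(.ID_COLS, names(raw))
  if (length(missing) > 0L)
    stop("interchange TSV '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) return(.emptyIds()[, c(.ID_COLS, "ambiguous",
                                              "siteKey")][0, .ID_COLS])
  asint <- function(x) suppressWarnings(as.integer(x))
  data.frame(run = raw$run, scan = asint(raw$scan), type = raw$type,
    pepA = raw$pepA, linkA = asint(raw$linkA), protA = raw$protA,
    resA = asint(raw$resA),
    pepB = ifelse(raw$pepB == "", NA_character_, raw$pepB),
    linkB = asint(raw$linkB),
    protB = ifelse(raw$protB == "", NA_character_, raw$protB),
    resB = asint(raw$resB),
    score = suppressWarnings(as.numeric(raw$score)),
    engine = raw$engine,
    decoy = tolower(raw$decoy) %in% c("true", "t", "1", "yes"),
    stringsAsFactors = FALSE)
}

.readPlink2Csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Title", "Peptide", "Proteins")
  if (!all(need %in% names(raw)))
    stop("pLink2 CSV '", path, "' lacks column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  if (nrow(raw) == 0L) return(.readInterchangeTsv0())
  title <- strsplit(raw$Title, ".", fixed = TRUE)
  run <- vapply(title, function(t) paste(t[seq_len(max(1L, length(t) - 3L))],
                                         collapse = "."), character(1))
  scan <- vapply(title, function(t)
    suppressWarnings(as.integer(t[max(1L, length(t) - 2L)])), integer(1))
  pep <- .parsePlinkPaired(raw$Peptide)
  prot <- .parsePlinkPaired(sub("/+$", "", raw$Proteins))
  data.frame(run = run, scan = scan,
    type = ifelse(is.na(pep$b), "mono", "xl"),
    pepA = pep$a, linkA = pep$posA, protA = prot$a, resA = prot$posA,
    pepB = pep$b, linkB = pep$posB, protB = prot$b, resB = prot$posB,
    score = if ("Score" %in% names(raw))
      suppressWarnings(as.numeric(raw$Score)) else NA_real_,
    engine = "pLink2",
    decoy = if ("Target_Decoy" %in% names(raw))
      raw$Target_Decoy %in% c("0", "decoy", "Decoy") else FALSE,
    stringsAsFactors = FALSE)
}

.readInterchangeTsv0 <- function() {
  df <- .emptyIds()
  df[, .ID_COLS]
}

## "ITEM1(p1)-ITEM2(p2)" or "ITEM(p)" -> components; item may itself
## contain "-" (protein names), so split on ")-" boundaries.
.parsePlinkPaired <- function(x) {
  x <- trimws(x)
  parts <- strsplit(x, ")-", fixed = TRUE)
  one <- function(s) {
    m <- regmatches(s, regexec("^(.*)\\(([0-9]+)\\)?$", s))[[1L]]
    if (length(m) != 3L) return(list(item = NA_character_, pos = NA_integer_))
    list(item = m[2L], pos = as.integer(m[3L]))
  }
  a <- character(length(x)); posA <- integer(length(x))
  b <- rep(NA_character_, length(x)); posB <- rep(NA_integer_, length(x))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    fa <- one(if (length(p) > 1L) paste0(p[1L], ")") else p[1L])
    a[i] <- fa$item; posA[i] <- fa$pos
    if (length(p) > 1L) {
      fb <- one(p[2L])
      b[i] <- fb$item; posB[i] <- fb$pos
    }
  }
  list(a = a, posA = posA, b = b, posB = posB)
}

#' Write identifications as interchange TSV
#'
#' @param ids Identification data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeIdentifications <- function(ids, path) {
  out <- ids[, .ID_COLS]
  out$decoy <- ifelse(out$decoy, "true", "false")
  for (cc in c("pepB", "protB")) out[[cc]][is.na(out[[cc]])] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Combine identifications from several search engines
#'
#' One record is kept per `(run, scan)`: when two engines identify the
#' same scan with the same site key the records are collapsed into one
#' whose `engine` field lists both (e.g. `"Nexus+pLink2"`); conflicting
#' site keys for one scan are all kept and flagged `ambiguous`. The
#' operation is idempotent.
#'
#' @param ... Identification data.frames (or one list of them).
#' @return Merged identification data.frame.
#' @export
mergeEngines <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.data.frame(sets[[1L]]) == FALSE)
    sets <- sets[[1L]]
  all <- do.call(rbind, lapply(sets, function(d)
    d[, c(.ID_COLS, "ambiguous", "siteKey")]))
  if (is.null(all) || nrow(all) == 0L) return(.finishIds(.emptyIds()[, .ID_COLS]))
  splitEngines <- function(e) sort(unique(unlist(strsplit(e, "+", fixed = TRUE))))
  key <- paste(all$run, all$scan, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    grp <- all[idx, , drop = FALSE]
    out <- do.call(rbind, lapply(split(grp, grp$siteKey), function(g) {
      rec <- g[1L, , drop = FALSE]
      rec$engine <- paste(splitEngines(g$engine), collapse = "+")
      rec$score <- suppressWarnings(max(g$score, na.rm = TRUE))
      rec
    }))
    out$ambiguous <- length(unique(grp$siteKey)) > 1L
    out
  })
  merged <- do.call(rbind, pieces)
  merged <- merged[order(merged$run, merged$scan, merged$siteKey), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of amino acid sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
readProteinFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Verify identification sites against protein sequences
#'
#' Checks that every referenced protein exists in the FASTA and that the
#' linked residue at the stated position is the expected letter
#' (default lysine, the Qlinker target).
#'
#' @param ids Identification data.frame.
#' @param proteins Named sequence vector from [readProteinFasta()].
#' @param expected Expected residue letter at link sites.
#' @return data.frame with one row per checked site: `row`, `protein`,
#'   `residue`, `found`, `ok`.
#' @export
verifySites <- function(ids, proteins, expected = "K") {
  one <- function(row, prot, res) {
    if (is.na(prot)) return(NULL)
    found <- if (!prot %in% names(proteins) ||
                 res > nchar(proteins[[prot]])) NA_character_
             else substr(proteins[[prot]], res, res)
    data.frame(row = row, protein = prot, residue = res, found = found,
               ok = !is.na(found) && found == expected,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(ids))) {
    out[[length(out) + 1L]] <- one(i, ids$protA[i], ids$resA[i])
    out[[length(out) + 1L]] <- one(i, ids$protB[i], ids$resB[i])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(row = integer(0),
    protein = character(0), residue = integer(0), found = character(0),
    ok = logical(0), stringsAsFactors = FALSE)
  res
}
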