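## Independent oracles used by the tests. These deliberately do NOT call
## package internals: residue masses are frozen from the ExPASy/Unimod
## tables, and algorithms are written as naive brute force.

## Monoisotopic residue masses (ExPASy), independent of the package table.
ORACLE_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276

## Brute-force b/y ladder: builds every prefix/suffix explicitly.
oracleLadder <- function(sequence, mods = NULL, charge = 1) {
  aa <- strsplit(sequence, "")[[1]]
  if (is.null(mods)) mods <- numeric(length(aa))
  n <- length(aa)
  b <- y <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    b[i] <- sum(ORACLE_RESIDUE[aa[1:i]]) + sum(mods[1:i])
    suff <- (i + 1):n
    y[n - i] <- sum(ORACLE_RESIDUE[aa[suff]]) + sum(mods[suff]) +
      ORACLE_WATER
  }
  list(b = (b + charge * ORACLE_PROTON) / charge,
       y = (y + charge * ORACLE_PROTON) / charge)
}

## Gaussian elimination by hand on the 2x2 purity system (no solve()).
oracleCorrect2x2 <- function(I126, I127, M) {
  ## eliminate A127 from the first equation
  f <- M[1, 2] / M[2, 2]
  a126 <- (I126 - I127 * f) / (M[1, 1] - M[2, 1] * f)
  g <- M[2, 1] / M[1, 1]
  a127 <- (I127 - I126 * g) / (M[2, 2] - M[1, 2] * g)
  c(a126, a127)
}

## Build the MS2 spectrum implied by an identification: the complete b/y
## ladder (charge 1) plus reporter peaks, optionally dropping fragments.
ladderSpectrum <- function(id, scan = id$scan, reporters = c(1000, 1000),
                          dropLabels = character(0), extraMz = numeric(0),
                          extraInt = numeric(0), fragInt = 500) {
  fr <- fragmentsForId(id, charges = 1L)
  keep <- !(fr$label %in% dropLabels | paste0(fr$peptide, ":", fr$label)
            %in% dropLabels)
  fr <- fr[keep, , drop = FALSE]
  rmz <- reporterMz()
  Spectrum(id$run, scan,
           mz = c(unname(rmz), fr$mz, extraMz),
           intensity = c(reporters, rep(fragInt, nrow(fr)), extraInt))
}

## Minimal interchange TSV written to a temp file.
writeIdsFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- c("run", "scan", "type", "pepA", "linkA", "protA", "resA",
              "pepB", "linkB", "protB", "resB", "score", "engine", "decoy")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

## A toy structure with exactly placed atoms.
toyStructure <- function() {
  StructureModel(data.frame(
    chain = c("A", "A", "A", "A", "B", "B"),
    resno = c(15L, 15L, 42L, 42L, 7L, 7L),
    resid = c("LYS", "LYS", "ASP", "ASP", "GLU", "GLU"),
    elety = c("CA", "NZ", "CA", "OD2", "CA", "OE2"),
    x = c(0, 2, 10, 5.8, 0, 2),
    y = c(0, 0, 0, 0, 20, 20),
    z = c(0, 0, 0, 0, 0, 3),
    stringsAsFactors = FALSE), structureId = "toy")
}
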