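#' Path to the bundled synthetic toy proteome
#'
#' Fifteen short synthetic protein sequences (named after RNA polymerase
#' II subunits and general transcription factors so that simulated site
#' keys look realistic) with tryptic K/R sites every 6-12 residues. These
#' sequences are invented fixtures, not the real proteins.
#'
#' @return File path of the FASTA.
#' @export
syntheticProteomeFasta <- function() {
  system.file("extdata", "synthetic_proteome.fasta",
              package = "QlinkerQuant", mustWork = TRUE)
}

#' Lysine positions available in a proteome
#'
#' @param proteome Named sequence vector ([readProteinFasta()]); default
#'   the bundled synthetic proteome.
#' @return data.frame with `prot` and `res` of every lysine.
#' @export
availableLysines <- function(proteome = readProteinFasta(
                               syntheticProteomeFasta())) {
  out <- do.call(rbind, lapply(names(proteome), function(p) {
    pos <- gregexpr("K", proteome[[p]], fixed = TRUE)[[1L]]
    pos <- pos[pos > 0L]
    if (length(pos) == 0L) return(NULL)
    data.frame(prot = p, res = as.integer(pos), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Deterministic panel of simulation sites
#'
#' Picks monolink, intralink and interlink sites from the proteome's
#' lysines in a fixed deterministic order (no RNG), assigning the given
#' true log2(127/126) ratios cyclically.
#'
#' @param nMono,nIntra,nInter Numbers of sites of each link class.
#' @param trueLog2 True site ratios, recycled over the sites.
#' @param nSpectra Spectra per site (recycled).
#' @param proteome Named sequence vector.
#' @return Site data.frame for [simConfig()]: `protA`, `resA`, `protB`,
#'   `resB`, `trueLog2`, `nSpectra`.
#' @export
makeSitePanel <- function(nMono = 0L, nIntra = 0L, nInter = 0L,
                          trueLog2 = 0, nSpectra = 5L,
                          proteome = readProteinFasta(
                            syntheticProteomeFasta())) {
  lys <- availableLysines(proteome)
  byProt <- split(lys$res, lys$prot)
  prots <- names(byProt)
  rows <- list()
  ## monolinks: first lysine of successive proteins, then second, ...
  k <- 0L
  for (i in seq_len(nMono)) {
    p <- prots[(k %% length(prots)) + 1L]
    depth <- k %/% length(prots) + 1L
    if (depth > length(byProt[[p]])) stop("not enough lysines for panel")
    rows[[length(rows) + 1L]] <- data.frame(protA = p,
      resA = byProt[[p]][depth], protB = NA_character_, resB = NA_integer_,
      stringsAsFactors = FALSE)
    k <- k + 1L
  }
  ## intralinks: consecutive lysine pairs within a protein
  k <- 0L
  for (i in seq_len(nIntra)) {
    p <- prots[(k %% length(prots)) + 1L]
    off <- k %/% length(prots)
    ks <- byProt[[p]]
    if (off + 2L > length(ks)) stop("not enough lysines for panel")
    rows[[length(rows) + 1L]] <- data.frame(protA = p, resA = ks[off + 1L],
      protB = p, resB = ks[off + 2L], stringsAsFactors = FALSE)
    k <- k + 1L
  }
  ## interlinks: lysines of adjacent protein pairs
  k <- 0L
  for (i in seq_len(nInter)) {
    p1 <- prots[(k %% (length(prots) - 1L)) + 1L]
    p2 <- prots[(k %% (length(prots) - 1L)) + 2L]
    off <- k %/% (length(prots) - 1L) + 1L
    if (off > length(byProt[[p1]]) || off > length(byProt[[p2]]))
      stop("not enough lysines for panel")
    rows[[length(rows) + 1L]] <- data.frame(protA = p1,
      resA = byProt[[p1]][off], protB = p2, resB = byProt[[p2]][off],
      stringsAsFactors = FALSE)
    k <- k + 1L
  }
  sites <- do.call(rbind, rows)
  sites$trueLog2 <- rep_len(trueLog2, nrow(sites))
  sites$nSpectra <- rep_len(as.integer(nSpectra), nrow(sites))
  sites
}

#' Simulation configuration
#'
#' Defines the forward model for synthetic qCLMS data. Per spectrum, the
#' true 126-channel intensity is log-normal; the site's true
#' log2(127/126) ratio plus Gaussian per-spectrum noise (SD
#' `ratioNoiseSd`, in log2 units) sets the 127 channel; the true channel
#' pair is then forward-mixed through the purity matrix into the observed
#' reporter peaks, and the peptide's b/y ladder and uniform background
#' noise peaks complete the spectrum.
#'
#' @param sites Site data.frame (`protA`, `resA`, `protB`, `resB`,
#'   `trueLog2`, optional per-site `nSpectra`), e.g. from
#'   [makeSitePanel()].
#' @param nSpectra Default spectra per site when `sites` has no
#'   `nSpectra` column.
#' @param seed Integer random seed; the whole dataset is a deterministic
#'   function of the config.
#' @param baseIntensityMeanLog,baseIntensitySdLog Log-normal parameters
#'   (natural-log space) of the true 126-channel intensity.
#' @param ratioNoiseSd Per-spectrum SD of the log2 ratio around the site
#'   truth (default 0.25, the spread seen in well-behaved mixing data).
#' @param purityMatrix 2x2 forward-mixing matrix.
#' @param noisePeaks Number of background noise peaks per spectrum.
#' @param noiseIntensityMeanLog,noiseIntensitySdLog Log-normal
#'   parameters of noise-peak intensity.
#' @param ladderCompleteness Probability that each theoretical fragment
#'   ion is emitted (1 = complete ladder).
#' @param reporterDropout Probability that a spectrum loses one reporter
#'   channel entirely.
#' @param interferenceFraction Probability that a spectrum receives a
#'   spurious peak inside the 126 reporter window (for interference-scan
#'   tests); background noise otherwise avoids both reporter windows.
#' @param proteome Named protein sequences the peptides are cut from.
#' @return A `SimConfig` list (validated).
#' @export
simConfig <- function(sites,
                      nSpectra = 5L,
                      seed = 1L,
                      baseIntensityMeanLog = log(5e4),
                      baseIntensitySdLog = 0.6,
                      ratioNoiseSd = 0.25,
                      purityMatrix = defaultPurityMatrix(),
                      noisePeaks = 20L,
                      noiseIntensityMeanLog = log(400),
                      noiseIntensitySdLog = 0.8,
                      ladderCompleteness = 1.0,
                      reporterDropout = 0,
                      interferenceFraction = 0,
                      proteome = readProteinFasta(
                        syntheticProteomeFasta())) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 1L,
            all(c("protA", "resA") %in% names(sites)))
  if (!"protB" %in% names(sites)) sites$protB <- NA_character_
  if (!"resB" %in% names(sites)) sites$resB <- NA_integer_
  if (!"trueLog2" %in% names(sites)) sites$trueLog2 <- 0
  if (!"nSpectra" %in% names(sites))
    sites$nSpectra <- as.integer(nSpectra)
  probs <- c(ladderCompleteness, reporterDropout, interferenceFraction)
  if (any(probs < 0 | probs > 1))
    stop("ladderCompleteness, reporterDropout and interferenceFraction ",
         "must be probabilities in [0, 1]")
  if (any(sites$nSpectra < 0) || noisePeaks < 0)
    stop("counts must be >= 0")
  if (ratioNoiseSd < 0 || baseIntensitySdLog < 0)
    stop("dispersions must be >= 0")
  for (i in seq_len(nrow(sites))) {
    .trypticPeptide(proteome, sites$protA[i], sites$resA[i])  # validates
    if (!is.na(sites$protB[i]))
      .trypticPeptide(proteome, sites$protB[i], sites$resB[i])
  }
  cfg <- list(sites = sites, seed = as.integer(seed),
              baseIntensityMeanLog = baseIntensityMeanLog,
              baseIntensitySdLog = baseIntensitySdLog,
              ratioNoiseSd = ratioNoiseSd, purityMatrix = purityMatrix,
              noisePeaks = as.integer(noisePeaks),
              noiseIntensityMeanLog = noiseIntensityMeanLog,
              noiseIntensitySdLog = noiseIntensitySdLog,
              ladderCompleteness = ladderCompleteness,
              reporterDropout = reporterDropout,
              interferenceFraction = interferenceFraction,
              proteome = proteome)
  class(cfg) <- "SimConfig"
  cfg
}

## Tryptic peptide containing a given (lysine) residue: cut after the
## previous K/R and after the next K/R (the linked lysine itself blocks
## cleavage). Returns sequence and 1-based link position within it.
.trypticPeptide <- function(proteome, prot, res) {
  if (!prot %in% names(proteome))
    stop("protein '", prot, "' not in proteome")
  s <- proteome[[prot]]
  if (res < 1L || res > nchar(s))
    stop("residue ", res, " outside protein '", prot, "'")
  if (substr(s, res, res) != "K")
    stop("residue ", prot, ":", res, " is not a lysine")
  cuts <- gregexpr("[KR]", s)[[1L]]
  cuts <- cuts[cuts > 0L]
  prev <- cuts[cuts < res]
  nxt <- cuts[cuts > res]
  start <- if (length(prev)) max(prev) + 1L else 1L
  end <- if (length(nxt)) min(nxt) else nchar(s)
  list(sequence = substr(s, start, end), link = res - start + 1L)
}

#' Simulate a complete qCLMS run
#'
#' Generates, fully determined by the config seed, an MS2 spectrum for
#' every (site, replicate): true channel intensities honouring the
#' site's log2(127/126) ratio, forward-mixed through the purity matrix
#' into reporter peaks at the theoretical reporter m/z, the (modified)
#' peptide b/y ladder, and background noise peaks, together with the
#' matching identification table and the ground truth.
#'
#' @param cfg A `SimConfig` from [simConfig()].
#' @param runId Run identifier.
#' @param engine Engine name written into the identifications.
#' @return List with `run` ([SpectraRun-class]), `ids` (identification
#'   data.frame) and `truth` (list: `sites` with `siteKey`, `linkClass`,
#'   `trueLog2`, `nSpectra`; `spectra` with per-scan true `A126`/`A127`).
#' @export
simulateRun <- function(cfg, runId = "sim", engine = "Nexus") {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  rmz <- reporterMz()
  rwin <- rbind(toleranceWindow(rmz[["126"]], 0.01, "Da"),
                toleranceWindow(rmz[["127"]], 0.01, "Da"))
  qd <- qlinkerDeltas()
  scan <- 0L
  specs <- list(); idRows <- list(); truthRows <- list()
  for (i in seq_len(nrow(cfg$sites))) {
    st <- cfg$sites[i, ]
    isXl <- !is.na(st$protB)
    pepA <- .trypticPeptide(cfg$proteome, st$protA, st$resA)
    pepB <- if (isXl) .trypticPeptide(cfg$proteome, st$protB, st$resB)
            else NULL
    id0 <- data.frame(run = runId, scan = 0L,
      type = if (isXl) "xl" else "mono",
      pepA = pepA$sequence, linkA = pepA$link, protA = st$protA,
      resA = st$resA,
      pepB = if (isXl) pepB$sequence else NA_character_,
      linkB = if (isXl) pepB$link else NA_integer_,
      protB = if (isXl) st$protB else NA_character_,
      resB = if (isXl) st$resB else NA_integer_,
      score = 100, engine = engine, decoy = FALSE,
      stringsAsFactors = FALSE)
    frTheo <- fragmentsForId(id0, charges = 1L)
    precMass <- if (isXl)
      peptideMass(pepA$sequence) + peptideMass(pepB$sequence) +
        qd["crosslink", "deltaMass"]
    else peptideMass(pepA$sequence, qd["monolink", "deltaMass"])
    z <- 3L
    precMz <- (precMass + z * PHYSICAL_CONSTANTS[["proton"]]) / z
    for (j in seq_len(st$nSpectra)) {
      scan <- scan + 1L
      A126 <- stats::rlnorm(1L, cfg$baseIntensityMeanLog,
                            cfg$baseIntensitySdLog)
      eps <- if (cfg$ratioNoiseSd > 0)
        stats::rnorm(1L, 0, cfg$ratioNoiseSd) else 0
      A127 <- A126 * 2^(st$trueLog2 + eps)
      A <- c(A126, A127)
      I <- as.numeric(cfg$purityMatrix %*% A)
      ## dropout: the reporter peak of one channel is simply not detected
      dropped <- cfg$reporterDropout > 0 &&
        stats::runif(1L) < cfg$reporterDropout
      if (dropped) I[sample.int(2L, 1L)] <- 0
      mzs <- c(); ints <- c()
      keepRep <- I > 0
      mzs <- c(mzs, unname(rmz)[keepRep])
      ints <- c(ints, I[keepRep])
      keepFrag <- if (cfg$ladderCompleteness >= 1) rep(TRUE, nrow(frTheo))
        else stats::runif(nrow(frTheo)) < cfg$ladderCompleteness
      nf <- sum(keepFrag)
      if (nf > 0L) {
        mzs <- c(mzs, frTheo$mz[keepFrag])
        ints <- c(ints, stats::runif(nf, 0.05, 0.4) * sum(A))
      }
      if (cfg$noisePeaks > 0L) {
        nm <- numeric(0)
        while (length(nm) < cfg$noisePeaks) {
          cand <- stats::runif(cfg$noisePeaks - length(nm), 100, 1500)
          inRep <- (cand >= rwin[1L, 1L] & cand <= rwin[1L, 2L]) |
                   (cand >= rwin[2L, 1L] & cand <= rwin[2L, 2L])
          nm <- c(nm, cand[!inRep])
        }
        mzs <- c(mzs, nm)
        ints <- c(ints, stats::rlnorm(cfg$noisePeaks,
                                      cfg$noiseIntensityMeanLog,
                                      cfg$noiseIntensitySdLog))
      }
      if (cfg$interferenceFraction > 0 &&
          stats::runif(1L) < cfg$interferenceFraction) {
        mzs <- c(mzs, 126.128)
        ints <- c(ints, stats::rlnorm(1L, cfg$noiseIntensityMeanLog,
                                      cfg$noiseIntensitySdLog))
      }
      specs[[scan]] <- Spectrum(runId, scan, mz = mzs, intensity = ints,
                                msLevel = 2L, precursorMz = precMz,
                                precursorCharge = z,
                                retentionTime = 10 * scan)
      idr <- id0; idr$scan <- scan
      idRows[[scan]] <- idr
      truthRows[[scan]] <- data.frame(scan = scan,
        siteKey = siteKey(st$protA, st$resA, st$protB, st$resB),
        A126 = A[[1L]], A127 = A[[2L]], dropped = dropped,
        stringsAsFactors = FALSE)
    }
  }
  ids <- .finishIds(do.call(rbind, idRows))
  truthSites <- data.frame(
    siteKey = siteKey(cfg$sites$protA, cfg$sites$resA,
                      cfg$sites$protB, cfg$sites$resB),
    trueLog2 = cfg$sites$trueLog2,
    nSpectra = cfg$sites$nSpectra,
    stringsAsFactors = FALSE)
  truthSites$linkClass <- linkClass(truthSites$siteKey)
  list(run = SpectraRun(runId, specs), ids = ids,
       truth = list(sites = truthSites,
                    spectra = do.call(rbind, truthRows)))
}

#' Simulate a label-swap experiment pair
#'
#' Two runs with swapped channel assignment: a site genuinely changed
#' between the biological samples shows anti-correlated log2(126/127)
#' ratios in the two experiments, unchanged sites are centred at 0 in
#' both. Ratios are given in the log2(126/127) orientation (the swap
#' convention); signs of the planted effects alternate across changed
#' sites.
#'
#' @param cfg A `SimConfig`; its sites' `trueLog2` column is overridden.
#' @param changed Logical vector over sites (or integer indices) marking
#'   changed sites.
#' @param effect Absolute planted |log2(126/127)| effect (default 1.5).
#' @return List with `exp1`, `exp2` (each as [simulateRun()]) and
#'   `truth` (data.frame: `siteKey`, `changed`, `log2Exp1`, `log2Exp2`,
#'   orientation 126/127).
#' @export
simulateSwap <- function(cfg, changed = logical(nrow(cfg$sites)),
                         effect = 1.5) {
  stopifnot(inherits(cfg, "SimConfig"))
  n <- nrow(cfg$sites)
  if (is.numeric(changed)) changed <- seq_len(n) %in% changed
  stopifnot(length(changed) == n)
  sign <- rep_len(c(1, -1), n)
  d1 <- ifelse(changed, sign * effect, 0)   # log2(126/127), experiment I
  d2 <- -d1                                 # swapped labels
  mk <- function(delta, seed, runId) {
    c2 <- cfg
    c2$sites$trueLog2 <- -delta  # simulateRun truth is log2(127/126)
    c2$seed <- seed
    simulateRun(c2, runId = runId)
  }
  exp1 <- mk(d1, cfg$seed, "swap_expI")
  exp2 <- mk(d2, cfg$seed + 1L, "swap_expII")
  truth <- data.frame(
    siteKey = siteKey(cfg$sites$protA, cfg$sites$resA,
                      cfg$sites$protB, cfg$sites$resB),
    changed = changed, log2Exp1 = d1, log2Exp2 = d2,
    stringsAsFactors = FALSE)
  list(exp1 = exp1, exp2 = exp2, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the spectra (JSON fixture format and optionally mzML), the
#' identification interchange TSV and the ground-truth site TSV.
#'
#' @param sim Result of [simulateRun()].
#' @param dir Output directory.
#' @param prefix File prefix.
#' @param mzml Also write mzML (default FALSE).
#' @return Named character vector of written paths, invisibly.
#' @export
writeSimulatedRun <- function(sim, dir = ".", prefix = "sim",
                              mzml = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    spectra = writeSpectraJSON(sim$run,
      file.path(dir, paste0(prefix, "_spectra.json"))),
    ids = writeIdentifications(sim$ids,
      file.path(dir, paste0(prefix, "_ids.tsv"))))
  utils::write.table(sim$truth$sites,
    file.path(dir, paste0(prefix, "_truth.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  if (mzml)
    paths <- c(paths, mzml = writeSpectraMzML(sim$run,
      file.path(dir, paste0(prefix, ".mzML"))))
  invisible(paths)
}
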