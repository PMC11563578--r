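test_that("reporter extraction sums peaks in the channel window", {
  s <- Spectrum("r", 1L, mz = c(126.1260, 126.1277, 126.1290, 300),
                intensity = c(2000, 1000, 500, 9))
  r <- extractReporters(s)
  ## 126.1260 is 0.0017 away, 126.1290 is 0.0013 away: all three summed
  expect_equal(r$I126, 3500)
  expect_equal(r$I127, 0)
  expect_equal(r$status, "missing127")
  expect_equal(extractReporters(s, method = "max")$I126, 2000)
  ## peakless spectrum
  r0 <- extractReporters(Spectrum("r", 2L))
  expect_equal(c(r0$I126, r0$I127), c(0, 0))
  expect_equal(r0$status, "both_missing")
  ## single-channel case
  s1 <- Spectrum("r", 3L, mz = 126.1277, intensity = 5000)
  expect_equal(extractReporters(s1)$I126, 5000)
})

test_that("impurity correction matches the elimination oracle", {
  M <- defaultPurityMatrix()
  r <- correctImpurity(c(1000, 1000), M)
  or <- oracleCorrect2x2(1000, 1000, M)
  expect_equal(c(r$A126, r$A127), or, tolerance = 1e-10)
  expect_equal(r$A126, 1090.96, tolerance = 1e-4)
  expect_equal(r$A127, 991.06, tolerance = 1e-4)
  ## identity matrix leaves intensities unchanged
  rid <- correctImpurity(c(123, 456), diag(2))
  expect_equal(c(rid$A126, rid$A127), c(123, 456))
  ## forward-mix then correct recovers the truth
  A <- c(500, 2000)
  I <- as.numeric(M %*% A)
  back <- correctImpurity(I, M)
  expect_equal(c(back$A126, back$A127), A, tolerance = 1e-9)
  expect_error(correctImpurity(c(1, 1), matrix(c(1, 1, 1, 1), 2)),
               "singular")
})

test_that("negative corrected intensities are flagged, not clamped", {
  ## heavy observed 127 with tiny 126 drives A126 negative
  r <- correctImpurity(c(1, 10000))
  expect_equal(r$status, "nonpositive_after_correction")
  expect_true(is.na(log2Ratio(list(A126 = -5, A127 = 10))))
})

test_that("log2 ratio handles orientation and guards", {
  expect_equal(log2Ratio(c(1000, 1000)), 0)
  expect_equal(log2Ratio(c(200, 800), "127/126"), 2)
  expect_equal(log2Ratio(c(200, 800), "126/127"), -2)
  expect_true(is.na(log2Ratio(c(0, 800))))
})

test_that("site aggregation groups by canonical key", {
  rec <- data.frame(
    siteKey = c("A:10--B:5", siteKey("B", 5, "A", 10), "C:1"),
    log2Ratio = c(1, 3, 0.5),
    engine = c("Nexus", "pLink2", "Nexus"),
    stringsAsFactors = FALSE)
  agg <- aggregateSites(rec)
  xl <- agg[agg$siteKey == "A:10--B:5", ]
  expect_equal(xl$nSpectra, 2L)
  expect_equal(xl$meanLog2, 2)
  expect_equal(xl$engines, "Nexus+pLink2")
  expect_equal(xl$linkClass, "interlink")
  ## permutation invariance and bounds
  set.seed(9)
  vals <- rnorm(7)
  r1 <- data.frame(siteKey = "X:1", log2Ratio = vals, engine = "N")
  r2 <- r1[sample(7), ]
  expect_equal(aggregateSites(r1)$meanLog2, aggregateSites(r2)$meanLog2)
  expect_true(aggregateSites(r1)$meanLog2 >= min(vals) &&
                aggregateSites(r1)$meanLog2 <= max(vals))
})

test_that("recentering shifts only the selected group", {
  sites <- data.frame(siteKey = c("TBP:1--TBP:5", "TBP:2--TBP:9", "A:1--B:2"),
                      linkClass = c("intralink", "intralink", "interlink"),
                      nSpectra = 1L, meanLog2 = c(0, 0.4, 1),
                      sdLog2 = NA_real_, engines = "N",
                      stringsAsFactors = FALSE)
  sel <- grepl("^TBP", sites$siteKey)
  out <- recenterSites(sites, sel, mode = "target", value = -0.5)
  expect_equal(attr(out, "shift"), -0.5 - 0.2)  # median of (0, 0.4) = 0.2
  expect_equal(out$meanLog2[3], 1)              # untouched
  expect_equal(median(out$meanLog2[sel]), -0.5)
  ## already-centred group is unchanged under matching target
  again <- recenterSites(out, sel, mode = "target", value = -0.5)
  expect_equal(again$meanLog2, out$meanLog2)
  ## fixed offset mode
  off <- recenterSites(sites, sel, mode = "offset", value = -0.5)
  expect_equal(off$meanLog2[sel], c(-0.5, -0.1))
  expect_error(recenterSites(sites, rep(FALSE, 3)), "no site")
})

test_that("interference scan counts spectra with in-window peaks", {
  mk <- function(scan, mzv) Spectrum("r", scan, mz = mzv,
                                     intensity = rep(10, length(mzv)))
  run <- SpectraRun("r", list(
    mk(1, c(126.128, 500)),   # hit at 126
    mk(2, c(126.128, 126.129)),  # two peaks, still one spectrum
    mk(3, 127.131),           # hit at 127
    mk(4, 500),               # no hit
    mk(5, numeric(0))))       # empty
  res <- interferenceScan(run, targets = c(126.127726, 127.131081),
                          tolPpm = 40)
  expect_equal(res$count, c(2L, 1L))
  expect_equal(res$percent, c(40, 20))
  expect_warning(res0 <- interferenceScan(SpectraRun("e", list())),
                 "empty run")
  expect_equal(res0$count, c(0L, 0L))
  expect_true(all(is.na(res0$percent)))
})

test_that("end-to-end quantification recovers noise-free ratios exactly", {
  sites <- makeSitePanel(nMono = 1, nIntra = 1, nInter = 1,
                         trueLog2 = c(0, 1, -2), nSpectra = 3)
  cfg <- simConfig(sites, seed = 2, ratioNoiseSd = 0, noisePeaks = 0,
                   reporterDropout = 0)
  sim <- simulateRun(cfg)
  rec <- quantifySpectra(sim$run, sim$ids)
  agg <- aggregateSites(rec)
  m <- merge(agg, sim$truth$sites, by = "siteKey")
  expect_equal(m$meanLog2, m$trueLog2, tolerance = 1e-9)
  expect_equal(m$linkClass.x, m$linkClass.y)
  ## orientation swap negates ratios
  rec2 <- quantifySpectra(sim$run, sim$ids, orientation = "126/127")
  expect_equal(rec2$log2Ratio, -rec$log2Ratio, tolerance = 1e-12)
  ## unmatched identifications produce a warning, not an error
  ids2 <- sim$ids
  ids2$scan[1] <- 9999L
  expect_warning(quantifySpectra(sim$run, ids2), "without a matching scan")
})
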