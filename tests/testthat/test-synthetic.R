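test_that("simulation is a deterministic function of the seed", {
  sites <- makeSitePanel(nMono = 2, nInter = 1, trueLog2 = c(0, 1, -1),
                         nSpectra = 3)
  cfg <- simConfig(sites, seed = 99)
  a <- simulateRun(cfg)
  b <- simulateRun(cfg)
  expect_identical(lapply(spectra(a$run), peakMatrix),
                   lapply(spectra(b$run), peakMatrix))
  expect_identical(a$ids, b$ids)
  expect_identical(a$truth, b$truth)
  c2 <- simulateRun(simConfig(sites, seed = 100))
  expect_false(identical(lapply(spectra(a$run), peakMatrix),
                         lapply(spectra(c2$run), peakMatrix)))
})

test_that("invalid configurations fail before generation", {
  sites <- makeSitePanel(nMono = 1)
  expect_error(simConfig(sites, reporterDropout = 1.5), "probabilities")
  expect_error(simConfig(sites, ladderCompleteness = -0.1), "probabilities")
  expect_error(simConfig(sites, ratioNoiseSd = -1), ">= 0")
  bad <- sites; bad$resA[1] <- bad$resA[1] + 1L
  expect_error(simConfig(bad), "not a lysine")
  bad2 <- sites; bad2$protA[1] <- "NoSuchProt"
  expect_error(simConfig(bad2), "not in proteome")
})

test_that("noise-free forward model is inverted exactly by the pipeline", {
  sites <- makeSitePanel(nMono = 1, nIntra = 1, trueLog2 = 0, nSpectra = 4)
  cfg <- simConfig(sites, seed = 3, ratioNoiseSd = 0, noisePeaks = 0)
  sim <- simulateRun(cfg)
  rec <- quantifySpectra(sim$run, sim$ids)
  expect_true(all(abs(rec$log2Ratio) < 1e-9))
  ## per-spectrum truth is recovered through the impurity correction
  m <- merge(rec, sim$truth$spectra, by = "scan")
  expect_equal(m$A126.x, m$A126.y, tolerance = 1e-6)
  expect_equal(m$A127.x, m$A127.y, tolerance = 1e-6)
})

test_that("site-mean recovery stays within sampling error at n = 50", {
  sites <- makeSitePanel(nMono = 3, nIntra = 1, nInter = 1,
                         trueLog2 = c(-2, 0, 2, -1, 1), nSpectra = 50)
  cfg <- simConfig(sites, seed = 17)
  sim <- simulateRun(cfg)
  agg <- aggregateSites(quantifySpectra(sim$run, sim$ids))
  m <- merge(agg, sim$truth$sites, by = "siteKey")
  se <- cfg$ratioNoiseSd / sqrt(m$nSpectra.y)
  expect_true(all(abs(m$meanLog2 - m$trueLog2) <= 3 * se))
})

test_that("simulated spectra carry valid ladders and identifications", {
  sites <- makeSitePanel(nMono = 1, nInter = 1, trueLog2 = 0, nSpectra = 1)
  cfg <- simConfig(sites, seed = 8)
  sim <- simulateRun(cfg)
  v <- verifySites(sim$ids, cfg$proteome)
  expect_true(all(v$ok))
  ## complete emitted ladder passes the spectrum-validation rule
  for (i in seq_len(nrow(sim$ids))) {
    s <- getSpectrum(sim$run, sim$ids$scan[i])
    rep_ <- validateSpectrum(sim$ids[i, ], s, charges = 1L)
    expect_true(rep_$pass)
  }
})

test_that("reporter dropout empties one channel", {
  sites <- makeSitePanel(nMono = 1, trueLog2 = 0, nSpectra = 30)
  cfg <- simConfig(sites, seed = 21, reporterDropout = 1)
  sim <- simulateRun(cfg)
  rec <- quantifySpectra(sim$run, sim$ids)
  expect_true(all(rec$status %in% c("missing126", "missing127")))
  expect_true(all(is.na(rec$log2Ratio)))
})

test_that("interference plants appear at the requested rate", {
  sites <- makeSitePanel(nMono = 1, trueLog2 = 0, nSpectra = 40)
  ## no reporter ions in the way: drop them via dropout of both? instead,
  ## scan a noise-only target far from the reporters for the baseline
  cfg0 <- simConfig(sites, seed = 5, interferenceFraction = 0)
  run0 <- simulateRun(cfg0)$run
  base <- interferenceScan(run0, targets = 126.128, tolPpm = 40)
  expect_equal(base$count, 40L)  # reporter 126 peak itself is in-window
  ## planted interference on a reporter-free target window
  cfg1 <- simConfig(sites, seed = 5, interferenceFraction = 0.5)
  run1 <- simulateRun(cfg1)$run
  ## count spectra with >1 peak in the 126 window (reporter + plant)
  extra <- sum(vapply(spectra(run1), function(s)
    nrow(peaksInWindow(s, 126.128, 40, "ppm")) > 1, logical(1)))
  expect_gt(extra, 10)
  expect_lt(extra, 30)
})

test_that("swap simulation plants anti-correlated effects", {
  sites <- makeSitePanel(nInter = 10, trueLog2 = 0, nSpectra = 5)
  cfg <- simConfig(sites, seed = 41)
  sw <- simulateSwap(cfg, changed = 1:3, effect = 1.5)
  expect_equal(sum(sw$truth$changed), 3L)
  expect_equal(sw$truth$log2Exp1, -sw$truth$log2Exp2)
  expect_true(all(abs(sw$truth$log2Exp1[sw$truth$changed]) == 1.5))
  expect_true(all(sw$truth$log2Exp1[!sw$truth$changed] == 0))
  ## quantified in the swap orientation, recovered near the planted truth
  agg1 <- aggregateSites(quantifySpectra(sw$exp1$run, sw$exp1$ids,
                                         orientation = "126/127"))
  m <- merge(agg1, sw$truth, by = "siteKey")
  expect_true(all(abs(m$meanLog2 - m$log2Exp1) < 0.5))
})

test_that("written simulated datasets re-read consistently", {
  sites <- makeSitePanel(nMono = 2, trueLog2 = 0.3, nSpectra = 2)
  sim <- simulateRun(simConfig(sites, seed = 19))
  dir <- tempfile()
  paths <- writeSimulatedRun(sim, dir = dir, prefix = "t")
  run <- readSpectra(paths[["spectra"]])
  ids <- readIdentifications(paths[["ids"]])
  expect_equal(length(run), length(sim$run))
  expect_equal(ids$siteKey, sim$ids$siteKey)
  agg <- aggregateSites(quantifySpectra(run, ids))
  aggMem <- aggregateSites(quantifySpectra(sim$run, sim$ids))
  expect_equal(agg$meanLog2, aggMem$meanLog2, tolerance = 1e-9)
})
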