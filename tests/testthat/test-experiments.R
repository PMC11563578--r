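test_that("mixing evaluation recovers exact and degenerate designs", {
  design <- defaultMixingDesign()
  ## data exactly on y = x
  obs <- data.frame(sample = rep(design$sample, each = 4),
                    log2Ratio = rep(log2(design$expectedRatio), each = 4))
  res <- evaluateMixing(obs, design)
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_equal(res$perLevel$sd, rep(0, 5))
  ## constant observed ratios: slope 0
  flat <- data.frame(sample = rep(design$sample, each = 3), log2Ratio = 0.7)
  expect_equal(evaluateMixing(flat, design)$slope, 0, tolerance = 1e-12)
  ## single level is an error
  expect_error(evaluateMixing(obs[obs$sample == "1to1", ],
                              design[design$sample == "1to1", ]),
               "2 distinct")
})

test_that("mixing evaluation recovers a known biased generator", {
  set.seed(31)
  design <- defaultMixingDesign()
  lv <- log2(design$expectedRatio)
  obs <- do.call(rbind, lapply(seq_along(lv), function(i)
    data.frame(sample = design$sample[i],
               log2Ratio = lv[i] - 0.4 + rnorm(60, 0, 0.25))))
  res <- evaluateMixing(obs, design)
  expect_equal(res$slope, 1, tolerance = 0.05)
  expect_equal(res$intercept, -0.4, tolerance = 0.05)
  sds <- res$perLevel$sd
  expect_true(all(abs(sds - 0.25) < 0.08))
})

test_that("swap join classifies presence and fits anti-correlation", {
  s <- function(keys, ratios) data.frame(
    siteKey = keys, linkClass = linkClass(keys),
    nSpectra = 1L, meanLog2 = ratios, sdLog2 = NA_real_, engines = "N",
    stringsAsFactors = FALSE)
  keys <- sprintf("A:%d--B:%d", 1:6, 11:16)
  r <- c(-2, -1, -0.2, 0.5, 1, 2)
  sj <- swapJoin(s(keys, r), s(keys, -r))
  expect_equal(unname(sj$counts), c(6L, 0L, 0L))
  expect_equal(sj$slope, -1, tolerance = 1e-12)
  expect_equal(sj$r2, 1, tolerance = 1e-12)
  ## disjoint site sets: no fit, flagged
  sj2 <- swapJoin(s(keys[1:3], r[1:3]), s(keys[4:6], r[4:6]))
  expect_false(sj2$fitDefined)
  expect_equal(unname(sj2$counts), c(0L, 3L, 3L))
  ## symmetry up to axis exchange
  sj3 <- swapJoin(s(keys, -r), s(keys, r))
  expect_equal(sj3$slope, sj$slope, tolerance = 1e-12)
})

test_that("change calls require fold exceedance in both with swapped sign", {
  pairs <- data.frame(
    siteKey = sprintf("S:%d--T:%d", 1:5, 11:15),
    linkClass = "interlink",
    ratio1 = c(1.5, 1.5, 0.3, 2.0, NA),
    ratio2 = c(-1.5, 1.5, -0.2, NA, -1.8),
    presence = c("both", "both", "both", "I-only", "II-only"),
    stringsAsFactors = FALSE)
  calls <- classifyChanges(pairs, fold = 2)
  expect_equal(calls$call,
               c("changed", "inconsistent", "unchanged",
                 "one_experiment_only", "one_experiment_only"))
  expect_equal(calls$largeSingle, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  ## monotone in fold: raising the threshold never adds "changed"
  for (fold in c(2, 3, 4, 8)) {
    c2 <- classifyChanges(pairs, fold = fold)
    was <- calls$call == "changed"
    expect_true(all(c2$call[!was] != "changed" | was[!was]))
  }
  expect_error(classifyChanges(pairs, fold = 1), "> 1")
})

test_that("ratio distribution summary reports per-class fractions", {
  sites <- data.frame(
    siteKey = c("A:1", "A:2", "A:1--A:5", "A:1--B:2"),
    linkClass = c("monolink", "monolink", "intralink", "interlink"),
    nSpectra = 1L, meanLog2 = c(0.4, -0.6, 0, 2), sdLog2 = NA_real_,
    engines = "N", stringsAsFactors = FALSE)
  out <- ratioDistributionSummary(sites, window = 0.5)
  expect_equal(out$fractionWithin[out$class == "overall"], 0.5)
  expect_equal(out$fractionWithin[out$class == "monolink"], 0.5)
  expect_equal(out$fractionWithin[out$class == "intralink"], 1)
  expect_equal(out$fractionWithin[out$class == "interlink"], 0)
  expect_error(ratioDistributionSummary(sites[0, ]), "no sites")
})

test_that("null fraction matches the normal-tail oracle", {
  ## site ratios ~ N(0, 0.2): P(|x| <= 0.5) = 2*pnorm(2.5) - 1
  sites <- makeSitePanel(nMono = 60, nIntra = 45, nInter = 45,
                         trueLog2 = 0, nSpectra = 1)
  cfg <- simConfig(sites, seed = 77, ratioNoiseSd = 0.2, noisePeaks = 5)
  sim <- simulateRun(cfg)
  agg <- aggregateSites(quantifySpectra(sim$run, sim$ids))
  out <- ratioDistributionSummary(agg, window = 0.5)
  frac <- out$fractionWithin[out$class == "overall"]
  expected <- 2 * pnorm(0.5 / 0.2) - 1   # 0.9876
  n <- sum(out$n[out$class == "overall"])
  band <- 3 * sqrt(expected * (1 - expected) / n)
  expect_true(abs(frac - expected) <= band + 1e-9)
})
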