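#' Default mixing-series design
#'
#' The two-channel mixing experiment: samples combined at known
#' 127:126 ratios spanning 10:1 to 1:10.
#'
#' @return data.frame with `sample` labels and `expectedRatio`
#'   (127:126, linear scale).
#' @export
defaultMixingDesign <- function() {
  data.frame(
    sample = c("10to1", "5to1", "1to1", "1to5", "1to10"),
    expectedRatio = c(10, 5, 1, 1 / 5, 1 / 10),
    stringsAsFactors = FALSE)
}

#' Evaluate a mixing series against its design
#'
#' Ordinary least-squares regression of observed log2(127/126) ratios on
#' the expected log2 ratios, plus per-level mean/SD. Accurate reporter
#' quantification should give a slope close to 1; a nonzero intercept
#' reflects a global channel bias (e.g. differential sample loss before
#' mixing).
#'
#' @param observed data.frame with columns `sample` and `log2Ratio`
#'   (per-site or per-spectrum, as configured upstream).
#' @param design Mixing design data.frame (`sample`, `expectedRatio`),
#'   default [defaultMixingDesign()].
#' @return List with `slope`, `intercept`, `r2`, `fit` (the `lm` object)
#'   and `perLevel` (data.frame: `sample`, `expectedLog2`, `n`, `mean`,
#'   `sd`).
#' @export
evaluateMixing <- function(observed, design = defaultMixingDesign()) {
  stopifnot(all(c("sample", "log2Ratio") %in% names(observed)),
            all(c("sample", "expectedRatio") %in% names(design)))
  if (any(design$expectedRatio <= 0)) stop("expected ratios must be > 0")
  df <- merge(observed, design, by = "sample")
  if (nrow(df) == 0L) stop("no observations match the design samples")
  df$expectedLog2 <- log2(df$expectedRatio)
  if (length(unique(df$expectedLog2)) < 2L)
    stop("need >= 2 distinct expected levels to fit a slope")
  df <- df[!is.na(df$log2Ratio), , drop = FALSE]
  fit <- stats::lm(log2Ratio ~ expectedLog2, data = df)
  perLevel <- do.call(rbind, lapply(split(df, df$sample), function(g)
    data.frame(sample = g$sample[1L], expectedLog2 = g$expectedLog2[1L],
               n = nrow(g), mean = mean(g$log2Ratio),
               sd = if (nrow(g) > 1L) stats::sd(g$log2Ratio) else NA_real_,
               stringsAsFactors = FALSE)))
  perLevel <- perLevel[order(perLevel$expectedLog2), , drop = FALSE]
  rownames(perLevel) <- NULL
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = suppressWarnings(summary(fit)$r.squared),
       fit = fit, perLevel = perLevel)
}

#' Join two label-swap experiments on site key
#'
#' Outer join of the site tables of experiments I and II (same
#' log2(126/127) orientation in both). Sites quantified in both
#' experiments ("both") are regressed (OLS) against each other; under a
#' clean label swap their ratios anti-correlate (slope near -1).
#'
#' @param exp1,exp2 Site quantification data.frames
#'   ([aggregateSites()]).
#' @return List with `pairs` (data.frame: `siteKey`, `linkClass`,
#'   `ratio1`, `ratio2`, `presence` in `{both, I-only, II-only}`),
#'   `counts`, and `slope`/`intercept`/`r2`/`fit` over the "both" pairs
#'   (`NA` and a flag `fitDefined = FALSE` when fewer than 2).
#' @export
swapJoin <- function(exp1, exp2) {
  j <- merge(exp1[, c("siteKey", "linkClass", "meanLog2")],
             exp2[, c("siteKey", "linkClass", "meanLog2")],
             by = "siteKey", all = TRUE, suffixes = c("1", "2"))
  pairs <- data.frame(
    siteKey = j$siteKey,
    linkClass = ifelse(is.na(j$linkClass1), j$linkClass2, j$linkClass1),
    ratio1 = j$meanLog21, ratio2 = j$meanLog22,
    presence = ifelse(!is.na(j$meanLog21) & !is.na(j$meanLog22), "both",
                      ifelse(is.na(j$meanLog22), "I-only", "II-only")),
    stringsAsFactors = FALSE)
  both <- pairs[pairs$presence == "both", , drop = FALSE]
  counts <- c(both = nrow(both),
              `I-only` = sum(pairs$presence == "I-only"),
              `II-only` = sum(pairs$presence == "II-only"))
  if (nrow(both) >= 2L && stats::var(both$ratio1) > 0) {
    fit <- stats::lm(ratio2 ~ ratio1, data = both)
    res <- list(slope = unname(stats::coef(fit)[2L]),
                intercept = unname(stats::coef(fit)[1L]),
                r2 = suppressWarnings(summary(fit)$r.squared), fit = fit, fitDefined = TRUE)
  } else {
    res <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                fit = NULL, fitDefined = FALSE)
  }
  c(list(pairs = pairs, counts = counts), res)
}

#' Classify per-site abundance changes from a swap experiment
#'
#' A site is called `changed` only when its |log2 ratio| reaches
#' `log2(fold)` in BOTH experiments with anti-correlated signs (the
#' direction a genuine abundance difference must take under a label
#' swap). Same-direction exceedances are `inconsistent`; sites seen in
#' only one experiment are `one_experiment_only` and are never called
#' changed (the `largeSingle` flag marks those whose single ratio
#' exceeds the threshold).
#'
#' @param pairs Swap-pair data.frame from [swapJoin()] (`$pairs`).
#' @param fold Fold-change threshold on the linear scale (> 1,
#'   default 2).
#' @return `pairs` with added columns `call` in
#'   `{changed, unchanged, inconsistent, one_experiment_only}` and
#'   `largeSingle`.
#' @export
classifyChanges <- function(pairs, fold = 2.0) {
  if (!is.numeric(fold) || fold <= 1) stop("fold threshold must be > 1")
  th <- log2(fold)
  both <- pairs$presence == "both"
  exceeds <- abs(pairs$ratio1) >= th & abs(pairs$ratio2) >= th
  anti <- pairs$ratio1 * pairs$ratio2 < 0
  call <- rep("one_experiment_only", nrow(pairs))
  call[both] <- "unchanged"
  call[both & exceeds & anti] <- "changed"
  call[both & exceeds & !anti] <- "inconsistent"
  single <- ifelse(is.na(pairs$ratio1), pairs$ratio2, pairs$ratio1)
  pairs$call <- call
  pairs$largeSingle <- !both & abs(single) >= th
  pairs$foldThreshold <- fold
  pairs
}

#' Fraction of site ratios within a log2 window
#'
#' Summary of a null-like ratio distribution: the fraction of sites whose
#' |mean log2 ratio| is at most `window`, overall and per link class.
#'
#' @param sites Site quantification data.frame ([aggregateSites()]).
#' @param window Half-width in log2 units (default 0.5).
#' @return data.frame: `class` (`overall` plus each link class present),
#'   `n`, `fractionWithin`.
#' @export
ratioDistributionSummary <- function(sites, window = 0.5) {
  if (nrow(sites) == 0L) stop("no sites to summarize")
  within <- abs(sites$meanLog2) <= window
  rows <- list(data.frame(class = "overall", n = nrow(sites),
                          fractionWithin = mean(within),
                          stringsAsFactors = FALSE))
  for (cl in unique(sites$linkClass)) {
    sel <- sites$linkClass == cl
    rows[[length(rows) + 1L]] <- data.frame(class = cl, n = sum(sel),
      fractionWithin = mean(within[sel]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  out
}
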