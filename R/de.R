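## Negative-binomial Wald differential expression with per-genome
## normalization, and temporal classification of phage genes.

#' Negative-binomial Wald test between two timepoints of one genome
#'
#' Self-contained NB differential-expression pipeline: size factors by
#' median-of-ratios over the chosen genome's features only
#' (\code{\link{sizeFactorsGenome}}), moment dispersions with trend
#' shrinkage (\code{\link{estimateFeatureDispersions}}), then a
#' per-feature NB generalized linear model with log link, a condition
#' indicator and log size factors as offset. The Wald statistic is the
#' fold-change estimate over its standard error; two-sided p-values use
#' a t reference with the model's residual degrees of freedom (the
#' normal reference is anticonservative with plug-in dispersions at the
#' 2-3 replicates typical here) and are adjusted by Benjamini-Hochberg
#' across the tested features of the same genome. Features with all-zero counts carry NA statistics and do
#' not enter the adjustment denominator.
#'
#' @param dce a \linkS4class{DualCountExperiment}
#' @param genome "phage" or "host": features tested and used for
#'   normalization (rRNA-class features always excluded)
#' @param contrast length-2 vector of timepoints (reference, test); the
#'   log2 fold-change is test vs reference
#' @param sf optional precomputed size factors for the contrast samples
#' @param dispersions optional precomputed per-feature dispersions
#' @param pseudoReference passed to \code{\link{sizeFactorsGenome}}
#' @param trendWeight passed to \code{\link{estimateFeatureDispersions}}
#' @return data.frame (rownames = feature ids) with baseMean, meanRef,
#'   meanTest (normalized condition means), log2FoldChange, lfcSE, stat,
#'   pvalue, padj and the contrast label
#' @export
nbWaldTest <- function(dce, genome = c("phage", "host"), contrast,
                       sf = NULL, dispersions = NULL,
                       pseudoReference = FALSE, trendWeight = 0.5) {
  stopifnot(is(dce, "DualCountExperiment"), length(contrast) == 2)
  genome <- match.arg(genome)
  cd <- SummarizedExperiment::colData(dce)
  selS <- cd$timepoint %in% contrast
  sub <- dce[, selS]
  cond <- factor(as.character(SummarizedExperiment::colData(sub)$timepoint),
                 levels = as.character(contrast))
  if (any(table(cond) < 2))
    stop("both conditions need >= 2 replicates (single-replicate ",
         "timepoints are descriptive only)")
  rd <- SummarizedExperiment::rowData(sub)
  selF <- rd$genome == genome & rd$class != "rRNA"
  cts <- SummarizedExperiment::assay(sub, "counts")[selF, , drop = FALSE]
  if (is.null(sf))
    sf <- sizeFactorsGenome(sub, genome, pseudoReference = pseudoReference)
  if (is.null(dispersions))
    dispersions <- estimateFeatureDispersions(cts, sf, cond,
                                              trendWeight = trendWeight)$alpha
  stopifnot(length(sf) == ncol(cts), length(dispersions) == nrow(cts))

  q <- sweep(cts, 2, sf, "/")
  isRef <- cond == levels(cond)[1]
  meanRef <- rowMeans(q[, isRef, drop = FALSE])
  meanTest <- rowMeans(q[, !isRef, drop = FALSE])
  off <- log(sf)
  x <- as.integer(!isRef)

  n <- nrow(cts)
  est <- se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    yi <- cts[i, ]
    if (all(yi == 0)) next
    fam <- if (dispersions[i] <= 1e-7) stats::poisson()
           else MASS::negative.binomial(theta = 1 / dispersions[i])
    fit <- tryCatch(
      suppressWarnings(stats::glm(yi ~ x, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- tryCatch(suppressWarnings(summary(fit)$coefficients),
                   error = function(e) NULL)
    if (is.null(cf) || nrow(cf) < 2) next
    est[i] <- cf[2, 1]; se[i] <- cf[2, 2]
  }
  log2fc <- est / log(2)
  lfcSE <- se / log(2)
  stat <- est / se
  ## t reference with the GLM residual df: the plug-in moment dispersions
  ## make the normal reference anticonservative at 2-3 replicates
  pvalue <- 2 * pt(-abs(stat), df = ncol(cts) - 2)
  padj <- benjaminiHochberg(pvalue)
  data.frame(baseMean = rowMeans(q), meanRef = meanRef, meanTest = meanTest,
             log2FoldChange = log2fc, lfcSE = lfcSE, stat = stat,
             pvalue = pvalue, padj = padj,
             contrast = paste(contrast[2], "vs", contrast[1]),
             row.names = rownames(cts))
}

#' Preset significance filters for host differential expression
#'
#' `paper-host-strict` is the stringent host cut-off
#' |log2 fold-change| > 1.3 and p < 0.05; `default` uses adjusted
#' p < 0.05.
#'
#' @param de an \code{\link{nbWaldTest}} table
#' @param preset "paper-host-strict" or "default"
#' @return logical vector marking significant features
#' @export
applyDEPreset <- function(de, preset = c("default", "paper-host-strict")) {
  preset <- match.arg(preset)
  if (preset == "paper-host-strict")
    !is.na(de$pvalue) & abs(de$log2FoldChange) > 1.3 & de$pvalue < 0.05
  else
    !is.na(de$padj) & de$padj < 0.05
}

#' Temporal classification of phage features
#'
#' Early features are significantly higher at the early timepoint of the
#' early-vs-late contrast, late features significantly higher at the late
#' one. A feature is classed middle when it is neither, but its
#' normalized mid-infection expression is at least \code{middleRatio}
#' times both flanking condition means (the middle phase is assessed
#' descriptively from a single sample). Everything else is
#' not_significant.
#'
#' @param de \code{\link{nbWaldTest}} result with contrast
#'   (early, late), so log2FoldChange > 0 means late-enriched
#' @param expr6p5 named numeric vector of normalized mid-timepoint
#'   expression per feature, or NULL to disable the middle class (with a
#'   warning)
#' @param padjThresh adjusted-p threshold for early/late (default 0.05)
#' @param middleRatio expression ratio for the middle rule (default 2)
#' @return factor (early/middle/late/not_significant) named by feature
#' @export
classifyTemporal <- function(de, expr6p5 = NULL, padjThresh = 0.05,
                             middleRatio = 2) {
  sig <- !is.na(de$padj) & de$padj < padjThresh
  cls <- rep("not_significant", nrow(de))
  cls[sig & de$log2FoldChange < 0] <- "early"
  cls[sig & de$log2FoldChange > 0] <- "late"
  if (is.null(expr6p5)) {
    warning("no mid-infection sample supplied; middle class disabled")
  } else {
    mid <- expr6p5[rownames(de)]
    isMid <- cls == "not_significant" & !is.na(mid) &
      mid >= middleRatio * de$meanRef & mid >= middleRatio * de$meanTest
    cls[isMid] <- "middle"
  }
  factor(setNames(cls, rownames(de)),
         levels = c("early", "middle", "late", "not_significant"))
}

#' Fixed-width genome bins for windowed expression
#'
#' Non-overlapping windows over one genome, one set per strand, the last
#' partial window kept. Used to summarise phage expression in 250-bp
#' tiles.
#'
#' @param genomeLen genome length (bp)
#' @param width window width (default 250)
#' @param genome seqname for the bins
#' @return \link[GenomicRanges]{GRanges} with both strands and a `bin` id
#' @export
binGenome <- function(genomeLen, width = 250, genome = "genome") {
  starts <- seq(1L, genomeLen, by = width)
  ends <- pmin(starts + width - 1L, genomeLen)
  one <- function(str) GenomicRanges::GRanges(
    genome, IRanges::IRanges(starts, ends), strand = str,
    bin = paste0("bin", str, "_", seq_along(starts)))
  c(one("+"), one("-"))
}

#' Windowed read counts from a coverage track
#'
#' Integrates per-base depth over fixed windows on each strand and
#' converts to approximate read counts by dividing by the read length.
#'
#' @param cov a \linkS4class{StrandedCoverage}
#' @param width window width in bp (default 250)
#' @param readLength read length used for the depth-to-count conversion
#' @return data.frame with bin coordinates, strand and counts
#' @export
binCoverageCounts <- function(cov, width = 250, readLength = 75) {
  stopifnot(is(cov, "StrandedCoverage"))
  len <- genomeLength(cov)
  starts <- seq(1L, len, by = width)
  ends <- pmin(starts + width - 1L, len)
  idx <- rep(seq_along(starts), times = ends - starts + 1L)
  data.frame(
    start = rep(starts, 2), end = rep(ends, 2),
    strand = rep(c("+", "-"), each = length(starts)),
    count = c(as.integer(round(tapply(cov@plus, idx, sum) / readLength)),
              as.integer(round(tapply(cov@minus, idx, sum) / readLength))))
}
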