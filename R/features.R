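## RNA-feature discovery from stranded coverage: intergenic small RNAs,
## cis-antisense RNAs within annotated genes, and riboswitch candidates
## (strong 5' leader transcription attenuated at the CDS boundary).
## These operationalise what is usually a manual strand-aware coverage
## curation, with every threshold exposed as a parameter.

geneRanges <- function(ann, types = c("CDS", "gene")) {
  ann[as.character(ann$type) %in% types]
}

checkCovAnn <- function(cov, ann) {
  len <- genomeLength(cov)
  if (length(ann) && max(GenomicRanges::end(ann)) > len)
    stop("annotation exceeds coverage length (", len, " bp): genome mismatch?")
  len
}

strandDepth <- function(cov, strand)
  if (strand == "+") cov@plus else cov@minus

rangesToCalls <- function(runs, strand, cls, depth, genome, context = NA) {
  if (nrow(runs) == 0)
    return(GenomicRanges::GRanges(seqinfo = NULL))
  gr <- GenomicRanges::GRanges(
    genome, IRanges::IRanges(runs$start, runs$end), strand = strand)
  gr$class <- cls
  gr$meanDepth <- vapply(seq_len(nrow(runs)),
                         function(i) mean(depth[runs$start[i]:runs$end[i]]), 0)
  gr$context <- rep_len(context, length(gr))
  gr
}

#' Call intergenic small RNAs from stranded coverage
#'
#' Maximal runs of bases with depth >= \code{minDepth}, merged across
#' gaps of at most \code{mergeGap} bp, are emitted as sRNA calls when
#' they overlap no same-strand annotated CDS, lie within the length
#' bounds and (by default) also avoid opposite-strand CDS so that the
#' sRNA and antisense classes stay disjoint.
#'
#' @param cov a \linkS4class{StrandedCoverage}
#' @param ann annotation \link[GenomicRanges]{GRanges} with a `type`
#'   metadata column (CDS/gene/tRNA/...)
#' @param minDepth minimum per-base depth (default 20)
#' @param minLen,maxLen length bounds in bp (defaults 50 and 500)
#' @param mergeGap merge runs separated by gaps <= this (default 10)
#' @param intergenicOnly if TRUE (default) calls inside opposite-strand
#'   genes are suppressed too (those are antisense territory)
#' @return GRanges of calls with class "sRNA", mean depth and context
#' @export
callIntergenicSrna <- function(cov, ann, minDepth = 20, minLen = 50,
                               maxLen = 500, mergeGap = 10,
                               intergenicOnly = TRUE) {
  stopifnot(is(cov, "StrandedCoverage"))
  checkCovAnn(cov, ann)
  genes <- geneRanges(ann)
  out <- GenomicRanges::GRanges()
  for (str in c("+", "-")) {
    depth <- strandDepth(cov, str)
    runs <- findRuns(depth >= minDepth, mergeGap = mergeGap)
    if (nrow(runs) == 0) next
    w <- runs$end - runs$start + 1L
    runs <- runs[w >= minLen & w <= maxLen, , drop = FALSE]
    if (nrow(runs) == 0) next
    gr <- GenomicRanges::GRanges(cov@genome,
                                 IRanges::IRanges(runs$start, runs$end),
                                 strand = str)
    same <- genes[GenomicRanges::strand(genes) == str]
    keep <- GenomicRanges::countOverlaps(gr, same, ignore.strand = TRUE) == 0
    if (intergenicOnly) {
      opp <- genes[GenomicRanges::strand(genes) != str]
      keep <- keep &
        GenomicRanges::countOverlaps(gr, opp, ignore.strand = TRUE) == 0
    }
    runs <- runs[keep, , drop = FALSE]
    out <- c(out, rangesToCalls(runs, str, "sRNA", depth, cov@genome))
  }
  out
}

#' Call cis-antisense RNAs within annotated genes
#'
#' Within every annotated gene, runs on the opposite strand with depth
#' >= \code{minDepth} and antisense/(sense + 1) per-base depth ratio
#' >= \code{minRatio} are emitted as antisense calls, classed small or
#' long at the \code{smallLongBoundary} (default 300 bp).
#'
#' @inheritParams callIntergenicSrna
#' @param minRatio minimum mean antisense/(sense + 1) ratio (default 0.1)
#' @param minLen minimum call length (default 100)
#' @param smallLongBoundary length separating asRNA_small from asRNA_long
#' @return GRanges of calls with class "asRNA_small"/"asRNA_long", mean
#'   depth and the containing gene id in `context`
#' @export
callAntisense <- function(cov, ann, minDepth = 20, minRatio = 0.1,
                          minLen = 100, smallLongBoundary = 300,
                          mergeGap = 10) {
  stopifnot(is(cov, "StrandedCoverage"))
  checkCovAnn(cov, ann)
  genes <- geneRanges(ann)
  out <- GenomicRanges::GRanges()
  ids <- if (!is.null(genes$ID)) genes$ID else as.character(seq_along(genes))
  for (i in seq_along(genes)) {
    gstr <- as.character(GenomicRanges::strand(genes[i]))
    if (!gstr %in% c("+", "-")) next
    astr <- if (gstr == "+") "-" else "+"
    s <- GenomicRanges::start(genes[i]); e <- GenomicRanges::end(genes[i])
    anti <- strandDepth(cov, astr)[s:e]
    sense <- strandDepth(cov, gstr)[s:e]
    ok <- anti >= minDepth & anti / (sense + 1) >= minRatio
    runs <- findRuns(ok, mergeGap = mergeGap)
    if (nrow(runs) == 0) next
    w <- runs$end - runs$start + 1L
    runs <- runs[w >= minLen, , drop = FALSE]
    if (nrow(runs) == 0) next
    runs$start <- runs$start + s - 1L
    runs$end <- runs$end + s - 1L
    w <- runs$end - runs$start + 1L
    cls <- ifelse(w < smallLongBoundary, "asRNA_small", "asRNA_long")
    out <- c(out, rangesToCalls(runs, astr, cls,
                                strandDepth(cov, astr), cov@genome,
                                context = ids[i]))
  }
  out
}

#' Call riboswitch candidates (attenuated 5' leaders)
#'
#' A riboswitch-like signature is strong same-strand transcription
#' starting well upstream of a gene and dropping sharply at the coding
#' sequence: a transcribed block on the gene's strand that begins at
#' least \code{minUpstreamGap} bp before the gene's 5' end, ends at (or
#' within \code{maxEndGap} bp of) the gene start, is intergenic, and
#' whose mean depth exceeds \code{dropRatio} times the mean depth in the
#' first \code{window} bp inside the gene.
#'
#' @inheritParams callIntergenicSrna
#' @param minUpstreamGap minimum distance from block start to the gene's
#'   5' end (default 70 bp); "a significant distance" upstream
#' @param dropRatio required leader/CDS depth ratio (default 3)
#' @param window bp just inside the gene used for the attenuated depth
#' @param maxEndGap maximum distance between block end and gene start for
#'   the block to count as that gene's leader (default 20 bp)
#' @param searchLimit how far upstream of each gene to search (default
#'   1000 bp)
#' @return GRanges of calls with class "riboswitch_candidate" and the
#'   downstream gene id in `context`
#' @export
callRiboswitchCandidates <- function(cov, ann, minUpstreamGap = 70,
                                     minDepth = 20, dropRatio = 3,
                                     window = 30, mergeGap = 10,
                                     maxEndGap = 20, searchLimit = 1000) {
  stopifnot(is(cov, "StrandedCoverage"))
  len <- checkCovAnn(cov, ann)
  genes <- geneRanges(ann)
  ids <- if (!is.null(genes$ID)) genes$ID else as.character(seq_along(genes))
  out <- GenomicRanges::GRanges()
  for (i in seq_along(genes)) {
    gstr <- as.character(GenomicRanges::strand(genes[i]))
    if (!gstr %in% c("+", "-")) next
    depth <- strandDepth(cov, gstr)
    gs <- GenomicRanges::start(genes[i]); ge <- GenomicRanges::end(genes[i])
    if (gstr == "+") {
      upFrom <- max(1L, gs - searchLimit); upTo <- gs - 1L
      inFrom <- gs; inTo <- min(len, gs + window - 1L)
    } else {
      upFrom <- ge + 1L; upTo <- min(len, ge + searchLimit)
      inFrom <- max(1L, ge - window + 1L); inTo <- ge
    }
    if (upTo < upFrom) next
    up <- depth[upFrom:upTo]
    runs <- findRuns(up >= minDepth, mergeGap = mergeGap)
    if (nrow(runs) == 0) next
    runs$start <- runs$start + upFrom - 1L
    runs$end <- runs$end + upFrom - 1L
    ## leader geometry relative to the gene's 5' end
    if (gstr == "+") {
      ok <- runs$start <= gs - minUpstreamGap & gs - 1L - runs$end <= maxEndGap
    } else {
      ok <- runs$end >= ge + minUpstreamGap & runs$start - ge - 1L <= maxEndGap
    }
    runs <- runs[ok, , drop = FALSE]
    if (nrow(runs) == 0) next
    ## intergenic on the same strand
    gr <- GenomicRanges::GRanges(cov@genome,
                                 IRanges::IRanges(runs$start, runs$end),
                                 strand = gstr)
    same <- genes[GenomicRanges::strand(genes) == gstr]
    runs <- runs[GenomicRanges::countOverlaps(gr, same,
                                              ignore.strand = TRUE) == 0, ,
                 drop = FALSE]
    if (nrow(runs) == 0) next
    insideMean <- mean(depth[inFrom:inTo])
    keep <- vapply(seq_len(nrow(runs)), function(j)
      mean(depth[runs$start[j]:runs$end[j]]) > dropRatio * insideMean,
      logical(1))
    runs <- runs[keep, , drop = FALSE]
    out <- c(out, rangesToCalls(runs, gstr, "riboswitch_candidate",
                                depth, cov@genome, context = ids[i]))
  }
  out
}

#' Differential expression of called RNA features
#'
#' Integrates each sample's strand-specific coverage over every call to
#' approximate read counts (depth sum / read length), then delegates to
#' the NB Wald pipeline. The log2 fold-change and adjusted p are
#' attached to the calls.
#'
#' @param calls GRanges of RNA-feature calls
#' @param covs list of \linkS4class{StrandedCoverage}, one per sample
#' @param timepoint per-sample timepoints (same length as `covs`)
#' @param contrast length-2 vector (reference, test) of timepoints, each
#'   with >= 2 replicates
#' @param readLength read length for depth-to-count conversion
#' @return `calls` with added log2FoldChange and padj metadata columns
#' @export
differentialFeatureExpression <- function(calls, covs, timepoint, contrast,
                                          readLength = 75) {
  stopifnot(length(covs) == length(timepoint), length(calls) > 0)
  cts <- vapply(covs, function(cv) {
    vapply(seq_along(calls), function(i) {
      str <- as.character(GenomicRanges::strand(calls[i]))
      d <- strandDepth(cv, str)
      as.integer(round(sum(
        d[GenomicRanges::start(calls[i]):GenomicRanges::end(calls[i])]) /
          readLength))
    }, integer(1))
  }, integer(length(calls)))
  cts <- matrix(cts, nrow = length(calls))
  rownames(cts) <- paste0("call_", seq_along(calls))
  colnames(cts) <- paste0("s", seq_along(covs))
  dce <- DualCountExperiment(
    ## single-genome contrast: tag everything host so the per-genome
    ## machinery applies unchanged
    rbind(cts, host_anchor = rep(1L, ncol(cts))),
    genome = "host", class = c(calls$class, "CDS"),
    timepoint = c(timepoint), replicate = seq_along(covs))
  de <- nbWaldTest(dce, "host", contrast, pseudoReference = TRUE)
  de <- de[rownames(cts), ]
  calls$log2FoldChange <- de$log2FoldChange
  calls$padj <- de$padj
  calls
}

#' Precision and recall of calls against planted truth
#'
#' A call matches a planted feature when both have the same class group,
#' the same strand, and their reciprocal overlap is at least
#' \code{minOverlap} of each length.
#'
#' @param calls GRanges with a `class` column
#' @param truth GRanges of planted features with a `class` column
#' @param minOverlap reciprocal-overlap fraction (default 0.5)
#' @return data.frame per class: nCalls, nTruth, truePositives,
#'   precision, recall
#' @export
evaluateCalls <- function(calls, truth, minOverlap = 0.5) {
  grp <- function(x) sub("asRNA_(small|long)", "asRNA", x)
  classes <- unique(grp(truth$class))
  rows <- lapply(classes, function(cl) {
    ca <- calls[grp(calls$class) == cl]
    tr <- truth[grp(truth$class) == cl]
    hit <- GenomicRanges::findOverlaps(ca, tr)
    if (length(hit)) {
      ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(ca)[S4Vectors::queryHits(hit)],
        GenomicRanges::ranges(tr)[S4Vectors::subjectHits(hit)]))
      wq <- GenomicRanges::width(ca)[S4Vectors::queryHits(hit)]
      ws <- GenomicRanges::width(tr)[S4Vectors::subjectHits(hit)]
      sameStr <- as.character(GenomicRanges::strand(ca))[
        S4Vectors::queryHits(hit)] ==
        as.character(GenomicRanges::strand(tr))[S4Vectors::subjectHits(hit)]
      good <- sameStr & ov >= minOverlap * wq & ov >= minOverlap * ws
      tp_calls <- unique(S4Vectors::queryHits(hit)[good])
      tp_truth <- unique(S4Vectors::subjectHits(hit)[good])
    } else tp_calls <- tp_truth <- integer(0)
    data.frame(class = cl, nCalls = length(ca), nTruth = length(tr),
               truePositives = length(tp_truth),
               precision = if (length(ca)) length(tp_calls) / length(ca)
                           else NA_real_,
               recall = if (length(tr)) length(tp_truth) / length(tr)
                        else NA_real_)
  })
  do.call(rbind, rows)
}
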