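## Transcriptome takeover: per-sample fractions of non-ribosomal reads by
## source genome, and the global host-depletion factor.

#' Per-sample phage/host read fractions
#'
#' For every sample, the fraction of non-rRNA counts on features of each
#' genome. During a lytic infection the phage fraction rises from ~0 to
#' dominate the transcript pool; this is the takeover profile.
#'
#' @param dce a \linkS4class{DualCountExperiment}
#' @return data.frame with columns sample, timepoint, replicate,
#'   phageFraction, hostFraction (fractions sum to 1 per sample)
#' @export
computeTakeover <- function(dce) {
  stopifnot(is(dce, "DualCountExperiment"))
  rd <- SummarizedExperiment::rowData(dce)
  if (!all(c("phage", "host") %in% rd$genome))
    stop("counts must contain features from both genomes")
  keep <- rd$class != "rRNA"
  cts <- SummarizedExperiment::assay(dce, "counts")[keep, , drop = FALSE]
  gnm <- rd$genome[keep]
  phage <- colSums(cts[gnm == "phage", , drop = FALSE])
  host <- colSums(cts[gnm == "host", , drop = FALSE])
  tot <- phage + host
  if (any(tot == 0))
    stop("sample(s) with zero non-rRNA counts: ",
         paste(colnames(cts)[tot == 0], collapse = ", "))
  cd <- SummarizedExperiment::colData(dce)
  data.frame(sample = colnames(dce),
             timepoint = cd$timepoint,
             replicate = if ("replicate" %in% names(cd)) cd$replicate else NA,
             phageFraction = unname(phage / tot),
             hostFraction = unname(host / tot))
}

#' Global host-transcript depletion factor
#'
#' Ratio of the mean host read fraction at the reference timepoint to the
#' mean host fraction at the late timepoint: how many fold the host share
#' of the (non-ribosomal) transcript pool has shrunk.
#'
#' @param takeover output of \code{\link{computeTakeover}}
#' @param t0,tLate timepoint values selecting the two sample sets
#' @return a single fold-change (> 1 means depletion)
#' @export
hostDepletionFactor <- function(takeover, t0, tLate) {
  sel0 <- takeover$timepoint == t0
  selL <- takeover$timepoint == tLate
  if (!any(sel0) || !any(selL)) stop("empty sample set for a timepoint")
  late <- mean(takeover$hostFraction[selL])
  if (late == 0) stop("late host fraction is zero")
  mean(takeover$hostFraction[sel0]) / late
}

#' Convert relative host fold-changes to absolute-abundance shifts
#'
#' Per-genome normalization removes the global depletion of the host
#' transcript pool, so host fold-changes are relative to other host
#' genes. Dividing by the depletion factor recovers the shift in absolute
#' abundance within the whole-cell RNA pool: a gene whose relative
#' enrichment exceeds the global depletion rises in absolute terms.
#'
#' @param de a differential-expression table from \code{\link{nbWaldTest}}
#'   computed with host-only normalization
#' @param depletion host-depletion factor from
#'   \code{\link{hostDepletionFactor}}
#' @return `de` with an added `absoluteFoldChange` column
#'   (= 2^log2FoldChange / depletion)
#' @export
relativeHostShift <- function(de, depletion) {
  stopifnot(is.numeric(depletion), depletion > 0)
  de$absoluteFoldChange <- 2^de$log2FoldChange / depletion
  de
}
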