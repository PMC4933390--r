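## Exact k-mer target scanning: every k-mer of a query small RNA is
## matched against both strands of a target genome, and hits are
## annotated with overlapping features (e.g. tRNAs). Ns never match.

#' Scan a query sequence's k-mers against a target genome
#'
#' For every k-mer of the query, all exact occurrences on both strands
#' of the target are reported. A minus-strand hit at forward-strand
#' positions [start, start+k-1] means the reverse complement of that
#' window equals the k-mer. Hits are deduplicated by (position, strand,
#' k-mer) and annotated with any overlapping feature.
#'
#' @param query query sequence (character or \link[Biostrings]{DNAString});
#'   length >= k; k-mers containing N are skipped
#' @param target target genome (character, DNAString or a length-1
#'   \link[Biostrings]{DNAStringSet})
#' @param ann optional annotation \link[GenomicRanges]{GRanges} with
#'   `type` (and optionally `ID`) metadata
#' @param k k-mer length (default 11)
#' @return data.frame with kmer, queryOffset (1-based offset of the
#'   k-mer in the query), start (1-based on the target forward strand),
#'   strand, feature id and feature type ("" when intergenic)
#' @export
scanKmers <- function(query, target, ann = NULL, k = 11) {
  if (is(target, "DNAStringSet")) {
    stopifnot(length(target) == 1)
    target <- target[[1]]
  }
  target <- Biostrings::DNAString(as.character(target))
  query <- toupper(as.character(query))
  if (nchar(query) < k) stop("query shorter than k = ", k)
  if (grepl("[^ACGTN]", query)) stop("query alphabet must be {A,C,G,T,N}")

  kmers <- substring(query, seq_len(nchar(query) - k + 1),
                     seq_len(nchar(query) - k + 1) + k - 1)
  offs <- seq_along(kmers)
  keep <- !grepl("N", kmers, fixed = TRUE)
  hits <- list()
  for (i in which(keep)) {
    km <- Biostrings::DNAString(kmers[i])
    fwd <- Biostrings::matchPattern(km, target)
    if (length(fwd))
      hits[[length(hits) + 1L]] <- data.frame(
        kmer = kmers[i], queryOffset = offs[i],
        start = BiocGenerics::start(fwd), strand = "+")
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(km), target)
    if (length(rev))
      hits[[length(hits) + 1L]] <- data.frame(
        kmer = kmers[i], queryOffset = offs[i],
        start = BiocGenerics::start(rev), strand = "-")
  }
  if (!length(hits))
    return(data.frame(kmer = character(0), queryOffset = integer(0),
                      start = integer(0), strand = character(0),
                      feature = character(0), featureType = character(0)))
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[, c("start", "strand", "kmer")]), ]
  out <- out[order(out$start, out$strand, out$kmer), ]
  rownames(out) <- NULL

  out$feature <- ""; out$featureType <- ""
  if (!is.null(ann) && length(ann)) {
    gr <- GenomicRanges::GRanges("target",
                                 IRanges::IRanges(out$start, out$start + k - 1))
    ann2 <- GenomicRanges::GRanges("target", GenomicRanges::ranges(ann))
    ov <- GenomicRanges::findOverlaps(gr, ann2)
    if (length(ov)) {
      ids <- if (!is.null(ann$ID)) as.character(ann$ID)
             else as.character(seq_along(ann))
      typ <- if (!is.null(ann$type)) as.character(ann$type)
             else rep("", length(ann))
      byHit <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
      for (qh in names(byHit)) {
        j <- as.integer(qh)
        out$feature[j] <- paste(ids[byHit[[qh]]], collapse = ",")
        out$featureType[j] <- paste(unique(typ[byHit[[qh]]]), collapse = ",")
      }
    }
  }
  out
}
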