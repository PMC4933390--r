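## Readers and writers for the standard interchange formats. All on-disk
## coordinates are 1-based inclusive (GFF3) or 0-based half-open
## (bedGraph); rtracklayer performs those conversions, and GRanges
## (1-based inclusive) is the in-memory convention throughout.

#' Read a titer CSV
#'
#' Expected columns: `time_min, titer_pfu_ml, chloroform` (0/1),
#' `replicate`.
#'
#' @param path CSV file path
#' @return a \linkS4class{TiterSeries}
#' @export
readTiterCsv <- function(path) {
  df <- read.csv(path)
  need <- c("time_min", "titer_pfu_ml", "chloroform", "replicate")
  if (!all(need %in% names(df)))
    stop("titer CSV must have columns: ", paste(need, collapse = ", "))
  TiterSeries(df$time_min, df$titer_pfu_ml, df$chloroform == 1,
              df$replicate)
}

#' @rdname readTiterCsv
#' @param series a \linkS4class{TiterSeries}
#' @export
writeTiterCsv <- function(series, path) {
  write.csv(data.frame(time_min = series@time,
                       titer_pfu_ml = series@titer,
                       chloroform = as.integer(series@chloroform),
                       replicate = series@replicate),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a dual-genome count table plus sample sheet
#'
#' The counts TSV carries `feature_id, genome, class, strand, start,
#' end` followed by one column per sample; the sample sheet CSV carries
#' `sample, timepoint, replicate`. Duplicate feature ids are rejected.
#'
#' @param countsPath TSV of counts
#' @param samplesPath CSV sample sheet
#' @return a \linkS4class{DualCountExperiment}
#' @export
readCountsTsv <- function(countsPath, samplesPath) {
  df <- read.delim(countsPath, check.names = FALSE)
  ss <- read.csv(samplesPath)
  meta <- c("feature_id", "genome", "class", "strand", "start", "end")
  if (!all(meta %in% names(df)))
    stop("counts TSV must start with columns: ",
         paste(meta, collapse = ", "))
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature ids: ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]),
               collapse = ", "))
  sampleCols <- setdiff(names(df), meta)
  if (!all(sampleCols %in% ss$sample))
    stop("sample sheet is missing samples: ",
         paste(setdiff(sampleCols, ss$sample), collapse = ", "))
  ss <- ss[match(sampleCols, ss$sample), ]
  cts <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(cts) <- df$feature_id
  DualCountExperiment(cts, genome = df$genome, class = df$class,
                      strand = df$strand, start = df$start, end = df$end,
                      timepoint = ss$timepoint, replicate = ss$replicate)
}

#' @rdname readCountsTsv
#' @param dce a \linkS4class{DualCountExperiment}
#' @export
writeCountsTsv <- function(dce, countsPath, samplesPath) {
  rd <- SummarizedExperiment::rowData(dce)
  cd <- SummarizedExperiment::colData(dce)
  df <- data.frame(feature_id = rownames(dce), genome = rd$genome,
                   class = rd$class, strand = rd$strand,
                   start = rd$start, end = rd$end, check.names = FALSE)
  df <- cbind(df, as.data.frame(SummarizedExperiment::assay(dce, "counts")))
  write.table(df, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(data.frame(sample = colnames(dce), timepoint = cd$timepoint,
                       replicate = cd$replicate),
            samplesPath, row.names = FALSE)
  invisible(countsPath)
}

#' Read a stranded bedGraph pair into a coverage track
#'
#' One bedGraph per strand (0-based half-open intervals, as the format
#' specifies). Overlapping intervals are resolved last-wins with a
#' warning.
#'
#' @param plusPath,minusPath bedGraph files for the two strands
#' @param genomeLen genome length in bp
#' @param genome,sample identifiers stored on the track
#' @return a \linkS4class{StrandedCoverage}
#' @export
readBedgraphPair <- function(plusPath, minusPath, genomeLen,
                             genome = "genome", sample = "s1") {
  readOne <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) && max(GenomicRanges::end(gr)) > genomeLen)
      stop("bedGraph interval exceeds genome length in ", path)
    if (any(GenomicRanges::countOverlaps(gr, gr) > 1))
      warning("overlapping bedGraph intervals in ", path,
              ": resolved last-wins")
    depth <- numeric(genomeLen)
    for (i in seq_along(gr))
      depth[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
        gr$score[i]
    depth
  }
  StrandedCoverage(readOne(plusPath), readOne(minusPath),
                   genome = genome, sample = sample)
}

#' @rdname readBedgraphPair
#' @param cov a \linkS4class{StrandedCoverage}
#' @export
writeBedgraphPair <- function(cov, plusPath, minusPath) {
  writeOne <- function(depth, path) {
    r <- rle(depth)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    gr <- GenomicRanges::GRanges(
      cov@genome, IRanges::IRanges(starts[keep], ends[keep]),
      score = r$values[keep])
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  writeOne(cov@plus, plusPath)
  writeOne(cov@minus, minusPath)
  invisible(plusPath)
}

#' Read / write a GFF3 annotation
#'
#' Import produces a \link[GenomicRanges]{GRanges} with `type` and `ID`
#' metadata (1-based inclusive, per the format). Duplicate IDs are
#' rejected.
#'
#' @param path GFF3 file
#' @return annotation GRanges
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(gr$ID) && anyDuplicated(stats::na.omit(gr$ID)))
    stop("duplicate feature IDs in ", path)
  gr
}

#' @rdname readGff3
#' @param ann annotation GRanges (with `type`, optionally `ID`)
#' @export
writeGff3 <- function(ann, path) {
  if (is.null(ann$type)) ann$type <- "region"
  if (is.null(ann$phase))
    ann$phase <- ifelse(as.character(ann$type) == "CDS", 0L, NA_integer_)
  rtracklayer::export(ann, path, format = "gff3")
  invisible(path)
}

#' Write RNA-feature calls as GFF3 plus a TSV summary
#'
#' @param calls GRanges of calls (class, meanDepth, context)
#' @param gffPath,tsvPath output paths
#' @export
writeCalls <- function(calls, gffPath, tsvPath) {
  gr <- calls
  gr$type <- gr$class
  gr$ID <- paste0(gr$class, "_", seq_along(gr))
  writeGff3(gr, gffPath)
  df <- data.frame(id = gr$ID, class = calls$class,
                   start = GenomicRanges::start(calls),
                   end = GenomicRanges::end(calls),
                   strand = as.character(GenomicRanges::strand(calls)),
                   meanDepth = calls$meanDepth, context = calls$context)
  write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gffPath)
}

#' Read an ion-intensity matrix with annotation tables
#'
#' Ion matrix CSV: `ion_id, mz` then one column per sample; sample
#' sheet CSV: `sample, time_min, bio_rep, tech_rep`; annotation CSVs:
#' `ion_id, metabolite_id` and `metabolite_id, pathway_id`.
#'
#' @param ionsPath,samplesPath,ionToMetPath,metToPathPath CSV paths
#' @return an \linkS4class{IonExperiment}
#' @export
readIonCsv <- function(ionsPath, samplesPath, ionToMetPath = NULL,
                       metToPathPath = NULL) {
  df <- read.csv(ionsPath, check.names = FALSE)
  ss <- read.csv(samplesPath)
  meta <- intersect(c("ion_id", "mz"), names(df))
  sampleCols <- setdiff(names(df), meta)
  ss <- ss[match(sampleCols, ss$sample), ]
  X <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(X) <- df$ion_id
  IonExperiment(X, time_min = ss$time_min, bio_rep = ss$bio_rep,
                tech_rep = ss$tech_rep,
                ionToMet = if (!is.null(ionToMetPath))
                  read.csv(ionToMetPath) else NULL,
                metToPath = if (!is.null(metToPathPath))
                  read.csv(metToPathPath) else NULL)
}
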