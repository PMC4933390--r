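## Time-course metabolomics: technical-replicate collapse, per-ion Welch
## tests versus t = 0, altered-fraction profiles and rank-subset
## (prefix) Fisher pathway enrichment.

#' Collapse technical replicates to biological-replicate means
#'
#' @param ie an \linkS4class{IonExperiment}
#' @return an \linkS4class{IonExperiment} with one column per
#'   (timepoint, biological replicate)
#' @export
collapseTechnical <- function(ie) {
  stopifnot(is(ie, "IonExperiment"))
  cd <- SummarizedExperiment::colData(ie)
  key <- paste(cd$time_min, cd$bio_rep, sep = "|")
  cells <- unique(data.frame(time = cd$time_min, bio = cd$bio_rep,
                             key = key, stringsAsFactors = FALSE))
  ## completeness: every timepoint must carry the full bio-replicate set
  bioSets <- split(cells$bio, cells$time)
  allBio <- sort(unique(cd$bio_rep))
  missing <- unlist(lapply(names(bioSets), function(tt) {
    mb <- setdiff(allBio, bioSets[[tt]])
    if (length(mb)) paste0("t=", tt, ":bio=", mb) else character(0)
  }))
  if (length(missing))
    stop("missing (timepoint, bio replicate) cells: ",
         paste(missing, collapse = ", "))
  X <- SummarizedExperiment::assay(ie, "intensity")
  M <- vapply(cells$key, function(kk) rowMeans(X[, key == kk, drop = FALSE]),
              numeric(nrow(X)))
  M <- matrix(M, nrow = nrow(X), dimnames = list(rownames(X), NULL))
  colnames(M) <- paste0("t", cells$time, "_b", cells$bio)
  IonExperiment(M, time_min = cells$time, bio_rep = cells$bio, tech_rep = 1,
                ionToMet = S4Vectors::metadata(ie)$ionToMet,
                metToPath = S4Vectors::metadata(ie)$metToPath)
}

#' Per-ion differential analysis of one timepoint versus t = 0
#'
#' Technical repeats are collapsed to biological-replicate means; per ion
#' the log2 fold-change of mean intensity (t vs 0) is reported and a
#' Welch test is run on log-transformed bio-replicate intensities.
#' P-values are Benjamini-Hochberg adjusted across ions within the
#' timepoint.
#'
#' @param ie an \linkS4class{IonExperiment}
#' @param t timepoint (minutes, != 0) to compare against t = 0
#' @return data.frame with ion_id, timepoint, log2FC, t, df, pvalue, padj
#' @export
differentialIons <- function(ie, t) {
  stopifnot(is(ie, "IonExperiment"), t != 0)
  bio <- collapseTechnical(ie)
  cd <- SummarizedExperiment::colData(bio)
  X <- SummarizedExperiment::assay(bio, "intensity")
  selT <- cd$time_min == t
  sel0 <- cd$time_min == 0
  if (sum(selT) < 2 || sum(sel0) < 2)
    stop("need >= 2 biological replicates at t = ", t, " and t = 0")
  res <- t(apply(X, 1, function(row) {
    xt <- row[selT]; x0 <- row[sel0]
    w <- welchTest(log(xt), log(x0))
    c(log2FC = log2(mean(xt) / mean(x0)), w)
  }))
  out <- data.frame(ion_id = rownames(X), timepoint = t,
                    log2FC = res[, "log2FC"], t = res[, "t"],
                    df = res[, "df"], pvalue = res[, "p"],
                    row.names = NULL)
  out$padj <- benjaminiHochberg(out$pvalue)
  out
}

#' Fractions of ions with altered levels
#'
#' Percentage of all measured ions passing both thresholds, split by the
#' sign of the fold-change. The denominator is every measured ion.
#'
#' @param diff a \code{\link{differentialIons}} table
#' @param p unadjusted p-value threshold (default 0.05)
#' @param absLfc absolute log2 fold-change threshold (default 0.5)
#' @return named numeric c(increased, decreased), in percent
#' @export
alteredFraction <- function(diff, p = 0.05, absLfc = 0.5) {
  pass <- !is.na(diff$pvalue) & diff$pvalue <= p &
    abs(diff$log2FC) >= absLfc
  n <- nrow(diff)
  c(increased = 100 * sum(pass & diff$log2FC > 0) / n,
    decreased = 100 * sum(pass & diff$log2FC < 0) / n)
}

# pathway -> ion sets: union over each ion's candidate metabolites.
# Duplicate annotations collapse, so results are invariant to repeated
# (ion, metabolite) rows.
pathwayIonSets <- function(ionToMet, metToPath) {
  stopifnot(all(c("ion_id", "metabolite_id") %in% names(ionToMet)),
            all(c("metabolite_id", "pathway_id") %in% names(metToPath)))
  mp <- merge(unique(ionToMet), unique(metToPath), by = "metabolite_id")
  split(mp$ion_id, mp$pathway_id) |> lapply(unique)
}

#' Rank-subset (prefix) Fisher pathway enrichment
#'
#' Significant ions of one direction (|log2FC| >= absLfc, adjusted
#' p < padjThresh, sign matching `direction`) are sorted by adjusted
#' p-value. For every prefix of size 1..n of that ranked list, each
#' pathway is tested for over-representation in the prefix with a
#' one-sided Fisher exact test over the full measured-ion universe; the
#' smallest p-value across prefixes is reported per pathway, together
#' with the prefix size attaining it, then adjusted across pathways by
#' Benjamini-Hochberg.
#'
#' @param diff a \code{\link{differentialIons}} table for one timepoint
#' @param ionToMet,metToPath annotation tables (ion -> metabolite,
#'   metabolite -> pathway)
#' @param direction "increased" or "decreased"
#' @param absLfc,padjThresh significance thresholds for the ranked list
#'   (defaults 0.5 and 0.1)
#' @param universe "all" (every measured ion, default) or "annotated"
#' @return data.frame with pathway_id, direction, timepoint, minP,
#'   prefixSize, pathwaySize, overlapAtMin, padj; zero rows when no ion
#'   is significant
#' @export
rankSubsetEnrichment <- function(diff, ionToMet, metToPath,
                                 direction = c("increased", "decreased"),
                                 absLfc = 0.5, padjThresh = 0.1,
                                 universe = c("all", "annotated")) {
  direction <- match.arg(direction)
  universe <- match.arg(universe)
  sets <- pathwayIonSets(ionToMet, metToPath)
  univ <- if (universe == "all") unique(diff$ion_id)
          else intersect(unique(diff$ion_id), unique(ionToMet$ion_id))
  sets <- lapply(sets, intersect, univ)
  sets <- sets[lengths(sets) > 0]
  N <- length(univ)

  sgn <- if (direction == "increased") 1 else -1
  sig <- !is.na(diff$padj) & diff$padj < padjThresh &
    abs(diff$log2FC) >= absLfc & sign(diff$log2FC) == sgn &
    diff$ion_id %in% univ
  empty <- data.frame(pathway_id = character(0), direction = character(0),
                      timepoint = numeric(0), minP = numeric(0),
                      prefixSize = integer(0), pathwaySize = integer(0),
                      overlapAtMin = integer(0), padj = numeric(0))
  if (!any(sig)) return(empty)
  sl <- diff[sig, ]
  ## deterministic ranking: adjusted p, then |log2FC| descending, then id
  sl <- sl[order(sl$padj, -abs(sl$log2FC), sl$ion_id), ]
  ranked <- sl$ion_id
  n <- length(ranked)

  rows <- lapply(names(sets), function(pw) {
    inPw <- ranked %in% sets[[pw]]
    K <- length(sets[[pw]])
    aCum <- cumsum(inPw)
    ps <- vapply(seq_len(n), function(s) {
      a <- aCum[s]
      fisherGreater(c(a, s - a, K - a, N - s - (K - a)))
    }, 0)
    sMin <- which.min(ps)
    data.frame(pathway_id = pw, direction = direction,
               timepoint = diff$timepoint[1], minP = ps[sMin],
               prefixSize = sMin, pathwaySize = K,
               overlapAtMin = aCum[sMin])
  })
  out <- do.call(rbind, rows)
  out$padj <- benjaminiHochberg(out$minP)
  out[order(out$padj, out$minP), ]
}
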