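## Per-genome library-size normalization and dispersion estimation.
##
## The central normalization contract of the dual-genome design: reads
## mapping to each genome are normalized independently of the other, so
## the global swing of the read pool towards the phage is removed and
## within-genome expression shifts can be tested for. Size factors are
## median-of-ratios against a geometric-mean pseudo-sample, computed from
## exactly one genome's (non-rRNA) features.

#' Median-of-ratios size factors for one genome
#'
#' Per-feature geometric means are computed across samples (features with
#' any zero count are excluded from the reference); each sample's size
#' factor is the median of its count/geometric-mean ratios.
#'
#' @param dce a \linkS4class{DualCountExperiment}, or a plain count matrix
#' @param genome which genome's features to use ("phage" or "host");
#'   ignored for a plain matrix
#' @param pseudoReference if TRUE, fall back to adding 0.5 to every count
#'   when no feature is nonzero in all samples (sparse matrices)
#' @return named numeric vector of positive per-sample factors, with the
#'   genome scope in \code{attr(, "genome")}
#' @export
sizeFactorsGenome <- function(dce, genome = c("phage", "host"),
                              pseudoReference = FALSE) {
  if (is(dce, "DualCountExperiment")) {
    genome <- match.arg(genome)
    rd <- SummarizedExperiment::rowData(dce)
    keep <- rd$genome == genome & rd$class != "rRNA"
    cts <- SummarizedExperiment::assay(dce, "counts")[keep, , drop = FALSE]
  } else {
    cts <- as.matrix(dce)
    genome <- "matrix"
  }
  if (nrow(cts) == 0) stop("no features for genome ", genome)
  allNonzero <- rowSums(cts == 0) == 0
  if (!any(allNonzero)) {
    if (!pseudoReference)
      stop("no feature of genome '", genome, "' is nonzero in all ",
           "samples; consider pseudoReference = TRUE")
    cts <- cts + 0.5
    allNonzero <- rep(TRUE, nrow(cts))
  }
  lc <- log(cts[allNonzero, , drop = FALSE])
  logGeo <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(median(col - logGeo)))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  structure(sf, genome = genome)
}

#' Per-feature negative-binomial dispersions (method of moments with
#' trend shrinkage)
#'
#' Counts are normalized by the size factors; for every feature the
#' within-condition mean and pooled variance give the moment estimate
#' \code{alpha = max(0, (s^2 - mu) / mu^2)} of the NB dispersion
#' (variance mu + alpha mu^2). Raw estimates are then shrunk towards a
#' fitted mean-dispersion trend \code{alpha_tr(mu) = a0/mu + a1} by
#' weighted averaging, which stabilises the noisy per-feature moments at
#' the few replicates typical of these designs.
#'
#' @param counts integer matrix, features x samples
#' @param sf per-sample size factors
#' @param condition per-sample condition labels; at least one condition
#'   needs >= 2 replicates
#' @param trendWeight weight of the trend in the shrunk estimate
#'   (default 0.5)
#' @return list with `alpha` (shrunk, used for testing), `alphaRaw`,
#'   `trend` coefficients (a0, a1) and `mu` (per-feature mean of
#'   normalized counts)
#' @export
estimateFeatureDispersions <- function(counts, sf, condition,
                                       trendWeight = 0.5) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  stopifnot(ncol(counts) == length(sf), ncol(counts) == length(condition))
  tab <- table(condition)
  if (!any(tab >= 2))
    stop("dispersion estimation needs >= 2 replicates in >= 1 condition",
         " (use descriptive mode for single-replicate designs)")
  q <- sweep(counts, 2, sf, "/")
  useCond <- names(tab)[tab >= 2]
  ssq <- 0; df <- 0
  for (cc in useCond) {
    qc <- q[, condition == cc, drop = FALSE]
    m <- rowMeans(qc)
    ssq <- ssq + rowSums((qc - m)^2)
    df <- df + ncol(qc) - 1
  }
  s2 <- ssq / df
  mu <- rowMeans(q[, condition %in% useCond, drop = FALSE])
  alphaRaw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  ## mean-dispersion trend alpha_tr(mu) = a0/mu + a1
  ok <- mu > 0
  if (sum(ok) >= 10) {
    fit <- lm(alphaRaw[ok] ~ I(1 / mu[ok]))
    a1 <- max(coef(fit)[1], 1e-8)
    a0 <- max(coef(fit)[2], 0)
  } else {
    a1 <- max(mean(alphaRaw[ok]), 1e-8); a0 <- 0
  }
  trend <- ifelse(mu > 0, a0 / mu + a1, a1)
  alpha <- pmax((1 - trendWeight) * alphaRaw + trendWeight * trend, 1e-8)
  list(alpha = alpha, alphaRaw = alphaRaw, trend = c(a0 = a0, a1 = a1),
       mu = mu)
}
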