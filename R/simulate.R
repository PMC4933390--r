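## Seeded simulators for every input the pipeline consumes. Each returns
## the simulated object(s) plus a `truth` record holding the generator
## name, seed, all generating parameters and the planted effects, and is
## bit-reproducible under a fixed seed.

truthRecord <- function(generator, seed, params, planted = NULL)
  list(generator = generator, seed = as.integer(seed), params = params,
       planted = planted)

#' Simulate a one-step growth titer series
#'
#' The -CHCl3 arm follows \code{plateauNoChcl3 + a/(1+exp(-k(t-xc)))}
#' (infective-centre plateau, then release of progeny); the +CHCl3 arm
#' follows the same logistic shifted left by \code{eclipseOffset}
#' minutes on a residual free-phage floor (chloroform reveals
#' intracellular virions before release). Multiplicative lognormal noise
#' on the log10 scale.
#'
#' Defaults reproduce the kinetics of a fast lytic myovirus: closed-form
#' eclipse 12.3 min, latency 13.0 min, cycle 18 min and a burst size of
#' ~53 progeny per infected cell.
#'
#' @param a logistic asymptote of the titer rise (pfu/mL)
#' @param k logistic slope (1/min)
#' @param xc inflection abscissa = mean cycle duration (min)
#' @param eclipseOffset left shift of the +CHCl3 curve (min)
#' @param plateauNoChcl3,plateauChcl3 pre-release titer floors (pfu/mL)
#' @param noiseSigmaLog10 SD of the lognormal noise on log10 titer
#' @param times sampling times (min)
#' @param nReps number of independent replicates
#' @param seed integer RNG seed
#' @return list(series = \linkS4class{TiterSeries} with both arms,
#'   truth = truth record incl. closed-form growth parameters)
#' @export
simulateTiterSeries <- function(a = 5.2e7, k = 0.58889, xc = 18,
                                eclipseOffset = 0.7,
                                plateauNoChcl3 = 1.05e6,
                                plateauChcl3 = 5e4,
                                noiseSigmaLog10 = 0.05,
                                times = seq(0, 30, by = 2), nReps = 4,
                                seed = 1) {
  withSeed(seed, {
    rows <- list()
    for (r in seq_len(nReps)) {
      muNo <- plateauNoChcl3 + logisticCurve(times, a, k, xc)
      muCh <- plateauChcl3 + logisticCurve(times, a, k, xc - eclipseOffset)
      noiseN <- 10^rnorm(length(times), 0, noiseSigmaLog10)
      noiseC <- 10^rnorm(length(times), 0, noiseSigmaLog10)
      rows[[length(rows) + 1L]] <- data.frame(
        time = c(times, times), titer = c(muNo * noiseN, muCh * noiseC),
        chloroform = rep(c(FALSE, TRUE), each = length(times)),
        replicate = paste0("r", r))
    }
    df <- do.call(rbind, rows)
    series <- TiterSeries(df$time, df$titer, df$chloroform, df$replicate)
    tct <- function(xcv) xcv - log(1 / 0.05 - 1) / k
    truth <- truthRecord("simulateTiterSeries", seed,
      params = list(a = a, k = k, xc = xc, eclipseOffset = eclipseOffset,
                    plateauNoChcl3 = plateauNoChcl3,
                    plateauChcl3 = plateauChcl3,
                    noiseSigmaLog10 = noiseSigmaLog10, times = times,
                    nReps = nReps),
      planted = list(
        eclipse = tct(xc - eclipseOffset), latency = tct(xc),
        cycleDuration = xc,
        burstSize = (a + (plateauNoChcl3 + plateauChcl3) / 2) /
          (plateauNoChcl3 - plateauChcl3)))
    list(series = series, truth = truth)
  })
}

#' Simulate an adsorption assay (exponential free-phage decay)
#'
#' Defaults give an adsorption rate constant k_a = 2.2e-9 mL/min and a
#' 90\%-adsorption time of ~4.6 min at the default cell density.
#'
#' @param p0 initial free-phage titer (pfu/mL)
#' @param lam decay rate (1/min)
#' @param cellDensity host density (CFU/mL); truth k_a = lam/cellDensity
#' @param times sampling times (min)
#' @param noiseSigmaLog10 lognormal noise SD on log10 titer
#' @param nReps replicates
#' @param seed integer RNG seed
#' @return list(series = \linkS4class{TiterSeries}, cellDensity, truth)
#' @export
simulateAdsorptionSeries <- function(p0 = 5e6, lam = 0.5006,
                                     cellDensity = 2.275e8,
                                     times = seq(0, 10, by = 2),
                                     noiseSigmaLog10 = 0.03, nReps = 4,
                                     seed = 1) {
  withSeed(seed, {
    rows <- lapply(seq_len(nReps), function(r) data.frame(
      time = times,
      titer = p0 * exp(-lam * times) * 10^rnorm(length(times), 0,
                                                noiseSigmaLog10),
      chloroform = FALSE, replicate = paste0("r", r)))
    df <- do.call(rbind, rows)
    truth <- truthRecord("simulateAdsorptionSeries", seed,
      params = list(p0 = p0, lam = lam, cellDensity = cellDensity,
                    times = times, noiseSigmaLog10 = noiseSigmaLog10,
                    nReps = nReps),
      planted = list(ka = lam / cellDensity,
                     adsorptionTime = log(10) / lam))
    list(series = TiterSeries(df$time, df$titer, df$chloroform,
                              df$replicate),
         cellDensity = cellDensity, truth = truth)
  })
}

#' Simulate dual-genome (phage + host) RNA-seq counts
#'
#' Per sample, the sequencing depth is split between the genomes by the
#' programmed host fraction, then distributed across features with
#' NB noise (variance mu + alpha mu^2) around lognormal baseline
#' weights carrying the planted relative fold-changes:
#' \itemize{
#'   \item a 6-gene host operon at \code{operonFold} (late vs 0),
#'   \item a host prophage block at \code{prophageFold} (late vs 0),
#'   \item further host features at +/- \code{strictFold} (late vs 0),
#'   \item phage early/middle/late programs (early features enriched at
#'     the early timepoint, late at the late one, middle peaking in the
#'     single mid sample),
#'   \item two sRNA-like phage features with strong late enrichment and
#'     a set of antisense-like phage features enriched early.
#' }
#' The default host-fraction trajectory (1, 0.5, 0.3, 0.12 at
#' 0/3.5/6.5/13 min) mirrors a transcriptome progressively taken over
#' by the phage.
#'
#' @param nHost,nPhage numbers of host/phage features (besides rRNA)
#' @param timepoints sample timepoints (min)
#' @param nReps replicates per timepoint (single-replicate timepoints
#'   are descriptive only)
#' @param hostFraction programmed host fraction of non-rRNA reads per
#'   timepoint
#' @param depth total non-rRNA read count per sample
#' @param dispersion NB dispersion alpha
#' @param operonFold,prophageFold,strictFold,nStrict planted host
#'   effects (relative, late vs 0)
#' @param earlyFold,lateFold,middleFold phage program enrichments
#' @param srnaFolds late-vs-early fold changes of the two sRNA-like
#'   phage features
#' @param nAsrna,asrnaFoldRange antisense-like phage features enriched
#'   early by folds drawn in this range
#' @param nRrna rRNA features (excluded from analyses)
#' @param seed integer RNG seed
#' @return list(dce = \linkS4class{DualCountExperiment}, truth)
#' @export
simulateDualCounts <- function(nHost = 1000, nPhage = 200,
                               timepoints = c(0, 3.5, 6.5, 13),
                               nReps = c(3, 3, 1, 3),
                               hostFraction = c(1.0, 0.5, 0.3, 0.12),
                               depth = 2e5, dispersion = 0.05,
                               operonFold = 80, prophageFold = 6.8,
                               strictFold = 4, nStrict = 20,
                               earlyFold = 8, lateFold = 8,
                               middleFold = 4,
                               srnaFolds = c(91, 12), nAsrna = 10,
                               asrnaFoldRange = c(2, 17), nRrna = 5,
                               seed = 1) {
  stopifnot(length(timepoints) == length(nReps),
            length(hostFraction) == length(nReps),
            all(hostFraction >= 0 & hostFraction <= 1))
  withSeed(seed, {
    hostIds <- sprintf("host_%04d", seq_len(nHost))
    phageIds <- sprintf("phage_%03d", seq_len(nPhage))
    wHost <- rlnorm(nHost, log(100), 1)
    wPhage <- rlnorm(nPhage, log(100), 1)

    ## planted host effects (late vs 0, applied progressively from 3.5)
    if (nHost < 18) stop("nHost must be at least 18")
    nStrict <- min(nStrict, (nHost - 16) %/% 2)
    operonIdx <- 1:6
    prophageIdx <- 7:16
    strictUpIdx <- 16 + seq_len(nStrict)
    strictDownIdx <- 16 + nStrict + seq_len(nStrict)
    hostFold13 <- rep(1, nHost)
    hostFold13[operonIdx] <- operonFold
    hostFold13[prophageIdx] <- prophageFold
    hostFold13[strictUpIdx] <- strictFold
    hostFold13[strictDownIdx] <- 1 / strictFold
    ## partial expression of the late program at 3.5 min
    hostFoldByTp <- sapply(seq_along(timepoints), function(i) {
      frac <- timepoints[i] / max(timepoints)
      hostFold13^frac
    })

    ## phage programs
    nP <- nPhage
    third <- floor(nP / 3)
    program <- rep(c("early", "middle", "late"),
                   c(third, third, nP - 2 * third))
    srnaIdx <- utils::head(which(program == "late"), 2)
    nAsrna <- min(nAsrna, sum(program == "early"))
    asrnaIdx <- utils::head(which(program == "early"), nAsrna)
    phageFoldEarly <- ifelse(program == "early", earlyFold, 1)
    phageFoldLate <- ifelse(program == "late", lateFold, 1)
    phageFoldLate[srnaIdx] <- srnaFolds[seq_along(srnaIdx)] *
      phageFoldEarly[srnaIdx]  # late-vs-early folds as specified
    asrnaFolds <- runif(nAsrna, asrnaFoldRange[1], asrnaFoldRange[2])
    phageFoldEarly[asrnaIdx] <- asrnaFolds
    phageFoldMid <- ifelse(program == "middle", middleFold,
                           sqrt(phageFoldEarly * phageFoldLate))
    program[srnaIdx] <- "sRNA-like"
    program[asrnaIdx] <- "asRNA-like"

    phageFoldByTp <- sapply(seq_along(timepoints), function(i) {
      tp <- timepoints[i]
      if (tp == 0) rep(1, nP)
      else if (tp <= 3.5) phageFoldEarly
      else if (tp < 10) phageFoldMid
      else phageFoldLate
    })

    scaleTo <- function(w, total)
      if (total <= 0) rep(0, length(w)) else w / sum(w) * total
    samples <- list(); cd <- list()
    for (i in seq_along(timepoints)) {
      muH <- scaleTo(wHost * hostFoldByTp[, i], depth * hostFraction[i])
      muP <- scaleTo(wPhage * phageFoldByTp[, i],
                     depth * (1 - hostFraction[i]))
      for (r in seq_len(nReps[i])) {
        mu <- c(muH, muP)
        cnt <- ifelse(mu == 0, 0L,
                      rnbinom(length(mu), mu = mu, size = 1 / dispersion))
        rr <- rpois(nRrna, depth * 0.05)
        samples[[length(samples) + 1L]] <- c(cnt, rr)
        cd[[length(cd) + 1L]] <- data.frame(timepoint = timepoints[i],
                                            replicate = paste0("r", r))
      }
    }
    cts <- do.call(cbind, samples)
    cdd <- do.call(rbind, cd)
    rownames(cts) <- c(hostIds, phageIds, sprintf("rrna_%02d",
                                                  seq_len(nRrna)))
    colnames(cts) <- paste0("t", cdd$timepoint, "_", cdd$replicate)

    featClass <- c(rep("CDS", nHost),
                   ifelse(program %in% c("sRNA-like"), "ncRNA",
                          ifelse(program == "asRNA-like", "asRNA", "CDS")),
                   rep("rRNA", nRrna))
    dce <- DualCountExperiment(
      cts,
      genome = c(rep("host", nHost), rep("phage", nPhage),
                 rep("host", nRrna)),
      class = featClass,
      timepoint = cdd$timepoint, replicate = cdd$replicate)

    planted <- list(
      hostFraction = setNames(hostFraction, timepoints),
      operon = data.frame(id = hostIds[operonIdx], fold = operonFold),
      prophage = data.frame(id = hostIds[prophageIdx],
                            fold = prophageFold),
      strictUp = hostIds[strictUpIdx], strictDown = hostIds[strictDownIdx],
      phageProgram = data.frame(id = phageIds, program = program),
      srna = data.frame(id = phageIds[srnaIdx],
                        lateVsEarlyFold = srnaFolds[seq_along(srnaIdx)]),
      asrna = data.frame(id = phageIds[asrnaIdx], earlyFold = asrnaFolds))
    truth <- truthRecord("simulateDualCounts", seed,
      params = list(nHost = nHost, nPhage = nPhage,
                    timepoints = timepoints, nReps = nReps,
                    hostFraction = hostFraction, depth = depth,
                    dispersion = dispersion, operonFold = operonFold,
                    prophageFold = prophageFold, strictFold = strictFold),
      planted = planted)
    list(dce = dce, truth = truth)
  })
}

#' Simulate stranded coverage with planted RNA features
#'
#' Lays out an annotated genome of alternating-strand genes separated by
#' intergenic gaps, plants intergenic sRNAs, intragenic antisense
#' blocks (half below, half above the small/long boundary) and
#' attenuated riboswitch-like 5' leaders (long transcribed leaders
#' ending at the gene start of low-expression genes), then draws
#' per-base Poisson depths.
#'
#' @param nGenes number of genes (default 60; gene 900 bp, gap 700 bp)
#' @param geneLen,gapLen layout dimensions (bp)
#' @param nSrna,nAsrna,nRibo planted feature counts per class
#' @param backgroundDepth,geneDepth,featureDepth Poisson depth means for
#'   background, gene sense coverage and planted features
#' @param riboGeneDepth sense depth of riboswitch-attenuated genes
#' @param seed integer RNG seed
#' @return list(cov = \linkS4class{StrandedCoverage}, ann = annotation
#'   GRanges, truth; `truth$planted$features` is a GRanges of planted
#'   features with their classes)
#' @export
simulateCoverage <- function(nGenes = 60, geneLen = 900, gapLen = 700,
                             nSrna = 20, nAsrna = 20, nRibo = 20,
                             backgroundDepth = 2, geneDepth = 30,
                             featureDepth = 100, riboGeneDepth = 8,
                             seed = 1) {
  if (nSrna + nRibo > nGenes || nAsrna > nGenes)
    stop("not enough genes/gaps to place the planted features")
  withSeed(seed, {
    unit <- geneLen + gapLen
    len <- nGenes * unit + gapLen
    geneStart <- gapLen + (seq_len(nGenes) - 1L) * unit + 1L
    geneEnd <- geneStart + geneLen - 1L
    geneStrand <- rep(c("+", "-"), length.out = nGenes)
    ann <- GenomicRanges::GRanges(
      "genome", IRanges::IRanges(geneStart, geneEnd), strand = geneStrand,
      type = "CDS", ID = sprintf("gene_%03d", seq_len(nGenes)))

    ## riboswitch leaders only upstream of forward-strand genes; their
    ## gap (and the remaining gaps used for sRNAs) never overlap
    plusGenes <- which(geneStrand == "+")
    if (nRibo > length(plusGenes))
      stop("nRibo exceeds the number of forward-strand genes")
    riboGene <- sort(sample(plusGenes, nRibo))
    srnaGap <- sort(sample(setdiff(seq_len(nGenes), riboGene), nSrna))
    asrnaGene <- sample(nGenes, nAsrna)

    muPlus <- rep(backgroundDepth, len)
    muMinus <- rep(backgroundDepth, len)
    addBlock <- function(mu, from, to, depth) {
      mu[from:to] <- depth; mu
    }
    senseDepth <- ifelse(seq_len(nGenes) %in% riboGene, riboGeneDepth,
                         geneDepth)
    for (i in seq_len(nGenes)) {
      if (geneStrand[i] == "+")
        muPlus <- addBlock(muPlus, geneStart[i], geneEnd[i], senseDepth[i])
      else
        muMinus <- addBlock(muMinus, geneStart[i], geneEnd[i],
                            senseDepth[i])
    }

    planted <- list()
    ## sRNAs: centred in the gap upstream of gene srnaGap[i], with
    ## clearance from both the previous gene and the next gene start
    for (i in seq_len(nSrna)) {
      g <- srnaGap[i]
      gapFrom <- geneStart[g] - gapLen; gapTo <- geneStart[g] - 1L
      w <- sample(60:280, 1)
      s <- gapFrom + 50L + sample.int(gapLen - w - 150L, 1)
      e <- s + w - 1L
      str <- sample(c("+", "-"), 1)
      if (str == "+") muPlus <- addBlock(muPlus, s, e, featureDepth)
      else muMinus <- addBlock(muMinus, s, e, featureDepth)
      planted[[length(planted) + 1L]] <- data.frame(
        start = s, end = e, strand = str, class = "sRNA")
    }
    ## antisense blocks inside genes, on the opposite strand
    for (i in seq_len(nAsrna)) {
      g <- asrnaGene[i]
      w <- if (i <= nAsrna / 2) sample(140:250, 1) else sample(310:450, 1)
      s <- geneStart[g] + 100L + sample.int(geneLen - w - 200L, 1)
      e <- s + w - 1L
      str <- if (geneStrand[g] == "+") "-" else "+"
      if (str == "+") muPlus <- addBlock(muPlus, s, e, featureDepth)
      else muMinus <- addBlock(muMinus, s, e, featureDepth)
      planted[[length(planted) + 1L]] <- data.frame(
        start = s, end = e, strand = str,
        class = if (w < 300) "asRNA_small" else "asRNA_long")
    }
    ## riboswitch leaders: long transcribed 5' leaders ending at the
    ## gene start of a weakly expressed gene
    for (i in seq_len(nRibo)) {
      g <- riboGene[i]
      w <- sample(520:650, 1)
      if (geneStrand[g] == "+") { e <- geneStart[g] - 1L; s <- e - w + 1L }
      else { s <- geneEnd[g] + 1L; e <- s + w - 1L }
      str <- geneStrand[g]
      if (str == "+") muPlus <- addBlock(muPlus, s, e, featureDepth)
      else muMinus <- addBlock(muMinus, s, e, featureDepth)
      planted[[length(planted) + 1L]] <- data.frame(
        start = s, end = e, strand = str, class = "riboswitch_candidate")
    }

    cov <- StrandedCoverage(rpois(len, muPlus), rpois(len, muMinus),
                            genome = "genome", sample = "sim")
    pl <- do.call(rbind, planted)
    plGr <- GenomicRanges::GRanges("genome",
                                   IRanges::IRanges(pl$start, pl$end),
                                   strand = pl$strand, class = pl$class)
    truth <- truthRecord("simulateCoverage", seed,
      params = list(nGenes = nGenes, geneLen = geneLen, gapLen = gapLen,
                    nSrna = nSrna, nAsrna = nAsrna, nRibo = nRibo,
                    backgroundDepth = backgroundDepth,
                    geneDepth = geneDepth, featureDepth = featureDepth,
                    riboGeneDepth = riboGeneDepth),
      planted = list(features = plGr))
    list(cov = cov, ann = ann, truth = truth)
  })
}

#' Simulate a genome with a k-mer planted inside annotated features
#'
#' Draws a random genome at the requested GC content, annotates evenly
#' spaced features of the requested class (default tRNAs, 76 bp), plants
#' the k-mer exactly \code{nCopies} times inside distinct features (in
#' the feature's own orientation), and rejection-edits any chance
#' occurrence elsewhere on either strand so the planted copies are the
#' only matches.
#'
#' @param length genome length (bp)
#' @param gc GC content (default 0.66, a high-GC bacterium)
#' @param kmer the planted k-mer (default an 11-nt tRNA T-loop-like
#'   motif)
#' @param nCopies planted copy number (default 8)
#' @param featureClass annotation type receiving the copies
#' @param nFeatures number of annotated features (>= nCopies)
#' @param featureLen feature length (default 76, a tRNA)
#' @param maxRetries rejection-editing rounds before giving up
#' @param seed integer RNG seed
#' @return list(genome = \link[Biostrings]{DNAStringSet}, ann = GRanges,
#'   truth with planted positions)
#' @export
simulateGenomeWithMotifs <- function(length = 50000, gc = 0.66,
                                     kmer = "GTTCGAATCCC", nCopies = 8,
                                     featureClass = "tRNA",
                                     nFeatures = 12, featureLen = 76,
                                     maxRetries = 50, seed = 1) {
  stopifnot(nFeatures >= nCopies, nchar(kmer) <= featureLen)
  k <- nchar(kmer)
  withSeed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqv <- sample(names(probs), length, replace = TRUE, prob = probs)

    gap <- length %/% (nFeatures + 1)
    fStart <- gap * seq_len(nFeatures) - featureLen %/% 2
    fStrand <- rep(c("+", "-"), length.out = nFeatures)
    ann <- GenomicRanges::GRanges(
      "genome", IRanges::IRanges(fStart, fStart + featureLen - 1L),
      strand = fStrand, type = featureClass,
      ID = sprintf("%s_%02d", featureClass, seq_len(nFeatures)))

    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    chosen <- sort(sample(nFeatures, nCopies))
    plantPos <- integer(nCopies)
    for (j in seq_along(chosen)) {
      i <- chosen[j]
      off <- 40L  # T-loop region of the feature
      s <- fStart[i] + off
      ins <- if (fStrand[i] == "+") kmer else rc(kmer)
      seqv[s:(s + k - 1L)] <- strsplit(ins, "")[[1]]
      plantPos[j] <- s
    }

    ## rejection-edit stray occurrences (either strand) outside plants
    genomeStr <- paste(seqv, collapse = "")
    for (try in seq_len(maxRetries)) {
      dna <- Biostrings::DNAString(genomeStr)
      pos <- c(BiocGenerics::start(Biostrings::matchPattern(kmer, dna)),
               BiocGenerics::start(Biostrings::matchPattern(rc(kmer), dna)))
      stray <- setdiff(pos, plantPos)
      if (!length(stray)) break
      for (s in stray) {
        at <- s + sample.int(k, 1) - 1L
        cur <- substring(genomeStr, at, at)
        substring(genomeStr, at, at) <- sample(setdiff(c("A", "C", "G", "T"),
                                                       cur), 1)
      }
      if (try == maxRetries)
        stop("k-mer keeps colliding with the random background")
    }
    genome <- Biostrings::DNAStringSet(genomeStr)
    names(genome) <- "genome"
    truth <- truthRecord("simulateGenomeWithMotifs", seed,
      params = list(length = length, gc = gc, kmer = kmer,
                    nCopies = nCopies, featureClass = featureClass,
                    nFeatures = nFeatures, featureLen = featureLen),
      planted = list(positions = plantPos,
                     features = ann$ID[chosen],
                     strand = fStrand[chosen]))
    list(genome = genome, ann = ann, truth = truth)
  })
}

#' Simulate a time-course ion-intensity matrix with planted pathway
#' shifts
#'
#' Lognormal baseline intensities with biological and technical noise;
#' ions are annotated to metabolites (some ions ambiguously to two) and
#' metabolites to pathways. At each non-zero timepoint a programmed
#' number of ions is shifted up or down by \code{effectLog2}; the up-set
#' always contains one focal pathway shifted coherently (all its ions),
#' and at later timepoints the down-set concentrates on a second focal
#' pathway. The default per-timepoint counts trace an altered-fraction
#' profile that rises among increased ions and dips then recovers among
#' decreased ions.
#'
#' @param nIons measured ions (default 377)
#' @param nPathways pathways in the map (default 20)
#' @param timepoints minutes (default 0, 5, 10, 15, 20, 25)
#' @param nBio,nTech biological / technical replicates (4 x 2)
#' @param nUp,nDown planted numbers of increased / decreased ions per
#'   non-zero timepoint
#' @param effectLog2 planted |log2 fold-change| (default 1)
#' @param bioSdLog,techSdLog lognormal noise SDs (natural log scale)
#' @param seed integer RNG seed
#' @return list(ie = \linkS4class{IonExperiment}, truth; truth$planted
#'   holds the per-timepoint shifted ion sets and the focal pathways)
#' @export
simulateIonMatrix <- function(nIons = 377, nPathways = 20,
                              timepoints = c(0, 5, 10, 15, 20, 25),
                              nBio = 4, nTech = 2,
                              nUp = c(52, 60, 68, 75, 83),
                              nDown = c(32, 20, 11, 28, 49),
                              effectLog2 = 1, bioSdLog = 0.2,
                              techSdLog = 0.05, seed = 1) {
  nt <- length(timepoints) - 1L
  stopifnot(length(nUp) == nt, length(nDown) == nt)
  withSeed(seed, {
    ionIds <- sprintf("ion_%03d", seq_len(nIons))
    metIds <- sprintf("met_%03d", seq_len(nIons))
    ## ~37% of ions carry a second candidate metabolite (mass isomers)
    extra <- sample(nIons, round(0.37 * nIons))
    ionToMet <- rbind(
      data.frame(ion_id = ionIds, metabolite_id = metIds),
      data.frame(ion_id = ionIds[extra],
                 metabolite_id = sprintf("met_x%03d", seq_along(extra))))
    pathIds <- sprintf("pw_%02d", seq_len(nPathways))
    metToPath <- data.frame(
      metabolite_id = ionToMet$metabolite_id,
      pathway_id = sample(pathIds, nrow(ionToMet), replace = TRUE))
    ## focal pathways with coherent membership: first 15 ions form the
    ## up-focal pathway, the next 15 the down-focal one
    upFocalIons <- ionIds[1:15]; downFocalIons <- ionIds[16:30]
    metToPath <- rbind(metToPath,
      data.frame(metabolite_id = metIds[1:15], pathway_id = "pw_up_focal"),
      data.frame(metabolite_id = metIds[16:30],
                 pathway_id = "pw_down_focal"))

    base <- rlnorm(nIons, log(1e4), 1)
    free <- setdiff(seq_len(nIons), 1:30)
    upSets <- list(); downSets <- list()
    for (i in seq_len(nt)) {
      ups <- if (nUp[i] >= 15) c(1:15, sample(free, nUp[i] - 15))
             else sample(1:15, nUp[i])
      dns <- if (nDown[i] <= 15) sample(16:30, nDown[i])
             else c(16:30, sample(setdiff(free, ups), nDown[i] - 15))
      upSets[[i]] <- ionIds[ups]; downSets[[i]] <- ionIds[dns]
    }

    cols <- list(); cd <- list()
    for (ti in seq_along(timepoints)) {
      tp <- timepoints[ti]
      eff <- rep(0, nIons)
      if (ti > 1) {
        eff[match(upSets[[ti - 1]], ionIds)] <- effectLog2
        eff[match(downSets[[ti - 1]], ionIds)] <- -effectLog2
      }
      mu <- base * 2^eff
      for (b in seq_len(nBio)) {
        bioNoise <- rlnorm(nIons, 0, bioSdLog)
        for (te in seq_len(nTech)) {
          cols[[length(cols) + 1L]] <-
            mu * bioNoise * rlnorm(nIons, 0, techSdLog)
          cd[[length(cd) + 1L]] <- data.frame(time_min = tp, bio_rep = b,
                                              tech_rep = te)
        }
      }
    }
    X <- do.call(cbind, cols)
    cdd <- do.call(rbind, cd)
    rownames(X) <- ionIds
    colnames(X) <- sprintf("t%g_b%d_t%d", cdd$time_min, cdd$bio_rep,
                           cdd$tech_rep)
    ie <- IonExperiment(X, time_min = cdd$time_min, bio_rep = cdd$bio_rep,
                        tech_rep = cdd$tech_rep, ionToMet = ionToMet,
                        metToPath = metToPath)
    truth <- truthRecord("simulateIonMatrix", seed,
      params = list(nIons = nIons, nPathways = nPathways,
                    timepoints = timepoints, nBio = nBio, nTech = nTech,
                    nUp = nUp, nDown = nDown, effectLog2 = effectLog2,
                    bioSdLog = bioSdLog, techSdLog = techSdLog),
      planted = list(upSets = setNames(upSets, timepoints[-1]),
                     downSets = setNames(downSets, timepoints[-1]),
                     upFocalPathway = "pw_up_focal",
                     downFocalPathway = "pw_down_focal",
                     upFocalIons = upFocalIons,
                     downFocalIons = downFocalIons))
    list(ie = ie, truth = truth)
  })
}
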