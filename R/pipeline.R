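## Umbrella pipeline: simulate every input under one seed, run all
## analysis stages in dependency order and write versioned outputs plus
## a machine-readable summary.

#' Run the full simulate-then-analyse pipeline
#'
#' Executes, under a single seed: growth-kinetics estimation on a
#' simulated one-step growth curve and adsorption assay; takeover,
#' per-genome differential expression and temporal classification on
#' simulated dual-genome counts; RNA-feature calling on simulated
#' stranded coverage; k-mer scanning on a simulated motif-planted
#' genome; and the metabolomics time course with pathway enrichment.
#' Stage parameters can be overridden through `config` (a nested list,
#' or a YAML file when the yaml package is available).
#'
#' @param seed integer seed driving every simulator (sub-seeds are
#'   derived per stage)
#' @param outDir output directory (created); NULL skips file output
#' @param config nested list of per-stage parameter overrides, or a
#'   YAML file path; unknown stage names are rejected
#' @return invisible list with every stage's objects and a `summary`
#'   list of headline numbers
#' @export
runTakeoverPipeline <- function(seed = 1, outDir = NULL, config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  known <- c("titer", "adsorption", "counts", "coverage", "motifs", "ions")
  if (length(config) && !all(names(config) %in% known))
    stop("unknown config stage(s): ",
         paste(setdiff(names(config), known), collapse = ", "))
  stageArgs <- function(stage) {
    args <- config[[stage]]
    args$seed <- subSeed(seed, stage)
    args
  }

  ## growth kinetics
  ts <- do.call(simulateTiterSeries, stageArgs("titer"))
  growth <- summarizeGrowth(ts$series)
  ads <- do.call(simulateAdsorptionSeries,
                 stageArgs("adsorption"))
  adsFit <- fitAdsorption(ads$series, ads$cellDensity)

  ## dual-genome transcriptomics
  dc <- do.call(simulateDualCounts, stageArgs("counts"))
  takeover <- computeTakeover(dc$dce)
  tps <- sort(unique(takeover$timepoint))
  depletion <- hostDepletionFactor(takeover, min(tps), max(tps))
  deHost <- nbWaldTest(dc$dce, "host", contrast = c(min(tps), max(tps)))
  deHost <- relativeHostShift(deHost, depletion)
  early <- 3.5; late <- max(tps)
  dePhage <- nbWaldTest(dc$dce, "phage", contrast = c(early, late))
  cd <- SummarizedExperiment::colData(dc$dce)
  mid <- which(cd$timepoint == 6.5)
  expr6p5 <- NULL
  if (length(mid) == 1) {
    rd <- SummarizedExperiment::rowData(dc$dce)
    selP <- rd$genome == "phage" & rd$class != "rRNA"
    sfAll <- sizeFactorsGenome(dc$dce, "phage", pseudoReference = TRUE)
    q <- SummarizedExperiment::assay(dc$dce, "counts")[selP, mid] /
      sfAll[mid]
    expr6p5 <- setNames(q, rownames(dc$dce)[selP])
  }
  temporal <- classifyTemporal(dePhage, expr6p5)

  ## RNA features
  cv <- do.call(simulateCoverage, stageArgs("coverage"))
  calls <- c(callIntergenicSrna(cv$cov, cv$ann),
             callAntisense(cv$cov, cv$ann),
             callRiboswitchCandidates(cv$cov, cv$ann))
  callEval <- evaluateCalls(calls, cv$truth$planted$features)

  ## k-mer scan
  mg <- do.call(simulateGenomeWithMotifs, stageArgs("motifs"))
  hits <- scanKmers(mg$truth$params$kmer, mg$genome, mg$ann,
                    k = nchar(mg$truth$params$kmer))

  ## metabolomics
  im <- do.call(simulateIonMatrix, stageArgs("ions"))
  ionTps <- setdiff(sort(unique(
    SummarizedExperiment::colData(im$ie)$time_min)), 0)
  diffs <- lapply(ionTps, function(tt) differentialIons(im$ie, tt))
  names(diffs) <- ionTps
  altered <- t(vapply(diffs, alteredFraction, numeric(2)))
  ann <- S4Vectors::metadata(im$ie)
  enrich <- lapply(diffs, function(d)
    rankSubsetEnrichment(d, ann$ionToMet, ann$metToPath, "increased"))

  summary <- list(
    eclipse_min = growth$parameters@eclipse,
    latency_min = growth$parameters@latency,
    cycle_duration_min = growth$parameters@cycleDuration,
    burst_size = growth$parameters@burstSize,
    adsorption_time_min = adsFit@adsorptionTime,
    adsorption_rate_constant_ml_min = adsFit@ka,
    host_fraction_late_pct = 100 *
      mean(takeover$hostFraction[takeover$timepoint == max(tps)]),
    host_depletion_factor = depletion,
    n_host_de = sum(applyDEPreset(deHost, "paper-host-strict")),
    n_phage_early = sum(temporal == "early"),
    n_phage_late = sum(temporal == "late"),
    feature_call_min_precision = min(callEval$precision),
    feature_call_min_recall = min(callEval$recall),
    kmer_hits = nrow(hits),
    altered_increased_pct_first = unname(altered[1, "increased"]),
    altered_decreased_pct_first = unname(altered[1, "decreased"]))

  result <- list(growth = growth, adsorption = adsFit,
                 takeover = takeover, depletion = depletion,
                 deHost = deHost, dePhage = dePhage, temporal = temporal,
                 calls = calls, callEval = callEval, kmerHits = hits,
                 ionDiffs = diffs, altered = altered, enrichment = enrich,
                 truth = list(titer = ts$truth, counts = dc$truth,
                              coverage = cv$truth, motifs = mg$truth,
                              ions = im$truth),
                 seed = seed, summary = summary)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) write.table(
      x, file.path(outDir, f), sep = "\t", quote = FALSE)
    wr(growth$perReplicate, "growth_per_replicate.tsv")
    wr(takeover, "takeover.tsv")
    wr(deHost, "de_host.tsv")
    wr(dePhage, "de_phage.tsv")
    writeCalls(calls, file.path(outDir, "calls.gff3"),
               file.path(outDir, "calls.tsv"))
    wr(hits, "kmer_hits.tsv")
    for (tt in names(diffs)) wr(diffs[[tt]], paste0("ions_t", tt, ".tsv"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(seed = seed, config = config),
                         file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
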