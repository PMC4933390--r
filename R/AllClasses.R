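## S4 classes for the central data containers.

#' Replicated phage-titer observations over time
#'
#' Container for one-step growth / adsorption assay titrations: time in
#' minutes post-mixing, titer in pfu/mL, a chloroform flag separating the
#' +CHCl3 (free + intracellular phage) arm from the -CHCl3 (free phage +
#' infective centres) arm, and a replicate identifier.
#'
#' Non-positive titers are below-detection events: the constructor drops
#' them with a warning rather than imputing.
#'
#' @slot time numeric, minutes (>= 0)
#' @slot titer numeric, pfu/mL (> 0)
#' @slot chloroform logical, TRUE for the +CHCl3 arm
#' @slot replicate character replicate identifier
#' @aliases TiterSeries-class
#' @exportClass TiterSeries
setClass("TiterSeries",
  representation(
    time = "numeric",
    titer = "numeric",
    chloroform = "logical",
    replicate = "character"
  ),
  validity = function(object) {
    msg <- NULL
    n <- length(object@time)
    if (length(object@titer) != n || length(object@chloroform) != n ||
        length(object@replicate) != n)
      msg <- c(msg, "all slots must have equal length")
    if (any(object@time < 0)) msg <- c(msg, "time must be >= 0")
    if (any(object@titer <= 0)) msg <- c(msg, "titer must be > 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a TiterSeries
#'
#' @param time numeric vector of minutes post-mixing (>= 0)
#' @param titer numeric vector of titers in pfu/mL; non-positive values
#'   are treated as below detection and dropped with a warning
#' @param chloroform logical vector (or 0/1), TRUE for +CHCl3 samples
#' @param replicate replicate identifiers (coerced to character)
#' @return a \linkS4class{TiterSeries}
#' @examples
#' ts <- TiterSeries(time = c(0, 2, 4), titer = c(1e6, 2e6, 8e6),
#'                   chloroform = FALSE, replicate = "r1")
#' @export
TiterSeries <- function(time, titer, chloroform = FALSE, replicate = "r1") {
  n <- length(time)
  chloroform <- as.logical(rep_len(chloroform, n))
  replicate <- as.character(rep_len(replicate, n))
  bad <- !is.finite(titer) | titer <= 0
  if (any(bad)) {
    warning(sum(bad), " below-detection (non-positive) titer(s) dropped")
    time <- time[!bad]; titer <- titer[!bad]
    chloroform <- chloroform[!bad]; replicate <- replicate[!bad]
  }
  new("TiterSeries", time = as.numeric(time), titer = as.numeric(titer),
      chloroform = chloroform, replicate = replicate)
}

setMethod("show", "TiterSeries", function(object) {
  cat("TiterSeries with", length(object@time), "observations,",
      length(unique(object@replicate)), "replicate(s)\n")
  cat("  time range:", paste(range(object@time), collapse = "-"), "min;",
      sum(object@chloroform), "+CHCl3 /", sum(!object@chloroform),
      "-CHCl3 samples\n")
})

#' Logistic growth-curve fit result
#'
#' Parameters of f(x) = baseline + a / (1 + exp(-k (x - xc))) fitted to
#' log10 titers. `a` is the asymptotic titer rise (pfu/mL), `xc` the
#' inflection abscissa (minutes; for the -CHCl3 curve this is the mean
#' infection-cycle duration), `k` the slope parameter (1/min).
#'
#' @slot a,k,xc numeric fitted parameters
#' @slot se named numeric standard errors of (a, k, xc)
#' @slot baseline fixed additive floor used during fitting (pfu/mL)
#' @slot residNorm residual norm on the fitted (log10) scale
#' @slot converged logical
#' @slot flag character; "" or a degeneracy note such as "flat"
#' @exportClass LogisticFit
setClass("LogisticFit",
  representation(a = "numeric", k = "numeric", xc = "numeric",
                 se = "numeric", baseline = "numeric",
                 residNorm = "numeric", converged = "logical",
                 flag = "character"),
  prototype(se = c(a = NA_real_, k = NA_real_, xc = NA_real_),
            baseline = 0, residNorm = NA_real_, converged = FALSE,
            flag = ""),
  validity = function(object) {
    if (isTRUE(object@converged)) {
      if (!(object@a > 0)) return("a must be > 0")
      if (!(object@k > 0)) return("k must be > 0")
    }
    TRUE
  }
)

setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit:",
      if (object@converged) "converged" else "NOT converged",
      if (nzchar(object@flag)) paste0("[", object@flag, "]") else "", "\n")
  cat(sprintf("  a = %.4g  k = %.4g /min  xc = %.4g min  (baseline %.3g)\n",
              object@a, object@k, object@xc, object@baseline))
})

#' Adsorption-kinetics fit result
#'
#' Exponential free-phage decay p(t) = p0 exp(-lam t). The second-order
#' adsorption rate constant is k_a = lam / cell density (mL/min) and the
#' adsorption time is the time to reach 10\% non-adsorbed particles,
#' ln(10)/lam.
#'
#' @slot p0 initial free-phage titer (pfu/mL)
#' @slot lam exponential decay rate (1/min)
#' @slot ka adsorption rate constant (mL/min)
#' @slot adsorptionTime minutes to 10\% non-adsorbed phage
#' @slot cellDensity host density used (CFU/mL)
#' @exportClass AdsorptionFit
setClass("AdsorptionFit",
  representation(p0 = "numeric", lam = "numeric", ka = "numeric",
                 adsorptionTime = "numeric", cellDensity = "numeric"),
  validity = function(object) {
    if (!(object@lam > 0)) return("lam must be > 0")
    TRUE
  }
)

setMethod("show", "AdsorptionFit", function(object) {
  cat(sprintf(
    "AdsorptionFit: lam = %.4g /min, k_a = %.4g mL/min, 90%% adsorbed in %.3g min\n",
    object@lam, object@ka, object@adsorptionTime))
})

#' Infection-cycle parameters
#'
#' @slot eclipse minutes to first intracellular assembled virions
#' @slot latency minutes to first spontaneous release of progeny
#' @slot cycleDuration mean infection-cycle duration (minutes)
#' @slot burstSize mean progeny per infected cell (NA until computed)
#' @exportClass GrowthParameters
setClass("GrowthParameters",
  representation(eclipse = "numeric", latency = "numeric",
                 cycleDuration = "numeric", burstSize = "numeric"),
  prototype(burstSize = NA_real_),
  validity = function(object) {
    if (!is.na(object@burstSize) && object@burstSize <= 0)
      return("burstSize must be > 0")
    TRUE
  }
)

setMethod("show", "GrowthParameters", function(object) {
  cat(sprintf(
    "GrowthParameters: eclipse %.3g min, latency %.3g min, cycle %.3g min, burst %.3g\n",
    object@eclipse, object@latency, object@cycleDuration, object@burstSize))
  if (!is.na(object@eclipse) && !is.na(object@latency) &&
      object@eclipse > object@latency)
    warning("eclipse exceeds latency; noisy fits?", call. = FALSE)
})

#' Dual-genome count experiment
#'
#' A \linkS4class{SummarizedExperiment} with a `counts` assay whose rows
#' are features tagged with their source genome (`phage` or `host`), a
#' feature class (CDS, ncRNA, asRNA, rRNA, bin250, ...), strand and
#' coordinates, and whose columns are samples with `timepoint` and
#' `replicate` metadata. rRNA-class features are retained in the object
#' but excluded from takeover and differential-expression computations.
#'
#' @aliases DualCountExperiment-class
#' @exportClass DualCountExperiment
setClass("DualCountExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"counts" %in% names(SummarizedExperiment::assays(object)))
      msg <- c(msg, "assay 'counts' is required")
    else {
      cts <- SummarizedExperiment::assay(object, "counts")
      if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(cts != round(cts))) msg <- c(msg, "counts must be integers")
    }
    rd <- SummarizedExperiment::rowData(object)
    for (col in c("genome", "class"))
      if (!col %in% names(rd)) msg <- c(msg, paste0("rowData$", col, " required"))
    if ("genome" %in% names(rd) &&
        !all(rd$genome %in% c("phage", "host")))
      msg <- c(msg, "genome must be 'phage' or 'host'")
    cd <- SummarizedExperiment::colData(object)
    if (!"timepoint" %in% names(cd)) msg <- c(msg, "colData$timepoint required")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a DualCountExperiment
#'
#' @param counts integer matrix, features x samples
#' @param genome character per feature, "phage" or "host"
#' @param class feature class per feature (default "CDS"); features of
#'   class "rRNA" are excluded from takeover and DE computations
#' @param strand per-feature strand ("+", "-" or "*")
#' @param start,end optional 1-based inclusive feature coordinates
#' @param timepoint per-sample timepoint (minutes)
#' @param replicate per-sample biological replicate id
#' @return a \linkS4class{DualCountExperiment}
#' @export
DualCountExperiment <- function(counts, genome, class = "CDS", strand = "*",
                                start = NA_integer_, end = NA_integer_,
                                timepoint, replicate = seq_len(ncol(counts))) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  nf <- nrow(counts)
  rd <- S4Vectors::DataFrame(
    genome = rep_len(as.character(genome), nf),
    class = rep_len(as.character(class), nf),
    strand = rep_len(as.character(strand), nf),
    start = rep_len(as.integer(start), nf),
    end = rep_len(as.integer(end), nf),
    row.names = rownames(counts))
  cd <- S4Vectors::DataFrame(
    timepoint = rep_len(timepoint, ncol(counts)),
    replicate = as.character(rep_len(replicate, ncol(counts))),
    row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  new("DualCountExperiment", se)
}

setMethod("show", "DualCountExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("DualCountExperiment:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  phage:", sum(rd$genome == "phage"), " host:",
      sum(rd$genome == "host"), " (rRNA:", sum(rd$class == "rRNA"), ")\n")
  cat("  timepoints:", paste(unique(
    SummarizedExperiment::colData(object)$timepoint), collapse = ", "), "\n")
})

#' Stranded per-base coverage over one genome
#'
#' Per-base read depth for the forward and reverse strands of a single
#' genome, for one sample (or a replicate-averaged track).
#'
#' @slot genome genome identifier
#' @slot plus,minus numeric per-base depth vectors (equal length = genome
#'   length, depths >= 0)
#' @slot sample sample identifier
#' @aliases StrandedCoverage-class
#' @exportClass StrandedCoverage
setClass("StrandedCoverage",
  representation(genome = "character", plus = "numeric", minus = "numeric",
                 sample = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@plus) != length(object@minus))
      msg <- c(msg, "plus and minus tracks must have equal length")
    if (any(object@plus < 0) || any(object@minus < 0))
      msg <- c(msg, "depths must be >= 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a StrandedCoverage track pair
#'
#' @param plus,minus numeric per-base depths (forward / reverse strand)
#' @param genome genome identifier
#' @param sample sample identifier
#' @export
StrandedCoverage <- function(plus, minus, genome = "genome", sample = "s1") {
  new("StrandedCoverage", genome = as.character(genome),
      plus = as.numeric(plus), minus = as.numeric(minus),
      sample = as.character(sample))
}

setMethod("show", "StrandedCoverage", function(object) {
  cat("StrandedCoverage for", object@genome, "(", length(object@plus),
      "bp ), sample", object@sample, "\n")
  cat(sprintf("  mean depth +: %.2f  -: %.2f\n",
              mean(object@plus), mean(object@minus)))
})

#' Genome length of a coverage track
#' @param x a \linkS4class{StrandedCoverage}
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname genomeLength
setMethod("genomeLength", "StrandedCoverage", function(x) length(x@plus))

#' Strand depth accessors
#' @param x a \linkS4class{StrandedCoverage}
#' @return numeric per-base depth vector
#' @export
setGeneric("plusDepth", function(x) standardGeneric("plusDepth"))
#' @rdname plusDepth
setMethod("plusDepth", "StrandedCoverage", function(x) x@plus)
#' @rdname plusDepth
#' @export
setGeneric("minusDepth", function(x) standardGeneric("minusDepth"))
#' @rdname plusDepth
setMethod("minusDepth", "StrandedCoverage", function(x) x@minus)

#' Ion-intensity experiment for time-course metabolomics
#'
#' A \linkS4class{SummarizedExperiment} with a strictly positive
#' `intensity` assay (ions x samples), sample metadata
#' (`time_min`, `bio_rep`, `tech_rep`) and, in `metadata()`, the ion ->
#' metabolite (`ionToMet`) and metabolite -> pathway (`metToPath`)
#' annotation tables.
#'
#' @aliases IonExperiment-class
#' @exportClass IonExperiment
setClass("IonExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"intensity" %in% names(SummarizedExperiment::assays(object)))
      msg <- c(msg, "assay 'intensity' is required")
    else if (any(SummarizedExperiment::assay(object, "intensity") <= 0))
      msg <- c(msg, "intensities must be strictly positive")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("time_min", "bio_rep", "tech_rep"))
      if (!col %in% names(cd)) msg <- c(msg, paste0("colData$", col, " required"))
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct an IonExperiment
#'
#' @param intensity positive numeric matrix, ions x samples
#' @param time_min per-sample timepoint in minutes
#' @param bio_rep,tech_rep per-sample biological / technical replicate ids
#' @param ionToMet data.frame with columns `ion_id`, `metabolite_id`
#' @param metToPath data.frame with columns `metabolite_id`, `pathway_id`
#' @return an \linkS4class{IonExperiment}
#' @export
IonExperiment <- function(intensity, time_min, bio_rep, tech_rep = 1,
                          ionToMet = NULL, metToPath = NULL) {
  intensity <- as.matrix(intensity)
  ns <- ncol(intensity)
  cd <- S4Vectors::DataFrame(
    time_min = rep_len(time_min, ns),
    bio_rep = as.character(rep_len(bio_rep, ns)),
    tech_rep = as.character(rep_len(tech_rep, ns)),
    row.names = colnames(intensity))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), colData = cd)
  obj <- new("IonExperiment", se)
  S4Vectors::metadata(obj)$ionToMet <- ionToMet
  S4Vectors::metadata(obj)$metToPath <- metToPath
  obj
}

setMethod("show", "IonExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("IonExperiment:", nrow(object), "ions x", ncol(object), "samples\n")
  cat("  timepoints:", paste(sort(unique(cd$time_min)), collapse = ", "),
      "min;", length(unique(cd$bio_rep)), "bio x",
      length(unique(cd$tech_rep)), "tech replicates\n")
  ann <- S4Vectors::metadata(object)$ionToMet
  if (!is.null(ann))
    cat("  annotated ions:", length(unique(ann$ion_id)), "\n")
})
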