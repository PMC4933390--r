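## One-step growth-curve and adsorption kinetics.
##
## The one-step growth curve is modelled as a logistic rise of the titer,
## f(x) = a / (1 + exp(-k (x - xc))),
## fitted on the log10 scale (titers span orders of magnitude). `a` is the
## final plateau, `xc` the inflection point (for the -CHCl3 curve, the mean
## infection-cycle duration) and `k` the slope of the exponential rise.
## Eclipse and latency are read off each arm's fit as the first time the
## curve exceeds 5% of its asymptote; burst size is the released progeny
## per infective centre. Adsorption is an exponential free-phage decay.

logisticCurve <- function(x, a, k, xc) a / (1 + exp(-k * (x - xc)))

#' Fit a logistic growth curve to titer data
#'
#' Least-squares fit of \code{baseline + a / (1 + exp(-k (x - xc)))} to
#' titers on the log10 scale, with multi-start initialisation
#' (\code{a0} = max titer; \code{xc0} = time of steepest log-titer
#' increase; \code{k0} in \{0.2, 0.5, 1, 2\}).
#'
#' The fixed \code{baseline} accounts for the titer floor present before
#' phage release: the -CHCl3 arm sits on the infective-centre plateau and
#' the +CHCl3 arm on the residual free-phage level. At \code{baseline = 0}
#' (the default) the model is the plain three-parameter logistic.
#'
#' @param series a \linkS4class{TiterSeries}
#' @param chloroform if non-NULL, keep only observations with this
#'   chloroform flag
#' @param replicates if non-NULL, keep only these replicate ids
#' @param baseline fixed additive titer floor in pfu/mL (default 0), or
#'   \code{"auto"} to estimate it as the pre-rise plateau
#' @param k0 numeric vector of slope starting values for the multi-start
#' @return a \linkS4class{LogisticFit}
#' @examples
#' tt <- seq(0, 30, 2)
#' ts <- TiterSeries(tt, 5.3e7 / (1 + exp(-0.8 * (tt - 15))))
#' fitLogistic(ts)
#' @export
fitLogistic <- function(series, chloroform = NULL, replicates = NULL,
                        baseline = 0, k0 = c(0.2, 0.5, 1, 2)) {
  stopifnot(is(series, "TiterSeries"))
  keep <- rep(TRUE, length(series@time))
  if (!is.null(chloroform)) keep <- keep & series@chloroform == chloroform
  if (!is.null(replicates)) keep <- keep & series@replicate %in% replicates
  x <- series@time[keep]; yraw <- series@titer[keep]
  if (length(unique(x)) < 5)
    stop("fitLogistic requires >= 5 distinct timepoints")
  if (identical(baseline, "auto")) baseline <- estimatePlateau(x, yraw)
  stopifnot(is.numeric(baseline), baseline >= 0)
  y <- log10(yraw)

  ## degenerate: no rise at all
  tmeans <- tapply(y, x, mean)
  if (diff(range(tmeans)) < 0.05) {
    warning("titer series is flat; logistic fit is degenerate")
    return(new("LogisticFit", a = 10^mean(y), k = NA_real_, xc = NA_real_,
               baseline = baseline, converged = FALSE, flag = "flat"))
  }

  tord <- as.numeric(names(tmeans))
  slope <- diff(tmeans) / diff(tord)
  xc0 <- mean(tord[which.max(slope) + 0:1])
  la0 <- log10(max(yraw))
  ## slope of log10 titer in the exponential phase is ~ k / ln(10)
  kEst <- max(slope) * log(10)
  k0 <- sort(unique(c(k0, kEst, 2 * kEst)))
  k0 <- k0[k0 > 0 & is.finite(k0)]
  xr <- range(x); ext <- 0.5 * diff(xr)
  lower <- c(la = la0 - 6, k = 1e-4, xc = xr[1] - ext)
  upper <- c(la = la0 + 3, k = 100, xc = xr[2] + ext)

  best <- NULL; bestRss <- Inf
  for (kk in k0) for (x0 in unique(c(xc0, median(x)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ log10(baseline + 10^la / (1 + exp(-k * (x - xc)))),
        start = list(la = la0, k = kk, xc = x0),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < bestRss) { best <- fit; bestRss <- rss }
    }
  }
  if (is.null(best))
    stop("logistic fit failed to converge from any start (k0 = ",
         paste(k0, collapse = ", "), ")")

  cf <- coef(best)
  sm <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) c(la = NA, k = NA, xc = NA))
  a <- 10^cf[["la"]]
  se <- c(a = unname(a * log(10) * sm[["la"]]), k = unname(sm[["k"]]),
          xc = unname(sm[["xc"]]))
  new("LogisticFit", a = a, k = cf[["k"]], xc = cf[["xc"]], se = se,
      baseline = baseline, residNorm = sqrt(bestRss), converged = TRUE)
}

# Pre-rise plateau: mean titer of timepoints whose log10 mean lies within
# 0.15 of the lowest per-timepoint mean.
estimatePlateau <- function(time, titer) {
  tm <- tapply(log10(titer), time, mean)
  10^mean(tm[tm <= min(tm) + 0.15])
}

#' Time at which a logistic fit crosses a fraction of its asymptote
#'
#' Closed form for the smallest x with f(x) > fraction * a:
#' \code{x = xc - log(1/fraction - 1) / k}. With the default
#' \code{fraction = 0.05} this is the eclipse/latency read-off.
#'
#' @param fit a converged \linkS4class{LogisticFit}
#' @param fraction proportion of the asymptote, in (0, 1)
#' @return crossing time in minutes
#' @examples
#' f <- new("LogisticFit", a = 100, k = 0.8, xc = 13, converged = TRUE)
#' thresholdCrossingTime(f)  # 13 - log(19)/0.8
#' @export
thresholdCrossingTime <- function(fit, fraction = 0.05) {
  stopifnot(is(fit, "LogisticFit"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  if (!fit@converged) stop("logistic fit did not converge")
  fit@xc - log(1 / fraction - 1) / fit@k
}

#' Eclipse, latency and cycle duration from paired logistic fits
#'
#' Eclipse is the 5\%-of-asymptote crossing of the +CHCl3 curve
#' (chloroform lysis reveals intracellular virions); latency the crossing
#' of the -CHCl3 curve (spontaneous release); cycle duration the
#' inflection abscissa of the -CHCl3 fit. Burst size is computed
#' separately from raw titers (\code{\link{burstSize}}).
#'
#' @param fitNoChcl3,fitChcl3 converged \linkS4class{LogisticFit}s for the
#'   -CHCl3 and +CHCl3 arms
#' @param fraction asymptote fraction for the crossing (default 0.05)
#' @return a \linkS4class{GrowthParameters} (burstSize NA)
#' @export
growthParameters <- function(fitNoChcl3, fitChcl3, fraction = 0.05) {
  if (!fitNoChcl3@converged || !fitChcl3@converged)
    stop("both logistic fits must have converged")
  eclipse <- thresholdCrossingTime(fitChcl3, fraction)
  latency <- thresholdCrossingTime(fitNoChcl3, fraction)
  if (eclipse > latency)
    warning("eclipse exceeds latency (noisy fits?)")
  new("GrowthParameters", eclipse = eclipse, latency = latency,
      cycleDuration = fitNoChcl3@xc, burstSize = NA_real_)
}

#' Burst size from initial and final titers
#'
#' The number of infective centres is the excess of the initial -CHCl3
#' titer over the initial +CHCl3 titer (infected cells count as single
#' plaques only without chloroform). Burst size is the mean final titer
#' divided by the infective-centre count.
#'
#' @param titerT0NoChcl3,titerT0Chcl3 initial titers (pfu/mL) without /
#'   with chloroform
#' @param titerFinalNoChcl3,titerFinalChcl3 final (post-lysis) titers
#' @return progeny phage per infected cell (dimensionless)
#' @examples
#' burstSize(2.0e5, 1.0e5, 5.2e6, 5.4e6)  # 53
#' @export
burstSize <- function(titerT0NoChcl3, titerT0Chcl3,
                      titerFinalNoChcl3, titerFinalChcl3) {
  infected <- titerT0NoChcl3 - titerT0Chcl3
  if (!(infected > 0))
    stop("no infective centres detectable: initial -CHCl3 titer must ",
         "exceed the initial +CHCl3 titer")
  mean(c(titerFinalNoChcl3, titerFinalChcl3)) / infected
}

#' Fit exponential adsorption kinetics
#'
#' Free-phage decay p(t) = p0 exp(-lam t), fitted by linear regression of
#' log titer on time. The adsorption rate constant is
#' \code{k_a = lam / cellDensity} (mL/min) and the adsorption time --
#' minutes until only 10\% of particles remain non-adsorbed -- is
#' \code{log(10) / lam}.
#'
#' @param series a \linkS4class{TiterSeries} of free-phage titers
#' @param cellDensity host cell density in CFU/mL (> 0)
#' @return an \linkS4class{AdsorptionFit}
#' @export
fitAdsorption <- function(series, cellDensity) {
  stopifnot(is(series, "TiterSeries"), cellDensity > 0)
  x <- series@time; y <- log(series@titer)
  if (length(unique(x)) < 3)
    stop("fitAdsorption requires >= 3 distinct timepoints")
  fit <- lm(y ~ x)
  lam <- -unname(coef(fit)[2])
  if (!(lam > 1e-9))
    stop("no adsorption detected: titers are not decreasing")
  new("AdsorptionFit", p0 = exp(unname(coef(fit)[1])), lam = lam,
      ka = lam / cellDensity, adsorptionTime = log(10) / lam,
      cellDensity = cellDensity)
}

#' Per-replicate growth-parameter estimation with a summary
#'
#' Fits both chloroform arms of every replicate separately
#' (baseline = "auto" so each arm's pre-release floor is absorbed),
#' derives eclipse/latency/cycle per replicate, computes the burst size
#' from raw titers at the first and last timepoints, and summarises as
#' mean +/- SD across replicates.
#'
#' @param series a \linkS4class{TiterSeries} containing both arms
#' @param fraction asymptote fraction for eclipse/latency (default 0.05)
#' @param baseline passed to \code{\link{fitLogistic}} (default "auto")
#' @return a list with `perReplicate` (data.frame), `summary`
#'   (mean/sd per parameter) and `parameters`
#'   (\linkS4class{GrowthParameters} built from the means)
#' @export
summarizeGrowth <- function(series, fraction = 0.05, baseline = "auto") {
  reps <- sort(unique(series@replicate))
  rows <- lapply(reps, function(r) {
    fitNo <- fitLogistic(series, chloroform = FALSE, replicates = r,
                         baseline = baseline)
    fitCh <- fitLogistic(series, chloroform = TRUE, replicates = r,
                         baseline = baseline)
    gp <- growthParameters(fitNo, fitCh, fraction)
    sel <- series@replicate == r
    t0 <- min(series@time[sel]); tF <- max(series@time[sel])
    pick <- function(tt, ch) mean(series@titer[sel & series@time == tt &
                                               series@chloroform == ch])
    bs <- tryCatch(burstSize(pick(t0, FALSE), pick(t0, TRUE),
                             pick(tF, FALSE), pick(tF, TRUE)),
                   error = function(e) NA_real_)
    data.frame(replicate = r, eclipse = gp@eclipse, latency = gp@latency,
               cycleDuration = gp@cycleDuration, burstSize = bs,
               a = fitNo@a, k = fitNo@k, xc = fitNo@xc)
  })
  per <- do.call(rbind, rows)
  num <- per[, c("eclipse", "latency", "cycleDuration", "burstSize")]
  summ <- data.frame(parameter = names(num),
                     mean = vapply(num, mean, 0, na.rm = TRUE),
                     sd = vapply(num, sd, 0, na.rm = TRUE),
                     row.names = NULL)
  gp <- new("GrowthParameters",
            eclipse = mean(per$eclipse), latency = mean(per$latency),
            cycleDuration = mean(per$cycleDuration),
            burstSize = mean(per$burstSize, na.rm = TRUE))
  list(perReplicate = per, summary = summ, parameters = gp)
}
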