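## Small statistical primitives shared by the DE and metabolomics
## modules: Benjamini-Hochberg adjustment, the Welch two-sample test and
## the one-sided (enrichment) Fisher exact test.

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated front end to the step-up FDR procedure. NA entries pass
#' through and do not enter the denominator.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed)
#' @return adjusted p-values, monotone and capped at 1
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
benjaminiHochberg <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. When both groups have zero variance
#' the test is undefined and (NA, NA, NA) is returned.
#'
#' @param x,y numeric vectors, each with >= 2 values
#' @return named numeric c(t, df, p)
#' @examples
#' welchTest(c(10, 12, 14), c(20, 26))  # t ~ -3.4217, df ~ 1.304
#' @export
welchTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 values")
  if (var(x) == 0 && var(y) == 0)
    return(c(t = NA_real_, df = NA_real_, p = NA_real_))
  tt <- t.test(x, y, var.equal = FALSE)
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value)
}

#' One-sided Fisher exact test (enrichment tail)
#'
#' Hypergeometric upper-tail probability of observing at least the given
#' overlap in a 2x2 table \code{[[a, b], [c, d]]} with a = overlap,
#' rows = selected/not, columns = in-set/not.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts
#' @return the one-sided (greater) p-value
#' @examples
#' fisherGreater(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 17/70
#' @export
fisherGreater <- function(tab) {
  tab <- as.vector(t(as.matrix(tab)))
  if (length(tab) != 4) stop("tab must be a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
  ## P(X >= a), X ~ Hypergeometric(white = a+c, black = b+d, drawn = a+b)
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}
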