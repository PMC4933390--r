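# Independent oracles used to check the package implementations.
# These deliberately use the most naive formulation available.

# Step-up FDR adjustment, written directly from the procedure.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# One-sided Fisher p by full enumeration over all tables with the
# observed margins.
enumFisherGreater <- function(tab) {
  tab <- as.vector(t(as.matrix(tab)))
  a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  aa <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(aa, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), 0)
  sum(probs[aa >= a])
}

# Sliding-window exact k-mer scan over both strands.
naiveKmerScan <- function(query, target, k) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  kmers <- unique(substring(query, seq_len(nchar(query) - k + 1),
                            seq_len(nchar(query) - k + 1) + k - 1))
  kmers <- kmers[!grepl("N", kmers)]
  wins <- substring(target, seq_len(nchar(target) - k + 1),
                    seq_len(nchar(target) - k + 1) + k - 1)
  hits <- list()
  for (km in kmers) {
    fw <- which(wins == km)
    rv <- which(wins == rc(km))
    if (length(fw)) hits[[length(hits) + 1]] <-
      data.frame(kmer = km, start = fw, strand = "+")
    if (length(rv)) hits[[length(hits) + 1]] <-
      data.frame(kmer = km, start = rv, strand = "-")
  }
  if (!length(hits))
    return(data.frame(kmer = character(0), start = integer(0),
                      strand = character(0)))
  out <- unique(do.call(rbind, hits))
  out[order(out$start, out$strand, out$kmer), , drop = FALSE]
}

# Prefix-scan enrichment: per pathway, the minimum one-sided Fisher p
# over every prefix of the ranked list, straight from the definition.
bruteForcePrefixMinP <- function(ranked, pathwayIons, universeSize) {
  K <- length(pathwayIons)
  ps <- vapply(seq_along(ranked), function(s) {
    a <- sum(ranked[1:s] %in% pathwayIons)
    enumFisherGreater(c(a, s - a, K - a, universeSize - s - (K - a)))
  }, 0)
  c(minP = min(ps), prefixSize = which.min(ps))
}

# Welch statistic and Satterthwaite df from the textbook formulas.
welchOracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  c(t = t, df = df)
}

# Random-letter DNA string
randomDna <- function(n, gc = 0.5)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
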