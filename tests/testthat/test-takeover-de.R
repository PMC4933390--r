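# Dual-genome takeover, per-genome normalization and the NB Wald
# differential-expression pipeline.

makeDce <- function(counts, genome, class = "CDS",
                    timepoint = rep(c(0, 13), each = ncol(counts) / 2)) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  DualCountExperiment(counts, genome = genome, class = class,
                      timepoint = timepoint)
}

test_that("takeover fractions are exact, sum to one and ignore rRNA", {
  cts <- rbind(p1 = c(870L, 0L), h1 = c(100L, 500L), h2 = c(30L, 500L),
               r1 = c(999L, 999L))
  dce <- DualCountExperiment(cts, genome = c("phage", "host", "host", "host"),
                             class = c("CDS", "CDS", "CDS", "rRNA"),
                             timepoint = c(13, 0))
  tk <- computeTakeover(dce)
  expect_equal(tk$phageFraction, c(0.87, 0))
  expect_equal(tk$hostFraction, c(0.13, 1))
  expect_equal(tk$phageFraction + tk$hostFraction, c(1, 1), tolerance = 1e-12)
  ## changing rRNA counts leaves fractions unchanged
  cts2 <- cts; cts2["r1", ] <- c(5L, 7L)
  dce2 <- DualCountExperiment(cts2, genome = c("phage", "host", "host", "host"),
                              class = c("CDS", "CDS", "CDS", "rRNA"),
                              timepoint = c(13, 0))
  expect_equal(computeTakeover(dce2)[, -1], tk[, -1])
  ## all-rRNA sample errors
  cts3 <- cts; cts3[c("p1", "h1", "h2"), 2] <- 0L
  dce3 <- DualCountExperiment(cts3, genome = c("phage", "host", "host", "host"),
                              class = c("CDS", "CDS", "CDS", "rRNA"),
                              timepoint = c(13, 0))
  expect_error(computeTakeover(dce3), "zero non-rRNA")
})

test_that("median-of-ratios size factors: identity, equivariance, hand case", {
  m <- matrix(rep(c(10L, 100L, 4L), 2), ncol = 2)
  expect_equal(sizeFactorsGenome(m), c(1, 1), ignore_attr = TRUE)
  ## doubling one sample doubles its factor relative to the others
  set.seed(2)
  m2 <- matrix(rnbinom(300, mu = 60, size = 8) + 1L, ncol = 3)
  sf <- sizeFactorsGenome(m2)
  m2d <- m2; m2d[, 2] <- m2d[, 2] * 2L
  sfd <- sizeFactorsGenome(m2d)
  expect_equal(sfd[2] / sfd[1], 2 * sf[2] / sf[1],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sfd[3] / sfd[1], sf[3] / sf[1],
               tolerance = 1e-12, ignore_attr = TRUE)
  ## hand-computed: geometric means (sqrt(200), sqrt(20000), sqrt(32));
  ## every ratio in sample 1 is 1/sqrt(2), in sample 2 sqrt(2)
  m3 <- matrix(c(10L, 20L, 100L, 200L, 4L, 8L), nrow = 3, byrow = TRUE)
  expect_equal(sizeFactorsGenome(m3), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## invariant under feature permutation
  set.seed(1)
  m4 <- matrix(rnbinom(300, mu = 50, size = 5) + 1L, ncol = 3)
  expect_equal(sizeFactorsGenome(m4), sizeFactorsGenome(m4[sample(100), ]))
  ## all features hit a zero -> error unless pseudo-reference requested
  m5 <- matrix(c(0L, 5L, 9L, 0L), 2)
  expect_error(sizeFactorsGenome(m5), "pseudoReference")
  expect_length(sizeFactorsGenome(m5, pseudoReference = TRUE), 2)
})

test_that("per-genome independence: one genome never affects the other", {
  set.seed(7)
  host <- matrix(rnbinom(600, mu = 80, size = 10), ncol = 6)
  rownames(host) <- paste0("h", 1:100)
  phageA <- matrix(rnbinom(120, mu = 40, size = 10), ncol = 6)
  rownames(phageA) <- paste0("pA", 1:20)
  phageB <- matrix(rnbinom(600, mu = 400, size = 2), ncol = 6)
  rownames(phageB) <- paste0("pB", 1:100)
  tp <- rep(c(0, 13), each = 3)
  dce1 <- DualCountExperiment(rbind(host, phageA),
                              genome = rep(c("host", "phage"), c(100, 20)),
                              timepoint = tp)
  dce2 <- DualCountExperiment(rbind(host, phageA, phageB),
                              genome = rep(c("host", "phage"), c(100, 120)),
                              timepoint = tp)
  expect_identical(sizeFactorsGenome(dce1, "host"),
                   sizeFactorsGenome(dce2, "host"))
  de1 <- nbWaldTest(dce1, "host", contrast = c(0, 13))
  de2 <- nbWaldTest(dce2, "host", contrast = c(0, 13))
  expect_identical(de1, de2)
  ## and symmetrically: extra host features leave phage results alone
  hostX <- matrix(rnbinom(180, mu = 300, size = 3), ncol = 6)
  rownames(hostX) <- paste0("hx", 1:30)
  dce3 <- DualCountExperiment(rbind(host, hostX, phageA),
                              genome = rep(c("host", "phage"), c(130, 20)),
                              timepoint = tp)
  expect_identical(sizeFactorsGenome(dce1, "phage"),
                   sizeFactorsGenome(dce3, "phage"))
  expect_identical(nbWaldTest(dce1, "phage", contrast = c(0, 13)),
                   nbWaldTest(dce3, "phage", contrast = c(0, 13)))
})

test_that("moment dispersion estimates behave as designed", {
  sf <- rep(1, 6)
  cond <- rep(c("a", "b"), each = 3)
  set.seed(21)
  pois <- sapply(1:6, function(j) rpois(2000, 60))
  dp <- estimateFeatureDispersions(pois, sf, cond)
  expect_lte(median(dp$alpha[dp$mu >= 50]), 0.05)
  nb <- sapply(1:6, function(j) rnbinom(2000, mu = 100, size = 5))
  dn <- estimateFeatureDispersions(nb, sf, cond)
  expect_gte(median(dn$alpha), 0.1)
  expect_lte(median(dn$alpha), 0.35)
  cst <- matrix(7L, nrow = 3, ncol = 6)
  expect_equal(estimateFeatureDispersions(cst, sf, cond)$alphaRaw,
               rep(0, 3))
  expect_error(estimateFeatureDispersions(pois[, 1:2], sf[1:2],
                                          c("a", "b")),
               ">= 2 replicates")
})

test_that("Wald contrast is antisymmetric and all-zero features excluded", {
  set.seed(31)
  cts <- sapply(1:6, function(j) rnbinom(60, mu = 100, size = 10))
  cts[1, ] <- 0L
  dce <- makeDce(cts, genome = "host")
  de <- nbWaldTest(dce, "host", contrast = c(0, 13))
  deRev <- nbWaldTest(dce, "host", contrast = c(13, 0))
  expect_true(all(is.na(de[1, c("log2FoldChange", "pvalue", "padj")])))
  ## BH denominator excludes the flagged feature
  ok <- !is.na(de$pvalue)
  expect_equal(de$padj[ok], bruteForceBH(de$pvalue[ok]), tolerance = 1e-12)
  expect_equal(de$log2FoldChange[ok], -deRev$log2FoldChange[ok],
               tolerance = 1e-6)
  expect_equal(de$pvalue[ok], deRev$pvalue[ok], tolerance = 1e-6)
  ## single-replicate condition refused
  dce1 <- makeDce(cts[, c(1, 4, 5)], genome = "host",
                  timepoint = c(0, 13, 13))
  expect_error(nbWaldTest(dce1, "host", contrast = c(0, 13)),
               ">= 2 replicates")
})

test_that("BH adjustment matches the brute-force step-up procedure", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjaminiHochberg(0.3), 0.3)
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  set.seed(41)
  for (i in 1:10) {
    p <- runif(sample(1:1000, 1))
    adj <- benjaminiHochberg(p)
    expect_equal(adj, bruteForceBH(p), tolerance = 1e-12)
    ## monotone in the input order statistics
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("depletion factor and absolute-shift conversion arithmetic", {
  tk <- data.frame(timepoint = c(0, 0, 13, 13),
                   hostFraction = c(0.94, 0.94, 0.13, 0.13))
  expect_equal(hostDepletionFactor(tk, 0, 13), 0.94 / 0.13)
  expect_equal(hostDepletionFactor(tk, 0, 13), 7.23, tolerance = 1e-2)
  tk2 <- data.frame(timepoint = c(0, 13), hostFraction = c(1, 1))
  expect_equal(hostDepletionFactor(tk2, 0, 13), 1)
  de <- data.frame(log2FoldChange = log2(c(80, 7.2, 1)))
  out <- relativeHostShift(de, 7.2)
  expect_equal(out$absoluteFoldChange, c(80 / 7.2, 1, 1 / 7.2))
  expect_equal(out$absoluteFoldChange[1], 11.1, tolerance = 1e-2)
})

test_that("temporal classification applies the early/middle/late rules", {
  de <- data.frame(
    meanRef = c(100, 5, 8, 10),         # early-timepoint normalized mean
    meanTest = c(10, 5, 8, 10),         # late-timepoint normalized mean
    log2FoldChange = c(-log2(10), 0, 0, 0),
    padj = c(1e-4, 0.9, 0.9, 0.9),
    row.names = paste0("g", 1:4))
  mid <- c(g1 = 50, g2 = 40, g3 = 8, g4 = NA)
  cls <- classifyTemporal(de, mid)
  expect_equal(as.character(cls),
               c("early", "middle", "not_significant", "not_significant"))
  lateDe <- de; lateDe$log2FoldChange <- abs(de$log2FoldChange)
  lateDe$meanRef <- de$meanTest; lateDe$meanTest <- de$meanRef
  expect_equal(as.character(classifyTemporal(lateDe, mid))[1], "late")
  expect_warning(classifyTemporal(de, NULL), "middle class disabled")
})

test_that("programmed takeover trajectories are recovered from counts", {
  sim <- simulateDualCounts(seed = 3)
  tk <- computeTakeover(sim$dce)
  truth <- sim$truth$planted$hostFraction
  for (tp in names(truth)) {
    got <- mean(tk$hostFraction[tk$timepoint == as.numeric(tp)])
    expect_lt(abs(got - truth[[tp]]), 0.01)
  }
  expect_equal(tk$phageFraction + tk$hostFraction,
               rep(1, nrow(tk)), tolerance = 1e-12)
})

test_that("planted host operon and prophage folds are recovered", {
  sim <- simulateDualCounts(seed = 3)
  de <- nbWaldTest(sim$dce, "host", contrast = c(0, 13))
  op <- sim$truth$planted$operon$id
  expect_true(all(de[op, "padj"] < 0.05))
  ## ~80x relative enrichment, among the top features by fold-change
  expect_equal(median(2^de[op, "log2FoldChange"]), 80, tolerance = 0.25)
  rk <- match(op, rownames(de)[order(-de$log2FoldChange)])
  expect_true(all(rk <= 10))
  pp <- sim$truth$planted$prophage$id
  expect_equal(median(2^de[pp, "log2FoldChange"]), 6.8, tolerance = 0.3)
})
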