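# Coverage-based RNA-feature calling against planted truth.

# one 3000-bp genome with a single +strand gene at 1001..2000
tinyAnn <- function() {
  GenomicRanges::GRanges("genome", IRanges::IRanges(1001, 2000),
                         strand = "+", type = "CDS", ID = "geneA")
}
tinyCov <- function(plus = numeric(3000), minus = numeric(3000))
  StrandedCoverage(plus, minus, genome = "genome", sample = "t")

test_that("sRNA caller: empty coverage, planted block, bound rules", {
  ann <- tinyAnn()
  expect_length(callIntergenicSrna(tinyCov(), ann), 0)
  ## planted 120-bp intergenic block at depth 100
  plus <- numeric(3000); plus[301:420] <- 100
  calls <- callIntergenicSrna(tinyCov(plus = plus), ann)
  expect_length(calls, 1)
  expect_equal(calls$class, "sRNA")
  expect_lt(abs(GenomicRanges::start(calls) - 301), 5)
  expect_lt(abs(GenomicRanges::end(calls) - 420), 5)
  expect_equal(calls$meanDepth, 100)
  ## 800-bp block exceeds maxLen
  plus2 <- numeric(3000); plus2[2101:2900] <- 100
  expect_length(callIntergenicSrna(tinyCov(plus = plus2), ann), 0)
  ## block overlapping a same-strand CDS is not an sRNA
  plus3 <- numeric(3000); plus3[950:1100] <- 100
  expect_length(callIntergenicSrna(tinyCov(plus = plus3), ann), 0)
  ## gaps <= mergeGap are bridged
  plus4 <- numeric(3000); plus4[301:400] <- 100; plus4[406:480] <- 100
  expect_length(callIntergenicSrna(tinyCov(plus = plus4), ann), 1)
  ## annotation/coverage mismatch is rejected
  badAnn <- GenomicRanges::GRanges("genome", IRanges::IRanges(1, 9000),
                                   strand = "+", type = "CDS")
  expect_error(callIntergenicSrna(tinyCov(), badAnn), "genome mismatch")
})

test_that("antisense caller: ratio rule and small/long boundary", {
  ann <- tinyAnn()
  sense <- numeric(3000); sense[1001:2000] <- 30
  expect_length(callAntisense(tinyCov(plus = sense), ann), 0)
  ## planted 176-bp antisense block inside the gene
  minus <- numeric(3000); minus[1201:1376] <- 100
  calls <- callAntisense(tinyCov(plus = sense, minus = minus), ann)
  expect_length(calls, 1)
  expect_equal(calls$class, "asRNA_small")
  expect_equal(as.character(GenomicRanges::strand(calls)), "-")
  expect_equal(calls$context, "geneA")
  ## 400-bp block crosses the small/long boundary
  minus2 <- numeric(3000); minus2[1201:1600] <- 100
  calls2 <- callAntisense(tinyCov(plus = sense, minus = minus2), ann)
  expect_equal(calls2$class, "asRNA_long")
  ## strong sense expression suppresses a weak antisense signal
  sense2 <- sense; sense2[1001:2000] <- 500
  minus3 <- numeric(3000); minus3[1201:1376] <- 30
  expect_length(callAntisense(tinyCov(plus = sense2, minus = minus3), ann),
                0)
  ## antisense block outside any gene is ignored
  minus4 <- numeric(3000); minus4[2301:2500] <- 100
  expect_length(callAntisense(tinyCov(plus = sense, minus = minus4), ann),
                0)
})

test_that("riboswitch caller needs an upstream leader with a depth drop", {
  ann <- tinyAnn()
  ## uniform read-through into the gene: no drop, no call
  plus <- numeric(3000); plus[801:2000] <- 100
  expect_length(callRiboswitchCandidates(tinyCov(plus = plus), ann), 0)
  ## leader at depth 150 dropping to 10 inside the CDS
  plus2 <- numeric(3000); plus2[801:1000] <- 150; plus2[1001:2000] <- 10
  calls <- callRiboswitchCandidates(tinyCov(plus = plus2), ann)
  expect_length(calls, 1)
  expect_equal(calls$class, "riboswitch_candidate")
  expect_equal(calls$context, "geneA")
  ## block only 20 bp upstream of the gene start fails the gap rule
  plus3 <- numeric(3000); plus3[981:1000] <- 150; plus3[1001:2000] <- 10
  expect_length(callRiboswitchCandidates(tinyCov(plus = plus3), ann), 0)
  ## leader detached from the gene start is not its 5' leader
  plus4 <- numeric(3000); plus4[501:700] <- 150; plus4[1001:2000] <- 10
  expect_length(callRiboswitchCandidates(tinyCov(plus = plus4), ann), 0)
  ## minus-strand gene: leader downstream in coordinates
  annM <- GenomicRanges::GRanges("genome", IRanges::IRanges(1001, 2000),
                                 strand = "-", type = "CDS", ID = "geneB")
  minus <- numeric(3000); minus[2001:2200] <- 150; minus[1001:2000] <- 10
  callsM <- callRiboswitchCandidates(tinyCov(minus = minus), annM)
  expect_length(callsM, 1)
  expect_equal(callsM$context, "geneB")
})

test_that("callers recover >= 20 planted features per class at 0.9", {
  sim <- simulateCoverage(seed = 5)
  calls <- c(callIntergenicSrna(sim$cov, sim$ann),
             callAntisense(sim$cov, sim$ann),
             callRiboswitchCandidates(sim$cov, sim$ann))
  ev <- evaluateCalls(calls, sim$truth$planted$features)
  expect_true(all(ev$nTruth >= 20))
  expect_true(all(ev$precision >= 0.9))
  expect_true(all(ev$recall >= 0.9))
  ## class invariants hold on every call
  w <- GenomicRanges::width(calls)
  expect_true(all(w[calls$class == "asRNA_small"] < 300))
  expect_true(all(w[calls$class == "asRNA_long"] >= 300))
  srna <- calls[calls$class == "sRNA"]
  genes <- sim$ann[sim$ann$type == "CDS"]
  expect_equal(sum(GenomicRanges::countOverlaps(srna, genes)), 0)
  asr <- calls[grepl("asRNA", calls$class)]
  expect_true(all(GenomicRanges::countOverlaps(
    asr, genes, ignore.strand = TRUE) > 0))
})

test_that("sRNA calls on one strand ignore opposite-strand coverage", {
  ann <- tinyAnn()
  plus <- numeric(3000); plus[301:420] <- 100
  base <- callIntergenicSrna(tinyCov(plus = plus), ann)
  ## pile coverage on the opposite strand outside annotated genes
  minus <- numeric(3000); minus[2201:2600] <- 80; minus[101:260] <- 90
  with <- callIntergenicSrna(tinyCov(plus = plus, minus = minus), ann)
  plusCalls <- with[GenomicRanges::strand(with) == "+"]
  expect_equal(GenomicRanges::ranges(plusCalls),
               GenomicRanges::ranges(base))
  ## and the antisense caller stays silent outside genes
  expect_length(callAntisense(tinyCov(plus = plus, minus = minus), ann), 0)
})

test_that("differential expression of calls recovers planted folds", {
  ## two planted features; coverage tracks for 3+3 replicates
  ann <- tinyAnn()
  calls <- GenomicRanges::GRanges(
    "genome", IRanges::IRanges(c(301, 1201), c(420, 1376)),
    strand = c("+", "-"), class = c("sRNA", "asRNA_small"))
  mkCov <- function(dSrna, dAs) {
    plus <- numeric(3000); minus <- numeric(3000)
    plus[301:420] <- rpois(120, dSrna)
    minus[1201:1376] <- rpois(176, dAs)
    plus[1001:2000] <- rpois(1000, 30)
    tinyCov(plus = plus, minus = minus)
  }
  set.seed(77)
  ## identical timepoints -> log2FC ~ 0
  covs0 <- c(replicate(3, mkCov(100, 100)), replicate(3, mkCov(100, 100)))
  de0 <- differentialFeatureExpression(calls, covs0,
                                       timepoint = rep(c(3.5, 13), each = 3),
                                       contrast = c(3.5, 13))
  expect_true(all(abs(de0$log2FoldChange) < 0.5))
  ## sRNA 91x late-enriched, asRNA 8x early-enriched
  covs <- c(replicate(3, mkCov(2, 160)), replicate(3, mkCov(182, 20)))
  de <- differentialFeatureExpression(calls, covs,
                                      timepoint = rep(c(3.5, 13), each = 3),
                                      contrast = c(3.5, 13))
  srnaFc <- 2^de$log2FoldChange[1]
  asFc <- 2^(-de$log2FoldChange[2])
  expect_gt(srnaFc, 20)        # strongly late, right sign
  expect_lt(de$padj[1], 0.05)
  expect_gte(asFc, 4)          # early enrichment within [4, 16]
  expect_lte(asFc, 16)
})
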