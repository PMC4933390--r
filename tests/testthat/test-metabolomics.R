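# Time-course metabolomics: Welch tests, altered fractions and
# rank-subset Fisher pathway enrichment.

# small experiment built by hand: nIons x (timepoints x bio x tech)
makeIe <- function(X, time, bio, tech, ionToMet = NULL, metToPath = NULL) {
  rownames(X) <- paste0("ion_", seq_len(nrow(X)))
  colnames(X) <- paste0("s", seq_len(ncol(X)))
  IonExperiment(X, time_min = time, bio_rep = bio, tech_rep = tech,
                ionToMet = ionToMet, metToPath = metToPath)
}

test_that("technical replicates collapse to bio-replicate means", {
  X <- matrix(c(10, 20, 30, 30, 5, 15), nrow = 1)
  ie <- makeIe(X, time = c(0, 0, 0, 0, 5, 5), bio = c(1, 1, 2, 2, 1, 1),
               tech = c(1, 2, 1, 2, 1, 2))
  expect_error(collapseTechnical(ie), "missing.*cells")  # t5 lacks bio 2
  ie2 <- makeIe(matrix(c(10, 20, 30, 30, 5, 15, 7, 9), nrow = 1),
                time = c(0, 0, 0, 0, 5, 5, 5, 5),
                bio = c(1, 1, 2, 2, 1, 1, 2, 2),
                tech = c(1, 2, 1, 2, 1, 2, 1, 2))
  got <- collapseTechnical(ie2)
  expect_equal(unname(SummarizedExperiment::assay(got, "intensity")[1, ]),
               c(15, 30, 10, 8))
  ## permuting technical labels changes nothing
  ie3 <- makeIe(matrix(c(20, 10, 30, 30, 15, 5, 9, 7), nrow = 1),
                time = c(0, 0, 0, 0, 5, 5, 5, 5),
                bio = c(1, 1, 2, 2, 1, 1, 2, 2),
                tech = c(2, 1, 2, 1, 2, 1, 2, 1))
  expect_equal(SummarizedExperiment::assay(collapseTechnical(ie3)),
               SummarizedExperiment::assay(got))
  ## identical repeats are passed through
  ie4 <- makeIe(matrix(c(10, 10, 4, 4), nrow = 1), time = c(0, 0, 5, 5),
                bio = c(1, 2, 1, 2), tech = 1)
  expect_equal(unname(SummarizedExperiment::assay(
    collapseTechnical(ie4), "intensity")[1, ]), c(10, 10, 4, 4))
})

test_that("Welch test matches the textbook formulas", {
  w <- welchTest(c(10, 12, 14), c(20, 26))
  expect_equal(unname(w["t"]), -3.4217, tolerance = 1e-3)
  expect_equal(unname(w["df"]), 1.304, tolerance = 1e-3)
  ## p agrees with the t CDF at the Satterthwaite df
  expect_equal(unname(w["p"]), 2 * pt(-abs(w[["t"]]), w[["df"]]),
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:8, 1), 1, sd = runif(1, 0.5, 3))
    w <- welchTest(x, y)
    o <- welchOracle(x, y)
    expect_equal(unname(w["t"]), unname(o["t"]), tolerance = 1e-10)
    expect_equal(unname(w["df"]), unname(o["df"]), tolerance = 1e-10)
    wr <- welchTest(y, x)
    expect_equal(unname(wr["t"]), -unname(w["t"]))
    expect_equal(unname(wr["p"]), unname(w["p"]))
  }
  expect_equal(unname(welchTest(c(1, 2, 3), c(1, 2, 3))["t"]), 0)
  expect_equal(unname(welchTest(c(1, 2, 3), c(1, 2, 3))["p"]), 1)
  expect_true(all(is.na(welchTest(c(2, 2), c(3, 3)))))
  expect_error(welchTest(1, c(2, 3)), ">= 2 values")
})

test_that("differential ions: fold-changes, rescaling invariance, null", {
  ## exact doubling -> log2FC = 1 everywhere
  set.seed(31)
  base <- rlnorm(50, log(1e4), 1)
  X <- cbind(sapply(1:4, function(b) base), sapply(1:4, function(b) 2 * base))
  ie <- makeIe(X, time = rep(c(0, 5), each = 4), bio = rep(1:4, 2), tech = 1)
  d <- differentialIons(ie, 5)
  expect_equal(d$log2FC, rep(1, 50))
  ## common rescaling leaves log2FC and p unchanged
  noisy <- X * rlnorm(length(X), 0, 0.2)
  ieA <- makeIe(noisy, time = rep(c(0, 5), each = 4), bio = rep(1:4, 2),
                tech = 1)
  ieB <- makeIe(noisy * 1e3, time = rep(c(0, 5), each = 4),
                bio = rep(1:4, 2), tech = 1)
  dA <- differentialIons(ieA, 5); dB <- differentialIons(ieB, 5)
  expect_equal(dA$log2FC, dB$log2FC, tolerance = 1e-12)
  expect_equal(dA$pvalue, dB$pvalue, tolerance = 1e-12)
  ## null simulation at the study's scale: false-positive rate near alpha
  sim <- simulateIonMatrix(nUp = rep(0, 5), nDown = rep(0, 5), seed = 47)
  d0 <- differentialIons(sim$ie, 5)
  fp <- mean(d0$pvalue <= 0.05, na.rm = TRUE)
  expect_gte(fp, 0.02); expect_lte(fp, 0.09)
  ## planted 2x shift in 40 ions, n = 4: most are detected
  sim2 <- simulateIonMatrix(nUp = c(40, rep(0, 4)), nDown = rep(0, 5),
                            seed = 48)
  d2 <- differentialIons(sim2$ie, 5)
  hit <- d2$ion_id %in% sim2$truth$planted$upSets[["5"]]
  expect_gte(sum(d2$pvalue[hit] <= 0.05 & d2$log2FC[hit] >= 0.5), 30)
})

test_that("altered fractions follow the threshold arithmetic", {
  d <- data.frame(ion_id = paste0("i", 1:377),
                  log2FC = rep(0, 377), pvalue = rep(0.5, 377))
  expect_equal(alteredFraction(d), c(increased = 0, decreased = 0))
  d$log2FC[1:52] <- 1; d$pvalue[1:52] <- 0.01
  d$log2FC[53:84] <- -1; d$pvalue[53:84] <- 0.01
  af <- alteredFraction(d)
  expect_equal(unname(af["increased"]), 100 * 52 / 377, tolerance = 1e-12)
  expect_equal(unname(af["decreased"]), 100 * 32 / 377, tolerance = 1e-12)
  expect_equal(round(unname(af), 1), c(13.8, 8.5))
  expect_lte(sum(af), 100)
  ## sub-threshold effects are not counted
  d$log2FC[100] <- 0.4; d$pvalue[100] <- 1e-9
  expect_equal(alteredFraction(d), af)
})

test_that("one-sided Fisher equals hypergeometric enumeration", {
  expect_equal(fisherGreater(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               17 / 70, tolerance = 1e-12)
  expect_equal(fisherGreater(c(0, 5, 3, 10)), 1, tolerance = 1e-12)
  set.seed(53)
  for (i in 1:50) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)  # margins <= 30
    expect_equal(fisherGreater(tab), enumFisherGreater(tab),
                 tolerance = 1e-12)
    expect_equal(fisherGreater(tab),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisherGreater(c(-1, 2, 3, 4)), "non-negative")
})

test_that("rank-subset enrichment: closed form, oracle and invariances", {
  ## 20-ion universe, one 5-ion pathway fully top-ranked
  ions <- sprintf("ion_%02d", 1:20)
  i2m <- data.frame(ion_id = ions, metabolite_id = paste0("m", 1:20))
  m2p <- data.frame(metabolite_id = paste0("m", 1:20),
                    pathway_id = rep(c("pwA", "pwB"), c(5, 15)))
  d <- data.frame(ion_id = ions, timepoint = 5,
                  log2FC = c(rep(2, 5), rep(0, 15)),
                  pvalue = c(seq(1e-6, 5e-6, length.out = 5), rep(0.9, 15)))
  d$padj <- benjaminiHochberg(d$pvalue)
  en <- rankSubsetEnrichment(d, i2m, m2p, "increased")
  expect_equal(nrow(en), 2)
  a <- en[en$pathway_id == "pwA", ]
  expect_lte(a$minP, 1 / choose(20, 5) + 1e-15)
  expect_equal(a$minP, 1 / 15504, tolerance = 1e-9)
  expect_equal(a$prefixSize, 5)
  ## no significant ions -> empty, not an error
  dNull <- d; dNull$padj <- 1
  expect_equal(nrow(rankSubsetEnrichment(dNull, i2m, m2p, "increased")), 0)
  ## brute-force prefix scan on random instances
  set.seed(59)
  for (i in 1:5) {
    n <- 40
    ionsR <- sprintf("r%02d", 1:n)
    i2mR <- data.frame(ion_id = ionsR, metabolite_id = ionsR)
    m2pR <- data.frame(metabolite_id = ionsR,
                       pathway_id = sample(c("p1", "p2", "p3"), n, TRUE))
    dR <- data.frame(ion_id = ionsR, timepoint = 5,
                     log2FC = runif(n, 0.6, 3), pvalue = runif(n, 0, 0.01))
    dR$padj <- benjaminiHochberg(dR$pvalue)
    enR <- rankSubsetEnrichment(dR, i2mR, m2pR, "increased",
                                padjThresh = 1)
    ranked <- dR$ion_id[order(dR$padj, -abs(dR$log2FC), dR$ion_id)]
    for (pw in enR$pathway_id) {
      pwIons <- ionsR[m2pR$pathway_id == pw]
      oracle <- bruteForcePrefixMinP(ranked, pwIons, n)
      expect_equal(enR$minP[enR$pathway_id == pw], unname(oracle["minP"]),
                   tolerance = 1e-9)
    }
  }
  ## duplicate (ion, metabolite) annotations change nothing
  en2 <- rankSubsetEnrichment(d, rbind(i2m, i2m[1:3, ]),
                              rbind(m2p, m2p[1:3, ]), "increased")
  expect_equal(en2, en)
  ## promoting a pathway ion to rank 1 never worsens its min-p
  d3 <- d
  d3$pvalue[6] <- 1e-9   # a pwB ion jumps to the top of the list
  d3$log2FC[6] <- 2
  d3$padj <- benjaminiHochberg(d3$pvalue)
  before <- rankSubsetEnrichment(d, i2m, m2p, "increased")
  after <- rankSubsetEnrichment(d3, i2m, m2p, "increased")
  expect_lte(after$minP[after$pathway_id == "pwB"],
             before$minP[before$pathway_id == "pwB"])
})

test_that("a coherently shifted pathway tops the enrichment ranking", {
  sim <- simulateIonMatrix(seed = 61)
  d5 <- differentialIons(sim$ie, 5)
  ann <- S4Vectors::metadata(sim$ie)
  en <- rankSubsetEnrichment(d5, ann$ionToMet, ann$metToPath, "increased")
  expect_equal(en$pathway_id[1], sim$truth$planted$upFocalPathway)
  expect_lt(en$padj[1], 0.05)
})
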