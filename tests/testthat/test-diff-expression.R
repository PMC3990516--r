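.pairStudy <- function(nGenes = 80, seed = 1) {
  set.seed(seed)
  m <- 2 ^ matrix(rnorm(nGenes * 6, 6, 1), nGenes,
                  dimnames = list(paste0("g", seq_len(nGenes)),
                                  paste0("s", 1:6)))
  CSSExperiment(m,
                colData = data.frame(strain = rep(c("T", "R"), each = 3),
                                     age = 5, replicate = rep(1:3, 2),
                                     row.names = colnames(m)),
                rowData = data.frame(chrom = "1",
                                     position = seq_len(nGenes),
                                     row.names = rownames(m)))
}

test_that("log2 fold changes are differences of log2 group means", {
  expr <- .pairStudy()
  fcSelf <- log2FoldChanges(expr, "T", "T")
  expect_true(all(fcSelf == 0))
  fc <- log2FoldChanges(expr, "T", "R")
  expect_equal(log2FoldChanges(expr, "R", "T"), -fc)  # antisymmetry
  doubled <- CSSExperiment(
    cbind(intensity(expr)[, 1:3] * 2, intensity(expr)[, 4:6]),
    SummarizedExperiment::colData(expr),
    SummarizedExperiment::rowData(expr))
  expect_equal(log2FoldChanges(doubled, "T", "R"), fc + 1)
})

test_that("moderated t is zero with identical groups", {
  set.seed(2)
  x <- matrix(rnorm(50 * 3), 50)
  res <- moderatedT(x, x)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
})

test_that("zero prior weight reduces to the ordinary two-sample t", {
  set.seed(3)
  x <- matrix(rnorm(200 * 3, 0, 1.5), 200)
  y <- matrix(rnorm(200 * 4), 200)
  res <- moderatedT(x, y, priorDf = 0)
  for (g in c(1, 57, 200)) {
    tt <- t.test(x[g, ], y[g, ], var.equal = TRUE)
    expect_equal(res$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[g], tt$p.value, tolerance = 1e-10)
    expect_equal(res$df[g], unname(tt$parameter))
  }
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(4)
  n <- 500
  x <- matrix(rnorm(n * 3, 0, sqrt(rchisq(n, 4) / 4)), n)
  y <- matrix(rnorm(n * 3, 0, sqrt(rchisq(n, 4) / 4)), n)
  res <- moderatedT(x, y)
  design <- cbind(1, rep(c(1, 0), each = 3))
  fit <- limma::eBayes(limma::lmFit(cbind(x, y), design))
  expect_equal(attr(res, "priorDf"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(res, "priorVar"), fit$s2.prior, tolerance = 1e-4)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("shrunken variances concentrate when genes share one variance", {
  set.seed(5)
  x <- matrix(rnorm(2000 * 3, 0, 2), 2000)
  y <- matrix(rnorm(2000 * 3, 5, 2), 2000)
  res <- moderatedT(x, y)
  # posterior variances are far less spread than raw pooled variances
  expect_lt(sd(res$s2Post), 0.25 * sd(res$s2))
  expect_equal(median(res$s2Post), 4, tolerance = 0.5)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1)) ^ sample(1:3, 1)
    adj <- bhAdjust(p)
    expect_equal(adj, bhStepUpOracle(p))
    expect_true(all(adj >= p))                      # dominance
    expect_true(all(diff(adj[order(p)]) >= 0))  # order preservation
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DE calls require both FDR and fold-change thresholds", {
  fc <- log2(c(1.6, 1.6, 1.49, 1 / 1.6))
  adjP <- c(0.01, 0.10, 0.001, 0.01)
  calls <- callDE(fc, adjP)
  expect_identical(calls$significant, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(calls$direction, c("up", "none", "none", "down"))
  expect_error(callDE(fc, adjP[1:2]), "length mismatch")
})

test_that("frequency table reproduces published per-chromosome arithmetic", {
  counts <- read.delim(system.file("extdata", "chrX_css_de_counts.tsv",
                                   package = "cssmisreg"))
  w5 <- frequencyTableFromCounts(counts[counts$strain == "wholeX" &
                                          counts$age == 5, ])
  x5 <- w5[w5$chrom == "X", ]
  expect_equal(x5$upPct, 3.43)
  expect_equal(x5$downPct, 9.84)
  d5 <- frequencyTableFromCounts(counts[counts$strain == "distalX" &
                                          counts$age == 5, ])
  expect_equal(d5$upPct[d5$chrom == "disX"], 2.51)
  expect_equal(d5$downPct[d5$chrom == "disX"], 9.62)
})

test_that("frequency table counts and percentages are internally consistent", {
  st <- tinyStudy(pIncomp = 0.3, seed = 9)
  calls <- deTest(st$expr, "cssX", "host")
  tab <- chromFrequencyTable(calls)
  expect_equal(sum(tab$expressed), nrow(calls))
  expect_true(all(tab$up + tab$down <= tab$expressed))
  expect_equal(tab$upPct, round(100 * tab$up / tab$expressed, 2))
  # X split partitions the X row
  tabSplit <- chromFrequencyTable(calls, xSplitBp = 8e7)
  expect_setequal(setdiff(tabSplit$chrom, tab$chrom), c("proX", "disX"))
  xRow <- tab[tab$chrom == "X", ]
  expect_equal(sum(tabSplit$expressed[tabSplit$chrom %in%
                                        c("proX", "disX")]), xRow$expressed)
  # no significant calls -> all-zero percentages
  none <- calls; none$significant <- FALSE; none$direction <- "none"
  expect_true(all(chromFrequencyTable(none)$upPct == 0))
  bad <- calls; bad$chrom[1] <- NA
  expect_error(chromFrequencyTable(bad), "unknown chromosome")
})

test_that("autosome aggregation supports pooled and mean-of-percentage", {
  tab <- data.frame(chrom = c("1", "2", "X"),
                    expressed = c(100, 400, 50),
                    up = c(2, 4, 5), upPct = c(2, 1, 10),
                    down = c(1, 8, 10), downPct = c(1, 2, 20))
  pooled <- autosomeAggregate(tab, "pooled")
  expect_equal(pooled$upPct, round(100 * 6 / 500, 2))
  meanPct <- autosomeAggregate(tab, "meanPct")
  expect_equal(meanPct$upPct, 1.5)  # unweighted mean of 2 and 1
  expect_equal(meanPct$downPct, 1.5)
})
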