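test_that("PCA scores match a direct eigendecomposition oracle", {
  expr <- .pcaStudy()
  pca <- pcaSamples(expr, k = 3)
  x <- t(log2(intensity(expr)))
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(xc %*% t(xc) / (nrow(xc) - 1), symmetric = TRUE)
  scoresOracle <- xc %*% eigen(t(xc) %*% xc / (nrow(xc) - 1),
                               symmetric = TRUE)$vectors[, 1:3]
  for (j in 1:3)  # sign-free comparison against the oracle
    expect_equal(abs(unname(pca$scores[, j])), abs(unname(scoresOracle[, j])),
                 tolerance = 1e-8)
  expect_equal(pca$varPct[1:3],
               100 * eig$values[1:3] / sum(pmax(eig$values, 0)),
               tolerance = 1e-6)
  expect_true(all(diff(pca$varPct) <= 1e-9))
  expect_error(pcaSamples(expr, k = 20), "sample count")
})

test_that("identical samples get identical scores; rank-1 data load on PC1", {
  m <- 2 ^ matrix(rnorm(40 * 4, 6, 1), 40)
  m[, 2] <- m[, 1]
  colnames(m) <- paste0("s", 1:4)
  rownames(m) <- paste0("g", 1:40)
  expr <- CSSExperiment(m, data.frame(strain = "a", age = 5,
                                      replicate = 1:4,
                                      row.names = colnames(m)),
                        data.frame(chrom = "1", position = 1:40,
                                   row.names = rownames(m)))
  pca <- pcaSamples(expr, k = 2)
  expect_equal(pca$scores[1, ], pca$scores[2, ], ignore_attr = TRUE)
  # rank-1 structure: one direction carries ~all variance
  v <- rnorm(30); w <- c(1, 2, 3, 4)
  m1 <- 2 ^ (6 + outer(v, w))
  rownames(m1) <- paste0("g", 1:30); colnames(m1) <- paste0("s", 1:4)
  expr1 <- CSSExperiment(m1, data.frame(strain = "a", age = 5,
                                        replicate = 1:4,
                                        row.names = colnames(m1)),
                         data.frame(chrom = "1", position = 1:30,
                                    row.names = rownames(m1)))
  expect_gt(pcaSamples(expr1, k = 2)$varPct[1], 99.9)
})

test_that("restoration typing is nearest-centroid on PC1 with a dead band", {
  expr <- .pcaStudy()
  pca <- pcaSamples(expr, k = 2)
  host <- paste0("host", 1:3); css <- paste0("css", 1:3)
  f1 <- paste0("F1", 1:3)
  res <- assignRestoration(pca, host, css, c(host[1], css[1], f1))
  expect_identical(res$type[1], "restored")       # at the host centroid
  expect_identical(res$type[2], "non_restored")   # at the CSS centroid
  # a huge margin pushes everything into the conservative class
  wide <- assignRestoration(pca, host, css, f1, margin = 1e6)
  expect_true(all(wide$type == "non_restored"))
  expect_error(assignRestoration(pca, host[1], css, f1), "length")
})

test_that("known restored/non-restored F1 individuals are recovered", {
  layout <- tinyLayout(genesPerChrom = 80, seed = 52)
  arch <- sampleArchitecture(layout, pCis = 0.1, pIncomp = 0.3, seed = 52)
  cfg <- simulationConfig(noiseSd = 0.25, ages = 7, seed = 52)
  f1 <- generateF1Restoration(layout, arch, tinyStrains(), cfg,
                              nRestored = 3, nNonRestored = 5)
  pca <- pcaSamples(f1$experiment, k = 2)
  cd <- SummarizedExperiment::colData(f1$experiment)
  res <- assignRestoration(pca,
                           rownames(cd)[cd$strain == "host"],
                           rownames(cd)[cd$strain == "cssX"],
                           f1$truth$sample)
  expect_identical(res$type == "restored", f1$truth$restored)
})

test_that("restoration typing is invariant to overall intensity scaling", {
  expr <- .pcaStudy()
  scaled <- CSSExperiment(intensity(expr) * 16,
                          SummarizedExperiment::colData(expr),
                          SummarizedExperiment::rowData(expr))
  host <- paste0("host", 1:3); css <- paste0("css", 1:3)
  f1 <- paste0("F1", 1:3)
  a <- assignRestoration(pcaSamples(expr, 2), host, css, f1)
  b <- assignRestoration(pcaSamples(scaled, 2), host, css, f1)
  expect_identical(a$type, b$type)
})

test_that("top-k ranking uses |log2FC| with documented tie-breaks", {
  calls <- data.frame(
    probeSet = c("a", "b", "c", "d", "e"),
    chrom = "X", position = 1:5,
    log2FC = c(2, -2, 1.5, 1, 0.2),
    adjP = c(0.02, 0.01, 0.001, 0.001, 0.4),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  top <- topKTable(calls, k = 3)
  # |2| ties a vs b -> smaller adjP (b) first; then a; then c
  expect_identical(top$probeSet, c("b", "a", "c"))
  expect_identical(topKTable(calls, k = 1)$probeSet, "b")
  # k larger than the significant set truncates
  expect_equal(nrow(topKTable(calls, k = 50)), 4)
  # comparison columns are matched by probe id
  other <- calls; other$log2FC <- calls$log2FC / 10
  top2 <- topKTable(calls, k = 2, comparisonCalls = list(restored = other))
  expect_equal(top2$log2FC_restored, top2$log2FC / 10)
})
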