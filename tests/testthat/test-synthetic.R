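test_that("genome layout has the requested size and is seed-deterministic", {
  gl <- generateGenome(19, 50, seed = 1)
  expect_equal(nrow(gl$genes), 1000)
  expect_equal(nrow(gl$chromosomes), 20)
  expect_true("X" %in% gl$chromosomes$chrom)
  expect_identical(gl, generateGenome(19, 50, seed = 1))
  expect_false(identical(gl$genes, generateGenome(19, 50, seed = 2)$genes))

  minimal <- generateGenome(1, 1, seed = 0)
  expect_equal(nrow(minimal$genes), 2)
  expect_setequal(minimal$genes$chrom, c("1", "X"))
  expect_true(all(minimal$genes$position <= minimal$chromosomes$lengthBp))

  expect_error(generateGenome(0, 5), "must be >= 1")
  expect_error(generateGenome(5, 0), "must be >= 1")
})

test_that("all-conserved architecture gives null fold changes", {
  st <- tinyStudy(noiseSd = 0.05)
  arch <- uniformArchitecture(st$layout, "conserved")
  cfg <- simulationConfig(noiseSd = 0.05, ages = 5, seed = 3)
  expr <- generateExpressionStudy(st$layout, arch, st$strains, cfg)
  fc <- log2FoldChanges(expr, "cssX", "host")
  # group means differ only by replicate noise: sd(fc) ~ noiseSd*sqrt(2/3)
  expect_lt(max(abs(fc)), 0.05 * sqrt(2 / 3) * 5)
  expect_lt(abs(mean(fc)), 0.02)
})

test_that("cis-divergent gene inside the donor interval tracks the donor", {
  layout <- tinyLayout()
  arch <- uniformArchitecture(layout, "conserved")
  xGene <- which(layout$genes$chrom == "X")[1]
  arch$class[xGene] <- "cis_divergent"
  arch$cisEffect[xGene] <- 1
  cfg <- simulationConfig(replicates = 50, noiseSd = 0.05, ages = 5,
                          seed = 11)
  expr <- generateExpressionStudy(layout, arch, tinyStrains(), cfg)
  fcHost <- log2FoldChanges(expr, "cssX", "host")[xGene]
  fcDonor <- log2FoldChanges(expr, "cssX", "donor")[xGene]
  expect_equal(unname(2 ^ fcHost), 2.0, tolerance = 0.05)
  expect_equal(unname(2 ^ fcDonor), 1.0, tolerance = 0.05)
})

test_that("realized down-direction fraction matches the configured bias", {
  layout <- generateGenome(19, 50, seed = 11)
  arch <- sampleArchitecture(layout, pCis = 0, pIncomp = 0.2, pDown = 0.7,
                             seed = 11)
  inc <- arch[arch$class == "trans_incompatible", ]
  expect_gt(nrow(inc), 100)
  fracDown <- mean(inc$incompEffect < 0)
  se <- sqrt(0.7 * 0.3 / nrow(inc))
  expect_lt(abs(fracDown - 0.7), 3 * se)
  expect_true(all(abs(inc$incompEffect) >= 1))  # shifted folded normal
})

test_that("expression study is deterministic and linear-scale positive", {
  st <- tinyStudy(seed = 5)
  st2 <- tinyStudy(seed = 5)
  expect_identical(intensity(st$expr), intensity(st2$expr))
  expect_true(all(intensity(st$expr) > 0))
  cd <- SummarizedExperiment::colData(st$expr)
  expect_equal(sum(cd$strain == "host"), 3)
})

test_that("cascade targets shift only in the cascade epoch", {
  layout <- tinyLayout()
  arch <- uniformArchitecture(layout, "conserved")
  autoGene <- which(layout$genes$chrom == "1")[1]
  arch$class[autoGene] <- "cascade_target"
  arch$incompEffect[autoGene] <- -2
  cfg <- simulationConfig(replicates = 20, noiseSd = 0.05, ages = c(5, 7),
                          cascade = TRUE, seed = 13)
  expr <- generateExpressionStudy(layout, arch, tinyStrains(), cfg)
  fc5 <- log2FoldChanges(expr, "cssX", "host", age = 5)[autoGene]
  fc7 <- log2FoldChanges(expr, "cssX", "host", age = 7)[autoGene]
  expect_lt(abs(fc5), 0.15)
  expect_equal(unname(fc7), -2, tolerance = 0.1)
  # host and donor strains never cascade
  expect_lt(abs(log2FoldChanges(expr, "donor", "host", age = 7)[autoGene]),
            0.15)
})

test_that("probe annotation rates follow the configured polymorphism rates", {
  layout <- tinyLayout(genesPerChrom = 300)
  strains <- tinyStrains()

  clean <- generateProbeAnnotation(layout, strains["cssX"], 0, 0, seed = 2)
  expect_true(all(clean$nIdentified == 11 & clean$nPerfect == 11))
  expect_true(all(clean$polyScore == 0))
  expect_true(all(clean$status == "conserved"))

  full <- generateProbeAnnotation(layout, strains["cssX"], 1, 0, seed = 2)
  onX <- full$chrom == "X"
  expect_true(all(full$nPerfect[onX] == 0))
  expect_true(all(full$status[onX] == "polymorphic"))
  expect_true(all(full$nPerfect[!onX] >= 0))

  ann <- generateProbeAnnotation(layout, strains["cssX"], 0.35, 0.02,
                                 seed = 4)
  fracPoly <- mean((11 - ann$nPerfect[ann$chrom == "X"]) / 11)
  nProbes <- sum(ann$chrom == "X") * 11
  se <- sqrt(0.35 * 0.65 / nProbes)
  expect_lt(abs(fracPoly - 0.35), 4 * se)
  expect_true(all(ann$nPerfect <= ann$nIdentified &
                    ann$nIdentified <= ann$nProbes))
  expect_error(generateProbeAnnotation(layout, strains["cssX"], 1.2, 0),
               "polyRateDonor")
})

test_that("backcross recombination follows the Haldane map function", {
  # Haldane properties
  expect_equal(haldane(0), 0)
  expect_equal(haldane(1e9), 0.5)
  d <- seq(0, 200, by = 5)
  expect_true(all(diff(haldane(d)) > 0))

  # adjacent markers 10 cM apart: recombinant fraction 0.5(1 - e^{-0.2})
  bc <- generateBackcross(nProgeny = 5000, nMarkers = 2,
                          chromLengthBp = 2e7 + 1, cmPerMb = 0.5,
                          qtlPosBp = 1e7, qtlEffect = 0, seed = 21)
  g <- genotypes(bc)
  expect_equal(diff(markerMap(bc)$cM), 10, tolerance = 1e-6)
  rec <- mean(g[, 1] != g[, 2])
  expected <- 0.5 * (1 - exp(-0.2))
  se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(rec - expected), 4 * se)

  # no recombination: all markers co-inherit
  bc0 <- generateBackcross(nProgeny = 50, nMarkers = 10, cmPerMb = 0,
                           seed = 3)
  expect_true(all(apply(genotypes(bc0), 1,
                        function(r) length(unique(r)) == 1)))

  expect_error(generateBackcross(qtlPosBp = 1e12), "outside")
})

test_that("genotype coding and trait model are as declared", {
  bc <- generateBackcross(nProgeny = 200, nMarkers = 20, qtlEffect = 5,
                          residualSd = 0.5, seed = 9)
  g <- genotypes(bc)
  expect_true(all(g %in% c(0L, 1L)))
  # marker nearest the QTL separates the trait classes by ~ the effect
  map <- markerMap(bc)
  k <- which.min(abs(map$bp - 6.45e7))
  y <- traits(bc)$trait
  expect_equal(mean(y[g[, k] == 1]) - mean(y[g[, k] == 0]), 5,
               tolerance = 0.5)
})
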