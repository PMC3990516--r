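test_that("default polymorphism score follows the linear classifier", {
  expect_identical(polymorphismScore(11, 11, 11), 0L)
  expect_identical(probeStatus(0L), "conserved")
  expect_identical(polymorphismScore(0, 0, 11), 33L)
  expect_identical(probeStatus(33L), "polymorphic")
  expect_identical(polymorphismScore(11, 7, 11), 8L)   # conserved
  expect_identical(polymorphismScore(11, 5, 11), 12L)  # polymorphic
  expect_identical(probeStatus(c(8L, 12L)), c("conserved", "polymorphic"))
  expect_error(polymorphismScore(5, 7, 11), "nPerfect")
  expect_error(polymorphismScore(12, 3, 11), "nPerfect")
})

test_that("score is monotone in unidentified and mismatched probe counts", {
  for (id in 0:11) for (pf in 0:id) {
    s <- polymorphismScore(id, pf, 11)
    if (id < 11)  # one more probe identified (perfectly) never raises score
      expect_gte(s, polymorphismScore(id + 1, pf + 1, 11))
    if (pf < id)  # one more mismatch raises the score
      expect_gt(polymorphismScore(id, pf, 11), polymorphismScore(id, pf + 1,
                                                                 11))
  }
  # score 0 iff fully identified and perfect
  grid <- expand.grid(id = 0:11, pf = 0:11)
  grid <- grid[grid$pf <= grid$id, ]
  z <- polymorphismScore(grid$id, grid$pf, 11) == 0L
  expect_identical(z, grid$id == 11 & grid$pf == 11)
})

test_that("a custom score table overrides the linear rule", {
  tab <- matrix(0L, 12, 12)
  tab[1, 1] <- 99L       # zero identified probes
  tab[12, 3] <- 7L       # 11 identified, 2 polymorphic
  expect_identical(polymorphismScore(0, 0, 11, scoreTable = tab), 99L)
  expect_identical(polymorphismScore(11, 9, 11, scoreTable = tab), 7L)
  expect_error(polymorphismScore(11, 9, 11, scoreTable = tab[1:3, 1:3]),
               "scoreTable")
})

.filterFixture <- function() {
  ann <- data.frame(
    probeSet = paste0("p", 1:6),
    chrom = c("X", "1", "Un", "Y", "X", "X"),
    position = c(5e7, 5e7, 1e6, 1e6, 9.9e7, 1.55e8),
    status = c("polymorphic", "polymorphic", "conserved", "conserved",
               "conserved", "polymorphic"),
    stringsAsFactors = FALSE)
  css <- StrainModel("css", chrom = c("X", "X"),
                     start = c(2e7, 1e7), end = c(1.5e8, 2e7 - 1),
                     zone = c("donor", "boundary"))
  list(ann = ann, strains = list(StrainModel("host"), css))
}

test_that("region filters remove the right probe sets", {
  fx <- .filterFixture()
  res <- applyRegionFilters(fx$ann, fx$strains)
  # p1: polymorphic inside donor X interval -> removed
  # p2: polymorphic on an untouched autosome -> retained
  # p3: unknown chromosome -> removed; p4: Y-linked -> removed
  # p5: conserved inside donor region -> retained
  # p6: polymorphic on X but outside the donor interval -> retained
  expect_identical(res$retained,
                   c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  rep <- setNames(res$report$count, res$report$filter)
  expect_identical(rep[["unknown_chromosome"]], 1L)
  expect_identical(rep[["y_linked"]], 1L)
  expect_identical(rep[["polymorphic_in_donor_region"]], 1L)
  expect_identical(sum(res$report$count), nrow(fx$ann))
})

test_that("boundary intervals exclude probe sets regardless of status", {
  fx <- .filterFixture()
  fx$ann$position[5] <- 1.5e7  # conserved probe, inside the boundary stripe
  res <- applyRegionFilters(fx$ann, fx$strains)
  expect_false(res$retained[5])
  expect_equal(res$report$count[res$report$filter == "boundary_region"], 1)
})

test_that("region filtering is idempotent and errors on missing locations", {
  fx <- .filterFixture()
  first <- applyRegionFilters(fx$ann, fx$strains)
  again <- applyRegionFilters(fx$ann[first$retained, ], fx$strains)
  expect_true(all(again$retained))
  fx$ann$position[2] <- NA
  expect_error(applyRegionFilters(fx$ann, fx$strains), "location")
})

test_that("intensity filter keeps probe sets expressed in either strain", {
  m <- rbind(a = c(5, 5, 5, 50, 50, 50),    # mean 5 vs 50 -> keep
             b = c(5, 5, 5, 5, 5, 5),       # 5 vs 5 -> drop
             c = c(10, 10, 10, 10, 10, 10), # exactly 10 -> drop (strict >)
             d = c(50, 50, 50, 5, 5, 5))    # 50 vs 5 -> keep
  colnames(m) <- paste0("s", 1:6)
  expr <- CSSExperiment(
    m,
    colData = data.frame(strain = rep(c("A", "B"), each = 3),
                         age = 5, replicate = rep(1:3, 2),
                         row.names = colnames(m)),
    rowData = data.frame(chrom = "1", position = 1:4,
                         row.names = rownames(m)))
  expect_identical(unname(intensityFilter(expr, "A", "B", 10)),
                   c(TRUE, FALSE, FALSE, TRUE))
  # per-sample variant keeps anything with a single sample above threshold
  m2 <- m; m2["b", 6] <- 11
  expr2 <- CSSExperiment(m2, SummarizedExperiment::colData(expr),
                         SummarizedExperiment::rowData(expr))
  expect_true(intensityFilter(expr2, "A", "B", 10, perSample = TRUE)[2])
  expect_error(intensityFilter(expr, "A", "nope", 10), "no samples")
})
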