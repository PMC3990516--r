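#' Pipeline run configuration
#'
#' Collects every knob of the synthetic end-to-end analysis in one list:
#' genome size, regulatory architecture, strain composition, replication and
#' noise, analysis thresholds, backcross design and the master seed. The
#' defaults emulate the study design the package models: ~20 chromosomes,
#' 3 replicates per strain at 5 and 7 days postpartum, a whole-X and a
#' distal-X substitution strain, an intensity filter at 10, fold-change
#' threshold 1.5 at FDR 0.05, polymorphism-score threshold 10, convergence
#' band 1.5, intensity strata 10/100/1000, and a 314-progeny backcross with
#' 80 markers and one QTL at 64.5 Mb.
#'
#' @param seed master seed; all stage seeds derive from it
#' @param nAutosomes,genesPerChrom genome size
#' @param chromLengthBp chromosome length (bp)
#' @param pCis,pIncomp,pCascade,pDown architecture fractions and down bias
#' @param replicates,noiseSd,ages,cascade study design
#' @param intensityThreshold,fcThreshold,alpha,scoreThreshold,band analysis
#'   thresholds
#' @param strata intensity band edges for dispersion stratification
#' @param xSplitBp proximal/distal X breakpoint (bp)
#' @param donorStartBp,donorEndBp donor interval of the whole-X strain
#' @param qtl list: \code{nProgeny}, \code{nMarkers}, \code{qtlPosBp},
#'   \code{qtlEffect}, \code{residualSd}, \code{cmPerMb}
#' @return list with class \code{"RunConfig"}
#' @export
runConfig <- function(seed = 1L, nAutosomes = 19L, genesPerChrom = 500L,
                      chromLengthBp = 1.66e8, pCis = 0.1, pIncomp = 0.1,
                      pCascade = 0.1, pDown = 0.7, replicates = 3L,
                      noiseSd = 0.25, ages = c(5, 7), cascade = TRUE,
                      intensityThreshold = 10, fcThreshold = 1.5,
                      alpha = 0.05, scoreThreshold = 10, band = 1.5,
                      strata = c(10, 100, 1000), xSplitBp = 86497454,
                      donorStartBp = 5341800, donorEndBp = 163344914,
                      qtl = list(nProgeny = 314L, nMarkers = 80L,
                                 qtlPosBp = 6.45e7, qtlEffect = 1,
                                 residualSd = 1, cmPerMb = 0.5)) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Validate a run configuration
#'
#' Checks every constraint and returns all violations (nothing is silently
#' corrected). An empty character vector means the configuration is valid.
#'
#' @param config a \code{"RunConfig"}
#' @return character vector of problems (empty if ok)
#' @export
validateConfig <- function(config) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(config$nAutosomes >= 1, "nAutosomes must be >= 1")
  chk(config$genesPerChrom >= 1, "genesPerChrom must be >= 1")
  chk(config$replicates >= 2, "replicates must be >= 2 for the t-test")
  chk(config$noiseSd > 0, "noiseSd must be > 0")
  chk(all(c(config$pCis, config$pIncomp, config$pCascade) >= 0) &&
        config$pCis + config$pIncomp + config$pCascade <= 1,
      "class fractions must be >= 0 and sum to <= 1")
  chk(config$pDown >= 0 && config$pDown <= 1, "pDown must be in [0, 1]")
  chk(config$intensityThreshold > 0, "intensityThreshold must be positive")
  chk(config$fcThreshold >= 1, "fcThreshold must be >= 1")
  chk(config$alpha >= 0 && config$alpha <= 1, "alpha must be in [0, 1]")
  chk(config$band > 1, "band must be > 1")
  chk(!is.unsorted(config$strata, strictly = TRUE),
      "strata must be strictly ascending")
  chk(config$donorStartBp < config$donorEndBp,
      "donor interval must have start < end")
  chk(config$xSplitBp > 0 && config$xSplitBp < config$chromLengthBp,
      "xSplitBp must lie inside the chromosome")
  q <- config$qtl
  chk(q$nProgeny >= 10, "qtl$nProgeny must be >= 10")
  chk(q$nMarkers >= 2, "qtl$nMarkers must be >= 2")
  chk(q$qtlPosBp > 0 && q$qtlPosBp <= config$chromLengthBp,
      "qtl$qtlPosBp must lie inside the chromosome")
  chk(q$residualSd > 0, "qtl$residualSd must be > 0")
  p
}

# the strain panel of the emulated design: host, donor, whole-X CSS,
# distal-X CSS (2 Mb boundary stripes flank each donor interval edge
# that lies inside the chromosome)
.defaultStrains <- function(config) {
  bnd <- 2e6
  len <- config$chromLengthBp
  end <- min(config$donorEndBp, len)
  autoChroms <- as.character(seq_len(config$nAutosomes))
  donorAll <- StrainModel("donor", c(autoChroms, "X"),
                          rep(1, config$nAutosomes + 1),
                          rep(len, config$nAutosomes + 1),
                          rep("donor", config$nAutosomes + 1))
  list(
    host = StrainModel("host"),
    donor = donorAll,
    cssX = StrainModel("cssX",
                       chrom = c("X", "X"),
                       start = c(config$donorStartBp,
                                 max(1, config$donorStartBp - bnd)),
                       end = c(end, config$donorStartBp - 1),
                       zone = c("donor", "boundary")),
    cssXT = StrainModel("cssXT",
                        chrom = c("X", "X"),
                        start = c(config$xSplitBp,
                                  config$xSplitBp - bnd),
                        end = c(len, config$xSplitBp - 1),
                        zone = c("donor", "boundary")))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a study from the configuration, then runs every analysis
#' stage: probe filtering, differential-expression calling and frequency
#' tables for the whole-X and distal-X substitution strains at both ages,
#' stratified dispersion tests, parent-of-origin correlation comparison,
#' cis/incompatibility typing, DE-set overlap, PCA with restoration typing
#' of F1 individuals, and backcross QTL mapping. All tabular outputs are
#' written as TSV into \code{outDir} along with a plain-text manifest
#' recording the seed, thresholds and per-stage row counts. Outputs are
#' byte-identical for a fixed configuration.
#'
#' @param config a \code{"RunConfig"}
#' @param outDir output directory (created if missing); NULL skips writing
#' @return (invisibly) list with every stage result
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  problems <- validateConfig(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(x, name) {
    if (!is.null(outDir))
      .writeTsv(x, file.path(outDir, paste0(name, ".tsv")))
  }
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  layout <- generateGenome(config$nAutosomes, config$genesPerChrom,
                           seed = config$seed,
                           chromLengthBp = config$chromLengthBp)
  arch <- sampleArchitecture(layout, pCis = config$pCis,
                             pIncomp = config$pIncomp,
                             pCascade = config$pCascade,
                             pDown = config$pDown, seed = config$seed + 1L)
  strains <- .defaultStrains(config)
  simCfg <- simulationConfig(replicates = config$replicates,
                             noiseSd = config$noiseSd, ages = config$ages,
                             cascade = config$cascade,
                             seed = config$seed + 2L)
  expr <- generateExpressionStudy(layout, arch, strains, simCfg,
                                  host = "host", donor = "donor")
  ann <- generateProbeAnnotation(layout, strains[names(strains) != "donor"],
                                 seed = config$seed + 3L)
  note("probe sets simulated: ", nrow(ann))

  calls <- list(); freq <- list(); masks <- list()
  for (css in c("cssX", "cssXT")) {
    reg <- applyRegionFilters(ann, list(strains$host, strains[[css]]))
    for (age in config$ages) {
      keep <- reg$retained & intensityFilter(expr, css, "host",
                                             config$intensityThreshold,
                                             age = age)
      id <- paste0(css, "_", age, "dpp")
      masks[[id]] <- keep
      calls[[id]] <- deTest(expr, css, "host", age = age, mask = keep,
                            fcThreshold = config$fcThreshold,
                            alpha = config$alpha)
      freq[[id]] <- chromFrequencyTable(
        calls[[id]], xSplitBp = if (css == "cssXT") config$xSplitBp)
      emit(calls[[id]], paste0("de_", id))
      if (!is.null(outDir))
        writeFrequencyTable(freq[[id]],
                            file.path(outDir, paste0("freq_", id, ".tsv")))
      note(id, ": ", sum(keep), " probe sets analysed, ",
           sum(calls[[id]]$significant), " significant")
    }
    emit(reg$report, paste0("filter_report_", css))
  }

  cx <- calls[[paste0("cssX_", max(config$ages), "dpp")]]
  disp <- do.call(rbind, lapply(config$ages, function(age) {
    cc <- calls[[paste0("cssX_", age, "dpp")]]
    d <- stratifiedDispersion(cc$log2FC, 2 ^ cc$meanLog2Ref,
                              ifelse(cc$chrom == "X", "X", "autosomes"),
                              strata = config$strata)
    cbind(age = age, d)
  }))
  emit(disp, "dispersion")

  isX <- SummarizedExperiment::rowData(expr)$chrom == "X"
  xMask <- masks[[paste0("cssX_", config$ages[1], "dpp")]] & isX
  corr <- correlationComparison(expr, "cssX", "host", "donor",
                                subset = which(xMask),
                                age = config$ages[1])
  emit(corr, "correlation")

  donorSig <- cx[cx$chrom == "X", , drop = FALSE]
  typing <- classifyRegulatoryType(donorSig, expr, "cssX", "donor",
                                   age = max(config$ages),
                                   band = config$band)
  emit(typing$typing, "typing")
  emit(typing$summary, "typing_summary")

  ovl <- overlapAnalysis(calls[[paste0("cssX_", max(config$ages), "dpp")]],
                         calls[[paste0("cssXT_", max(config$ages), "dpp")]],
                         xSplitBp = config$xSplitBp)
  emit(data.frame(nA = ovl$nA, nB = ovl$nB, nCommon = ovl$nCommon,
                  pctOfB = ovl$pctOfB), "overlap")
  emit(ovl$breakdown, "overlap_breakdown")

  f1cfg <- simulationConfig(replicates = config$replicates,
                            noiseSd = config$noiseSd,
                            ages = max(config$ages), cascade = config$cascade,
                            seed = config$seed + 4L)
  f1 <- generateF1Restoration(layout, arch,
                              strains[c("host", "donor", "cssXT")], f1cfg,
                              host = "host", donor = "donor")
  pca <- pcaSamples(f1$experiment, k = 3)
  cdF1 <- SummarizedExperiment::colData(f1$experiment)
  rest <- assignRestoration(pca,
                            rownames(cdF1)[cdF1$strain == "host"],
                            rownames(cdF1)[cdF1$strain == "cssXT"],
                            rownames(cdF1)[cdF1$strain == "F1"])
  emit(data.frame(sample = rownames(pca$scores), pca$scores), "pca_scores")
  emit(rest, "restoration")
  note("restored F1 individuals called: ",
       sum(rest$type == "restored"), "/", nrow(rest))

  top <- topKTable(cx, k = 50,
                   comparisonCalls = list(
                     cssXT = calls[[paste0("cssXT_", max(config$ages),
                                           "dpp")]]))
  emit(top, "topk")

  q <- config$qtl
  bc <- generateBackcross(q$nProgeny, q$nMarkers,
                          chromLengthBp = config$chromLengthBp,
                          cmPerMb = q$cmPerMb, qtlPosBp = q$qtlPosBp,
                          qtlEffect = q$qtlEffect,
                          residualSd = q$residualSd,
                          seed = config$seed + 5L)
  scanSingle <- singleMarkerScan(bc)
  scanHK <- intervalMappingHK(bc)
  emit(as.data.frame(scanSingle), "lod_single")
  emit(as.data.frame(scanHK), "lod_hk")
  note("QTL peak (interval mapping): ",
       sprintf("%.1f Mb, LOD %.2f", lodPeak(scanHK)$positionBp / 1e6,
               lodPeak(scanHK)$lod))

  if (!is.null(outDir)) {
    manifest <- c(
      paste0("package: cssmisreg ",
             as.character(utils::packageVersion("cssmisreg"))),
      paste0("seed: ", config$seed),
      paste0("thresholds: intensity>", config$intensityThreshold,
             " fc>=", config$fcThreshold, " alpha<", config$alpha,
             " score<=", config$scoreThreshold, " band<", config$band),
      paste0("xSplitBp: ", config$xSplitBp),
      log)
    writeLines(manifest, file.path(outDir, "manifest.txt"))
  }
  invisible(list(layout = layout, architecture = arch, strains = strains,
                 expr = expr, annotation = ann, masks = masks,
                 calls = calls, freq = freq, dispersion = disp,
                 correlation = corr, typing = typing, overlap = ovl,
                 pca = pca, restoration = rest, restorationTruth = f1$truth,
                 topk = top, backcross = bc, lodSingle = scanSingle,
                 lodHK = scanHK, log = log))
}
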