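#' Generate a genome layout
#'
#' Builds a compact genome of autosomes plus one X chromosome with genes
#' placed uniformly at random, mimicking reference-genome (mm9-style)
#' coordinates. Used as scaffold for all synthetic studies.
#'
#' @param nAutosomes number of autosomes (>= 1)
#' @param genesPerChrom genes placed on each chromosome (>= 1)
#' @param seed integer seed fixing all randomness
#' @param chromLengthBp chromosome length in bp (single value recycled)
#' @return list with class \code{"GenomeLayout"}: \code{chromosomes}
#'   (data.frame \code{chrom}, \code{lengthBp}) and \code{genes} (data.frame
#'   \code{gene}, \code{chrom}, \code{position})
#' @examples
#' gl <- generateGenome(19, 50, seed = 1)
#' nrow(gl$genes)  # 1000
#' @export
generateGenome <- function(nAutosomes, genesPerChrom, seed = 1L,
                           chromLengthBp = 1.6e8) {
  if (nAutosomes < 1 || genesPerChrom < 1)
    stop("nAutosomes and genesPerChrom must be >= 1")
  set.seed(seed)
  chroms <- c(as.character(seq_len(nAutosomes)), "X")
  chromosomes <- data.frame(chrom = chroms,
                            lengthBp = rep(chromLengthBp, length(chroms)),
                            stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(ceiling(runif(genesPerChrom, 1, chromLengthBp)))
    data.frame(gene = sprintf("g%s_%03d", ch, seq_len(genesPerChrom)),
               chrom = ch, position = pos, stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  stopifnot(!anyDuplicated(genes$gene))
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "GenomeLayout")
}

#' Sample a regulatory architecture
#'
#' Assigns each gene to one of four regulatory classes and draws its effect
#' sizes (log2 units): \code{conserved} (no divergence),
#' \code{cis_divergent} (the donor allele carries its own cis-regulatory
#' level, inherited wherever the donor allele is present),
#' \code{trans_incompatible} (misexpressed only when the donor allele meets
#' the host trans-acting background, i.e. in a substitution strain), and
#' \code{cascade_target} (secondary misregulation on any chromosome that
#' appears only in the later "cascade" epoch).
#'
#' Incompatibility magnitudes are drawn as a shifted folded normal
#' (\code{shift + |N(0, sd)|}) with a Bernoulli sign, negative with
#' probability \code{pDown}, reproducing the downregulation bias seen among
#' misexpressed genes.
#'
#' @param layout a \code{GenomeLayout}
#' @param pCis,pIncomp,pCascade class fractions (conserved is the remainder;
#'   fractions must sum to <= 1)
#' @param cisSd sd of cis effects (log2)
#' @param incompShift,incompSd shifted-folded-normal parameters for
#'   incompatibility magnitudes (log2)
#' @param pDown probability that an incompatibility effect is negative
#' @param seed integer seed
#' @return data.frame: \code{gene}, \code{class}, \code{cisEffect},
#'   \code{incompEffect} (signed; for \code{cascade_target} genes this is
#'   the cascade-epoch effect)
#' @export
sampleArchitecture <- function(layout, pCis = 0.1, pIncomp = 0.1,
                               pCascade = 0, cisSd = 0.8, incompShift = 1,
                               incompSd = 0.5, pDown = 0.7, seed = 1L) {
  stopifnot(pCis >= 0, pIncomp >= 0, pCascade >= 0,
            pCis + pIncomp + pCascade <= 1,
            pDown >= 0, pDown <= 1)
  set.seed(seed)
  n <- nrow(layout$genes)
  cls <- sample(c("conserved", "cis_divergent", "trans_incompatible",
                  "cascade_target"), n, replace = TRUE,
                prob = c(1 - pCis - pIncomp - pCascade, pCis, pIncomp,
                         pCascade))
  cisEffect <- ifelse(cls == "cis_divergent", rnorm(n, 0, cisSd), 0)
  sign <- ifelse(runif(n) < pDown, -1, 1)
  mag <- incompShift + abs(rnorm(n, 0, incompSd))
  incompEffect <- ifelse(cls %in% c("trans_incompatible", "cascade_target"),
                         sign * mag, 0)
  data.frame(gene = layout$genes$gene, class = cls, cisEffect = cisEffect,
             incompEffect = incompEffect, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param replicates replicates per strain and age (default 3)
#' @param baselineMean,baselineSd log2 baseline distribution of gene
#'   expression (defaults 6 and 2: linear intensities spanning the three
#'   intensity strata 10--100, 100--1000, >1000)
#' @param noiseSd replicate noise sd in log2 units (default 0.25)
#' @param ages days-postpartum time points to simulate (default c(5, 7))
#' @param cascade logical; when TRUE, \code{cascade_target} genes acquire
#'   their incompatibility-type shifts in substitution strains at the last
#'   age only, emulating the genome-wide spread of misregulation between
#'   the two time points
#' @param seed integer seed
#' @return list with class \code{"SimulationConfig"}
#' @export
simulationConfig <- function(replicates = 3L, baselineMean = 6,
                             baselineSd = 2, noiseSd = 0.25,
                             ages = c(5, 7), cascade = FALSE, seed = 1L) {
  stopifnot(replicates >= 1, baselineSd > 0, noiseSd > 0, length(ages) >= 1)
  structure(list(replicates = as.integer(replicates),
                 baselineMean = baselineMean, baselineSd = baselineSd,
                 noiseSd = noiseSd, ages = ages, cascade = isTRUE(cascade),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# expected log2 offset of one gene in one strain at one age, given roles
.strainOffset <- function(gene, arch, strainModel, role, age, maxAge,
                          cascade) {
  cls <- arch$class
  off <- numeric(nrow(arch))
  if (role == "donor") {
    off <- ifelse(cls == "cis_divergent", arch$cisEffect, 0)
  } else if (role == "css") {
    donor <- donorRegions(strainModel)
    if (length(donor)) {
      gpos <- GenomicRanges::GRanges(gene$chrom,
                                     IRanges::IRanges(gene$position,
                                                      gene$position))
      inDonor <- IRanges::overlapsAny(gpos, donor)
      # heterozygous donor intervals express half the effect (additive model)
      zyg <- rep(1, length(gpos))
      hits <- GenomicRanges::findOverlaps(gpos, donor)
      het <- S4Vectors::mcols(donor)$zygosity[S4Vectors::subjectHits(hits)] ==
        "heterozygous"
      zyg[S4Vectors::queryHits(hits)[het]] <- 0.5
      off <- ifelse(inDonor & cls == "cis_divergent", zyg * arch$cisEffect,
             ifelse(inDonor & cls == "trans_incompatible",
                    zyg * arch$incompEffect, 0))
    }
    if (cascade && age == maxAge)
      off <- off + ifelse(cls == "cascade_target", arch$incompEffect, 0)
  }
  off
}

#' Generate a synthetic expression study
#'
#' Simulates linear-scale probe-set intensities for a host strain, a donor
#' strain and one or more chromosome substitution strains, with known
#' per-gene ground truth. The log2 model is
#' \code{baseline + strain offset + N(0, noiseSd)} per replicate, then
#' exponentiated; offsets follow the regulatory architecture:
#' conserved genes track the host everywhere; cis-divergent genes track the
#' donor level wherever the donor allele is present; trans-incompatible
#' genes are misexpressed (host level + signed incompatibility effect) only
#' inside a donor-derived interval of a substitution strain; cascade targets
#' shift in substitution strains at the last age when cascade mode is on.
#'
#' @param layout a \code{GenomeLayout}
#' @param architecture data.frame from \code{\link{sampleArchitecture}}
#' @param strains named list of \linkS4class{StrainModel}; roles are given
#'   by \code{host} and \code{donor}, all other entries are substitution
#'   strains
#' @param config a \code{\link{simulationConfig}}
#' @param host,donor names (in \code{strains}) of the host and donor strains
#' @return a \linkS4class{CSSExperiment}; ground truth is stored in
#'   \code{rowData} (\code{class}, \code{cisEffect}, \code{incompEffect},
#'   \code{trueDirection} = realized direction in a substitution strain)
#' @export
generateExpressionStudy <- function(layout, architecture, strains, config,
                                    host = "host", donor = "donor") {
  stopifnot(inherits(config, "SimulationConfig"),
            host %in% names(strains), donor %in% names(strains),
            length(strains) >= 3)
  if (!identical(architecture$gene, layout$genes$gene))
    stop("architecture and layout gene lists differ")
  set.seed(config$seed)
  genes <- layout$genes
  maxAge <- max(config$ages)
  samples <- expand.grid(replicate = seq_len(config$replicates),
                         age = config$ages, strain = names(strains),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("strain", "age", "replicate")]
  sampleId <- sprintf("%s_%ddpp_r%d", samples$strain, samples$age,
                      samples$replicate)
  baseline <- rnorm(nrow(genes), config$baselineMean, config$baselineSd)
  mat <- matrix(NA_real_, nrow(genes), nrow(samples),
                dimnames = list(genes$gene, sampleId))
  for (j in seq_len(nrow(samples))) {
    s <- samples$strain[j]
    role <- if (s == host) "host" else if (s == donor) "donor" else "css"
    off <- .strainOffset(genes, architecture, strains[[s]], role,
                         samples$age[j], maxAge, config$cascade)
    mat[, j] <- 2 ^ (baseline + off + rnorm(nrow(genes), 0, config$noiseSd))
  }
  cssNames <- setdiff(names(strains), c(host, donor))
  # realized direction of misexpression in the (first) substitution strain
  offCss <- .strainOffset(genes, architecture, strains[[cssNames[1]]], "css",
                          maxAge, maxAge, config$cascade)
  trueDir <- ifelse(architecture$class %in%
                      c("trans_incompatible", "cascade_target") & offCss != 0,
                    ifelse(offCss > 0, "up", "down"), "none")
  rowData <- data.frame(chrom = genes$chrom, position = genes$position,
                        class = architecture$class,
                        cisEffect = architecture$cisEffect,
                        incompEffect = architecture$incompEffect,
                        trueDirection = trueDir,
                        row.names = genes$gene, stringsAsFactors = FALSE)
  CSSExperiment(mat, colData = data.frame(samples, row.names = sampleId),
                rowData = rowData)
}

#' Generate synthetic probe-set annotation
#'
#' Emulates the polymorphism structure of short-oligo probe sets measured
#' against a diverged donor genome: inside donor-derived intervals each
#' probe is polymorphic with probability \code{polyRateDonor} (elsewhere
#' \code{polyRateHost}); a polymorphic probe fails to be identified in the
#' donor genome with probability 0.3 and is otherwise identified but
#' imperfectly matched. Scores and status use
#' \code{\link{polymorphismScore}} with the default threshold.
#'
#' @param layout a \code{GenomeLayout}
#' @param strains list of \linkS4class{StrainModel}; the donor-divergent
#'   region is the union of their donor intervals
#' @param polyRateDonor,polyRateHost per-probe polymorphism rates in [0,1]
#' @param probesPerSet probes per probe set (default 11)
#' @param seed integer seed
#' @return data.frame: \code{probeSet}, \code{chrom}, \code{position},
#'   \code{nProbes}, \code{nIdentified}, \code{nPerfect}, \code{polyScore},
#'   \code{status}
#' @export
generateProbeAnnotation <- function(layout, strains, polyRateDonor = 0.35,
                                    polyRateHost = 0.02, probesPerSet = 11L,
                                    seed = 1L) {
  stopifnot(probesPerSet >= 1,
            polyRateDonor >= 0, polyRateDonor <= 1,
            polyRateHost >= 0, polyRateHost <= 1)
  set.seed(seed)
  genes <- layout$genes
  donor <- do.call(c, unname(lapply(strains, donorRegions)))
  gpos <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$position,
                                                  genes$position))
  inDonor <- if (length(donor)) IRanges::overlapsAny(gpos, donor)
             else rep(FALSE, length(gpos))
  rate <- ifelse(inDonor, polyRateDonor, polyRateHost)
  nPoly <- rbinom(nrow(genes), probesPerSet, rate)
  nUnident <- rbinom(nrow(genes), nPoly, 0.3)
  nIdentified <- probesPerSet - nUnident
  nPerfect <- probesPerSet - nPoly
  score <- polymorphismScore(nIdentified, nPerfect, probesPerSet)
  data.frame(probeSet = genes$gene, chrom = genes$chrom,
             position = genes$position, nProbes = probesPerSet,
             nIdentified = nIdentified, nPerfect = nPerfect,
             polyScore = score,
             status = ifelse(score <= 10, "conserved", "polymorphic"),
             stringsAsFactors = FALSE)
}

#' Haldane map function
#'
#' Recombination fraction for a genetic distance \code{d} in cM:
#' \code{r = 0.5 (1 - exp(-2 d / 100))}.
#'
#' @param dCm genetic distance in centimorgans
#' @return recombination fraction in [0, 0.5)
#' @export
haldane <- function(dCm) 0.5 * (1 - exp(-2 * dCm / 100))

#' Generate a synthetic backcross population
#'
#' Simulates a backcross (two genotype classes per locus: host homozygote
#' coded 0, heterozygote coded 1) along one chromosome. Genotypes follow a
#' Markov walk along ordered loci with Haldane recombination fractions from
#' the inter-locus genetic distances; one planted QTL contributes additively
#' to the quantitative trait.
#'
#' @param nProgeny number of progeny (default 314)
#' @param nMarkers number of equally spaced markers (default 80)
#' @param chromLengthBp chromosome length (default 195 Mb)
#' @param cmPerMb genetic map expansion (default 0.5 cM/Mb)
#' @param qtlPosBp position of the planted QTL (default 64.5 Mb)
#' @param qtlEffect additive effect of the heterozygous class, trait units
#' @param residualSd residual trait sd
#' @param seed integer seed
#' @param chrom chromosome name (default "1")
#' @param missingRate fraction of genotypes set missing (default 0)
#' @return a \linkS4class{BackcrossData} with trait columns \code{trait}
#'   (the QTL-linked trait) and, as metadata, the true QTL genotype is not
#'   retained -- only the markers are observed, as in a real cross
#' @export
generateBackcross <- function(nProgeny = 314L, nMarkers = 80L,
                              chromLengthBp = 1.95e8, cmPerMb = 0.5,
                              qtlPosBp = 6.45e7, qtlEffect = 1,
                              residualSd = 1, seed = 1L, chrom = "1",
                              missingRate = 0) {
  stopifnot(nProgeny >= 2, nMarkers >= 2, cmPerMb >= 0,
            missingRate >= 0, missingRate < 1)
  if (qtlPosBp < 1 || qtlPosBp > chromLengthBp)
    stop("qtlPosBp outside the chromosome")
  set.seed(seed)
  markerBp <- round(seq(1, chromLengthBp, length.out = nMarkers))
  lociBp <- sort(unique(c(markerBp, qtlPosBp)))
  qtlIdx <- match(qtlPosBp, lociBp)
  cm <- lociBp / 1e6 * cmPerMb
  r <- haldane(diff(cm))
  nLoci <- length(lociBp)
  g <- matrix(NA_integer_, nProgeny, nLoci)
  g[, 1] <- rbinom(nProgeny, 1, 0.5)
  for (k in seq_len(nLoci - 1L)) {
    flip <- rbinom(nProgeny, 1, r[k])
    g[, k + 1L] <- ifelse(flip == 1L, 1L - g[, k], g[, k])
  }
  trait <- 100 + qtlEffect * g[, qtlIdx] + rnorm(nProgeny, 0, residualSd)
  keep <- match(markerBp, lociBp)
  gm <- g[, keep, drop = FALSE]
  if (missingRate > 0)
    gm[matrix(runif(length(gm)) < missingRate, nrow(gm))] <- NA_integer_
  colnames(gm) <- sprintf("m%03d", seq_len(nMarkers))
  rownames(gm) <- sprintf("p%03d", seq_len(nProgeny))
  map <- data.frame(marker = colnames(gm), chrom = chrom, bp = markerBp,
                    cM = markerBp / 1e6 * cmPerMb, stringsAsFactors = FALSE)
  BackcrossData(gm, map, data.frame(trait = trait, row.names = rownames(gm)))
}

#' Generate an F1 restoration study
#'
#' Builds an expression study containing host replicates, substitution-strain
#' replicates, and F1 individuals of which a known subset is "restored"
#' (expresses at host levels; the incompatibility is rescued) while the rest
#' remain misexpressed like the substitution strain. Used to exercise
#' PCA-based restoration typing with known labels.
#'
#' @param layout,architecture,strains,config,host,donor as in
#'   \code{\link{generateExpressionStudy}}; \code{strains} must contain one
#'   substitution strain
#' @param nRestored,nNonRestored numbers of F1 individuals of each type
#' @return list: \code{experiment} (a \linkS4class{CSSExperiment} whose F1
#'   samples have strain \code{"F1"}), \code{truth} (data.frame sample /
#'   restored flag)
#' @export
generateF1Restoration <- function(layout, architecture, strains, config,
                                  nRestored = 3L, nNonRestored = 5L,
                                  host = "host", donor = "donor") {
  base <- generateExpressionStudy(layout, architecture, strains, config,
                                  host = host, donor = donor)
  css <- setdiff(names(strains), c(host, donor))[1]
  set.seed(config$seed + 1L)
  genes <- layout$genes
  maxAge <- max(config$ages)
  baselineLog2 <- NULL
  # rebuild per-sample F1 profiles: restored = host offsets, else css offsets
  offHost <- rep(0, nrow(genes))
  offCss <- .strainOffset(genes, architecture, strains[[css]], "css",
                          maxAge, maxAge, config$cascade)
  # use the realized host-group mean as the baseline anchor
  hostCols <- colnames(base)[SummarizedExperiment::colData(base)$strain ==
                               host]
  anchor <- rowMeans(log2(intensity(base)[, hostCols, drop = FALSE]))
  nF1 <- nRestored + nNonRestored
  f1 <- sapply(seq_len(nF1), function(i) {
    off <- if (i <= nRestored) offHost else offCss
    2 ^ (anchor + off + rnorm(nrow(genes), 0, config$noiseSd))
  })
  colnames(f1) <- sprintf("F1_%ddpp_i%d", maxAge, seq_len(nF1))
  rownames(f1) <- rownames(base)
  mat <- cbind(intensity(base), f1)
  cd <- rbind(
    as.data.frame(SummarizedExperiment::colData(base)),
    data.frame(strain = "F1", age = maxAge, replicate = seq_len(nF1),
               row.names = colnames(f1)))
  expt <- CSSExperiment(mat, colData = cd,
                        rowData =
                          as.data.frame(SummarizedExperiment::rowData(base)))
  list(experiment = expt,
       truth = data.frame(sample = colnames(f1),
                          restored = seq_len(nF1) <= nRestored))
}
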