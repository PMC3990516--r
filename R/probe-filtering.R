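#' Polymorphism score for a probe set
#'
#' Scores how diverged a probe set is from the donor genome, from the number
#' of its probes identified in the donor genome and the number matching it
#' perfectly. The default classifier is the linear rule
#' \code{3 (total - identified) + 2 (identified - perfect)}: an unidentified
#' probe counts more heavily than an identified-but-mismatched one, and the
#' score is monotone non-decreasing in both. Probe sets with score <= 10 are
#' treated as "conserved"; higher scores mark "polymorphic" probe sets whose
#' donor-allele signal is unreliable (mishybridisation) and which are
#' excluded inside donor-derived regions.
#'
#' @param nIdentified probes identified in the donor genome
#' @param nPerfect probes perfectly matching the donor sequence
#' @param nTotal probes per probe set (default 11)
#' @param scoreTable optional (nTotal+1) x (nTotal+1) matrix replacing the
#'   default rule; entry [i+1, j+1] is the score for i identified probes of
#'   which j are polymorphic (i.e. identified but mismatched)
#' @return integer score vector
#' @examples
#' polymorphismScore(11, 11, 11)  # 0, fully conserved
#' polymorphismScore(11, 5, 11)   # 12, polymorphic
#' @export
polymorphismScore <- function(nIdentified, nPerfect, nTotal = 11L,
                              scoreTable = NULL) {
  n <- max(length(nIdentified), length(nPerfect), length(nTotal))
  nIdentified <- rep_len(as.integer(nIdentified), n)
  nPerfect <- rep_len(as.integer(nPerfect), n)
  nTotal <- rep_len(as.integer(nTotal), n)
  if (any(nPerfect < 0 | nPerfect > nIdentified | nIdentified > nTotal))
    stop("need 0 <= nPerfect <= nIdentified <= nTotal")
  nMismatch <- nIdentified - nPerfect
  if (is.null(scoreTable))
    return(3L * (nTotal - nIdentified) + 2L * nMismatch)
  if (nrow(scoreTable) != nTotal[1] + 1L || ncol(scoreTable) != nTotal[1] + 1L)
    stop("scoreTable must be (nTotal+1) x (nTotal+1)")
  as.integer(scoreTable[cbind(nIdentified + 1L, nMismatch + 1L)])
}

#' Probe-set status from polymorphism score
#'
#' @param score integer score vector
#' @param threshold conserved iff score <= threshold (default 10)
#' @return character vector, \code{"conserved"} or \code{"polymorphic"}
#' @export
probeStatus <- function(score, threshold = 10L) {
  ifelse(score <= threshold, "conserved", "polymorphic")
}

#' Apply genomic region filters to probe sets
#'
#' Pre-analysis filtering for a two-strain comparison: removes probe sets
#' with an unknown chromosome location, Y-linked probe sets, probe sets in a
#' boundary (undefined-genotype) interval of either compared strain, and
#' polymorphic-status probe sets lying inside a donor-derived (homozygous or
#' heterozygous) interval of either strain. Conserved probe sets are kept
#' regardless of location; polymorphic probe sets outside any donor interval
#' are also kept, since there the host allele is the one measured.
#'
#' Each removed probe set is attributed to the first rule that removed it
#' (order: unknown chromosome, Y, boundary, polymorphic-in-donor), so the
#' report is a partition of the input.
#'
#' @param annotation data.frame as from \code{\link{generateProbeAnnotation}}
#'   (needs \code{probeSet}, \code{chrom}, \code{position}, \code{status})
#' @param strainModels list of \linkS4class{StrainModel} for the strains in
#'   the comparison (typically the two compared strains)
#' @param unknownChrom chromosome labels treated as unknown location
#' @return list: \code{retained} (logical mask aligned with
#'   \code{annotation}), \code{report} (data.frame of removal counts)
#' @export
applyRegionFilters <- function(annotation, strainModels,
                               unknownChrom = c("Un", "unknown", "NA", "")) {
  need <- c("probeSet", "chrom", "position", "status")
  if (!all(need %in% colnames(annotation)))
    stop("annotation must contain: ", paste(need, collapse = ", "))
  if (any(is.na(annotation$position)))
    stop("probe set(s) without a location record: ",
         paste(head(annotation$probeSet[is.na(annotation$position)], 3),
               collapse = ", "))
  if (inherits(strainModels, "StrainModel"))
    strainModels <- list(strainModels)
  gpos <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$position,
                                                  annotation$position))
  boundary <- do.call(c, unname(lapply(strainModels, boundaryRegions)))
  donor <- do.call(c, unname(lapply(strainModels, donorRegions)))
  inBoundary <- if (length(boundary)) IRanges::overlapsAny(gpos, boundary)
                else rep(FALSE, length(gpos))
  inDonor <- if (length(donor)) IRanges::overlapsAny(gpos, donor)
             else rep(FALSE, length(gpos))

  unknown <- annotation$chrom %in% unknownChrom | is.na(annotation$chrom)
  yLinked <- !unknown & annotation$chrom %in% c("Y", "chrY")
  bnd <- !unknown & !yLinked & inBoundary
  polyDonor <- !unknown & !yLinked & !bnd &
    annotation$status == "polymorphic" & inDonor
  retained <- !(unknown | yLinked | bnd | polyDonor)
  report <- data.frame(
    filter = c("unknown_chromosome", "y_linked", "boundary_region",
               "polymorphic_in_donor_region", "retained"),
    count = c(sum(unknown), sum(yLinked), sum(bnd), sum(polyDonor),
              sum(retained)),
    stringsAsFactors = FALSE)
  stopifnot(sum(report$count) == nrow(annotation))
  list(retained = retained, report = report)
}

#' Expression-intensity filter
#'
#' Keeps probe sets whose mean linear intensity over replicates exceeds the
#' threshold in at least one of the two compared strains (strictly greater:
#' a mean exactly at the threshold is removed). With
#' \code{perSample = TRUE}, any single sample above threshold suffices.
#'
#' @param expr a \linkS4class{CSSExperiment}
#' @param strainA,strainB strain names of the comparison
#' @param threshold raw intensity threshold (default 10)
#' @param age restrict to samples at this age (days postpartum); NULL uses
#'   all samples of each strain
#' @param perSample use per-sample rather than replicate-mean intensities
#' @return logical mask over probe sets
#' @export
intensityFilter <- function(expr, strainA, strainB, threshold = 10,
                            age = NULL, perSample = FALSE) {
  cd <- SummarizedExperiment::colData(expr)
  pick <- function(strain) {
    sel <- cd$strain == strain
    if (!is.null(age)) sel <- sel & cd$age == age
    if (!any(sel)) stop("no samples for strain ", strain)
    intensity(expr)[, sel, drop = FALSE]
  }
  a <- pick(strainA); b <- pick(strainB)
  if (perSample) {
    apply(a > threshold, 1, any) | apply(b > threshold, 1, any)
  } else {
    rowMeans(a) > threshold | rowMeans(b) > threshold
  }
}
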