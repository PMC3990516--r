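#' Strain genome composition
#'
#' Describes which genomic intervals of a chromosome substitution strain are
#' derived from the donor genome, and which boundary intervals have an
#' undefined genotype (recombination breakpoints are only localised between
#' flanking markers, so probe sets falling in these stripes cannot be
#' assigned to either parental genome and are excluded from analysis).
#'
#' @slot strain single strain name
#' @slot regions a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{zone} (\code{"donor"} or \code{"boundary"}) and \code{zygosity}
#'   (\code{"homozygous"} or \code{"heterozygous"}); coordinates are 1-based
#'   inclusive bp
#'
#' @details Donor intervals must not overlap each other within a chromosome.
#'   A pure host strain is represented by an empty \code{regions} object; a
#'   full donor strain by donor intervals covering every chromosome.
#'
#' @aliases StrainModel-class
#' @export
setClass("StrainModel",
  slots = c(strain = "character", regions = "GRanges"))

setValidity("StrainModel", function(object) {
  msg <- character()
  if (length(object@strain) != 1L || is.na(object@strain) ||
      !nzchar(object@strain))
    msg <- c(msg, "'strain' must be a single non-empty name")
  mc <- S4Vectors::mcols(object@regions)
  if (!all(c("zone", "zygosity") %in% colnames(mc))) {
    msg <- c(msg, "regions must carry 'zone' and 'zygosity' metadata columns")
  } else {
    if (!all(mc$zone %in% c("donor", "boundary")))
      msg <- c(msg, "zone must be 'donor' or 'boundary'")
    if (!all(mc$zygosity %in% c("homozygous", "heterozygous")))
      msg <- c(msg, "zygosity must be 'homozygous' or 'heterozygous'")
    donor <- object@regions[mc$zone == "donor"]
    if (length(donor) > 1L) {
      hits <- GenomicRanges::findOverlaps(donor, donor)
      if (length(hits) > length(donor))
        msg <- c(msg, "donor intervals overlap within a chromosome")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StrainModel
#'
#' @param strain strain name
#' @param chrom,start,end parallel vectors defining intervals (1-based
#'   inclusive bp); may be empty for a pure host strain
#' @param zone \code{"donor"} or \code{"boundary"} per interval
#' @param zygosity \code{"homozygous"} (default) or \code{"heterozygous"}
#'   per interval
#' @return a \linkS4class{StrainModel}
#' @examples
#' xt <- StrainModel("CSS-XT", "X", 86497454, 165344914, "donor")
#' donorRegions(xt)
#' @export
StrainModel <- function(strain, chrom = character(), start = integer(),
                        end = integer(), zone = character(),
                        zygosity = rep("homozygous", length(chrom))) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.numeric(start),
                              end = as.numeric(end)))
  S4Vectors::mcols(gr)$zone <- as.character(zone)
  S4Vectors::mcols(gr)$zygosity <- as.character(zygosity)
  methods::new("StrainModel", strain = strain, regions = gr)
}

#' @rdname accessors
#' @export
setMethod("strainName", "StrainModel", function(x) x@strain)

#' @rdname accessors
#' @export
setMethod("donorRegions", "StrainModel", function(x)
  x@regions[S4Vectors::mcols(x@regions)$zone == "donor"])

#' @rdname accessors
#' @export
setMethod("boundaryRegions", "StrainModel", function(x)
  x@regions[S4Vectors::mcols(x@regions)$zone == "boundary"])

setMethod("show", "StrainModel", function(object) {
  cat("StrainModel:", object@strain, "\n")
  cat("  donor intervals:   ", length(donorRegions(object)), "\n")
  cat("  boundary intervals:", length(boundaryRegions(object)), "\n")
})

#' Expression container for substitution-strain studies
#'
#' A thin \link[SummarizedExperiment]{SummarizedExperiment} extension holding
#' linear-scale probe-set intensities (assay \code{"intensity"}), per-sample
#' metadata (\code{strain}, \code{age} in days postpartum, \code{replicate})
#' and per-probe-set genomic annotation (\code{chrom}, \code{position}).
#' All statistics in the package are computed on \code{log2(intensity)};
#' intensities must therefore be strictly positive.
#'
#' @aliases CSSExperiment-class
#' @export
setClass("CSSExperiment",
  contains = "SummarizedExperiment")

setValidity("CSSExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(!is.finite(a)) || any(a <= 0))
      msg <- c(msg, "intensities must be finite and > 0 (linear scale)")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("strain", "age", "replicate")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "position") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chrom' and 'position'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe set ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a CSSExperiment
#'
#' @param intensity numeric matrix of linear-scale intensities, probe sets
#'   in rows (rownames = probe set ids), samples in columns
#' @param colData data.frame with one row per sample: \code{strain},
#'   \code{age} (days postpartum), \code{replicate}
#' @param rowData data.frame with one row per probe set: \code{chrom},
#'   \code{position} (bp), plus optional annotation columns
#' @return a \linkS4class{CSSExperiment}
#' @export
CSSExperiment <- function(intensity, colData, rowData) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = as.matrix(intensity)),
    colData = S4Vectors::DataFrame(colData),
    rowData = S4Vectors::DataFrame(rowData))
  methods::new("CSSExperiment", se)
}

#' @rdname accessors
#' @export
setMethod("intensity", "CSSExperiment", function(x)
  SummarizedExperiment::assay(x, "intensity"))

setMethod("show", "CSSExperiment", function(object) {
  methods::callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat("strains:", paste(unique(cd$strain), collapse = ", "), "\n")
  cat("ages (dpp):", paste(sort(unique(cd$age)), collapse = ", "), "\n")
})

#' Backcross genotype and trait data
#'
#' Genotypes of backcross progeny (two classes per locus: 0 = host
#' homozygote, 1 = heterozygote; NA = missing), the marker map, and one or
#' more quantitative traits (e.g. testis weight in mg and its ratio to body
#' weight).
#'
#' @slot genotypes integer matrix, progeny in rows, markers in columns
#' @slot map data.frame with columns \code{marker}, \code{chrom}, \code{bp},
#'   \code{cM}, sorted by position
#' @slot traits data.frame of quantitative traits, one row per progeny
#'
#' @aliases BackcrossData-class
#' @export
setClass("BackcrossData",
  slots = c(genotypes = "matrix", map = "data.frame", traits = "data.frame"))

setValidity("BackcrossData", function(object) {
  msg <- character()
  g <- object@genotypes
  if (!all(g[!is.na(g)] %in% c(0L, 1L)))
    msg <- c(msg, "genotypes must be 0, 1 or NA (backcross coding)")
  if (ncol(g) != nrow(object@map))
    msg <- c(msg, "one map row per marker column required")
  need <- c("marker", "chrom", "bp", "cM")
  if (!all(need %in% colnames(object@map)))
    msg <- c(msg, paste("map must contain:", paste(need, collapse = ", ")))
  else if (is.unsorted(object@map$bp))
    msg <- c(msg, "markers must be sorted by bp position")
  if (nrow(object@traits) != nrow(g))
    msg <- c(msg, "one trait row per progeny required")
  if (nrow(object@traits) &&
      !all(vapply(object@traits, function(v) all(is.finite(v)), logical(1))))
    msg <- c(msg, "traits must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a BackcrossData object
#'
#' @param genotypes progeny x marker matrix coded 0/1/NA
#' @param map marker map data.frame (\code{marker}, \code{chrom}, \code{bp},
#'   \code{cM})
#' @param traits data.frame of trait values, one row per progeny
#' @return a \linkS4class{BackcrossData}
#' @export
BackcrossData <- function(genotypes, map, traits) {
  g <- as.matrix(genotypes)
  storage.mode(g) <- "integer"
  methods::new("BackcrossData", genotypes = g,
               map = as.data.frame(map), traits = as.data.frame(traits))
}

#' @rdname accessors
#' @export
setMethod("genotypes", "BackcrossData", function(x) x@genotypes)

#' @rdname accessors
#' @export
setMethod("markerMap", "BackcrossData", function(x) x@map)

#' @rdname accessors
#' @export
setMethod("traits", "BackcrossData", function(x) x@traits)

setMethod("show", "BackcrossData", function(object) {
  cat("BackcrossData:", nrow(object@genotypes), "progeny x",
      ncol(object@genotypes), "markers\n")
  cat("  chromosome(s):", paste(unique(object@map$chrom), collapse = ", "),
      "\n")
  cat("  traits:", paste(colnames(object@traits), collapse = ", "), "\n")
})
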