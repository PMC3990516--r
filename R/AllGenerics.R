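#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats aggregate anova approx coef cor ecdf lm median p.adjust
#'   pnorm prcomp pt quantile rbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table head read.csv write.csv
NULL

#' Accessor generics
#'
#' Small set of generics for the package's S4 containers: strain genome
#' composition (\code{strainName}, \code{donorRegions},
#' \code{boundaryRegions}), expression containers (\code{intensity}), and
#' backcross objects (\code{genotypes}, \code{markerMap}, \code{traits}).
#'
#' @param x an object of the appropriate class
#' @return the slot contents (see the class documentation)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strainName", function(x) standardGeneric("strainName"))

#' @rdname accessors
#' @export
setGeneric("donorRegions", function(x) standardGeneric("donorRegions"))

#' @rdname accessors
#' @export
setGeneric("boundaryRegions", function(x) standardGeneric("boundaryRegions"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname accessors
#' @export
setGeneric("traits", function(x) standardGeneric("traits"))
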