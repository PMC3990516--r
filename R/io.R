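#' Read and write expression studies as TSV
#'
#' The on-disk form of a \linkS4class{CSSExperiment} is three TSV files:
#' the intensity matrix (first column \code{probeSet}, one column per
#' sample), the sample metadata (\code{sample}, \code{strain}, \code{age},
#' \code{replicate}) and the probe annotation (\code{probeSet},
#' \code{chrom}, \code{position}, plus any extra columns). All files are
#' tab-separated with a header row, UTF-8, '.' decimal.
#'
#' @param exprPath,metaPath,annPath file paths
#' @return \code{readExpression}: a \linkS4class{CSSExperiment}
#' @export
readExpression <- function(exprPath, metaPath, annPath) {
  tab <- .readTsv(exprPath)
  if (!"probeSet" %in% colnames(tab)) stop("expression TSV needs 'probeSet'")
  dup <- tab$probeSet[duplicated(tab$probeSet)]
  if (length(dup)) stop("duplicate probe id(s): ",
                        paste(unique(dup), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensity cells")
  rownames(m) <- tab$probeSet
  meta <- .readTsv(metaPath)
  need <- c("sample", "strain", "age", "replicate")
  if (!all(need %in% colnames(meta)))
    stop("metadata TSV needs: ", paste(need, collapse = ", "))
  if (!setequal(meta$sample, colnames(m)))
    stop("sample ids in metadata do not match expression columns")
  meta <- meta[match(colnames(m), meta$sample), ]
  ann <- readProbeAnnotation(annPath)
  if (!setequal(ann$probeSet, rownames(m)))
    stop("probe ids in annotation do not match expression rows")
  ann <- ann[match(rownames(m), ann$probeSet), ]
  CSSExperiment(m,
                colData = data.frame(meta[, c("strain", "age", "replicate")],
                                     row.names = meta$sample),
                rowData = data.frame(ann[, setdiff(colnames(ann), "probeSet"),
                                         drop = FALSE],
                                     row.names = ann$probeSet))
}

#' @rdname readExpression
#' @param expr a \linkS4class{CSSExperiment}
#' @export
writeExpression <- function(expr, exprPath, metaPath, annPath) {
  m <- intensity(expr)
  .writeTsv(data.frame(probeSet = rownames(m), m, check.names = FALSE),
            exprPath)
  cd <- as.data.frame(SummarizedExperiment::colData(expr))
  .writeTsv(data.frame(sample = rownames(cd), cd, check.names = FALSE),
            metaPath)
  rd <- as.data.frame(SummarizedExperiment::rowData(expr))
  .writeTsv(data.frame(probeSet = rownames(rd), rd, check.names = FALSE),
            annPath)
  invisible(NULL)
}

#' Read a probe annotation table
#'
#' @param path TSV with columns \code{probeSet}, \code{chrom},
#'   \code{position} and optionally \code{nProbes}, \code{nIdentified},
#'   \code{nPerfect}, \code{polyScore}, \code{status}
#' @return data.frame
#' @export
readProbeAnnotation <- function(path) {
  tab <- .readTsv(path)
  need <- c("probeSet", "chrom", "position")
  if (!all(need %in% colnames(tab)))
    stop("probe annotation needs: ", paste(need, collapse = ", "))
  dup <- tab$probeSet[duplicated(tab$probeSet)]
  if (length(dup)) stop("duplicate probe id(s): ",
                        paste(unique(dup), collapse = ", "))
  tab$chrom <- as.character(tab$chrom)
  if (all(c("nIdentified", "nPerfect", "nProbes") %in% colnames(tab))) {
    bad <- with(tab, nPerfect > nIdentified | nIdentified > nProbes |
                  nPerfect < 0)
    if (any(bad)) stop("probe count ordering violated for: ",
                       paste(head(tab$probeSet[bad], 3), collapse = ", "))
  }
  tab
}

#' Read strain genome composition
#'
#' One row per interval: \code{strain}, \code{chrom}, \code{start},
#' \code{end} (1-based inclusive bp), \code{zone} (donor/boundary),
#' \code{zygosity} (homozygous/heterozygous; optional, defaults to
#' homozygous). Donor intervals are validated for non-overlap within each
#' strain and chromosome. Host strains without donor material may simply be
#' absent from the file; \code{hostStrains} adds empty models for them.
#'
#' @param path TSV path
#' @param hostStrains strain names to add as empty (all-host) models
#' @return named list of \linkS4class{StrainModel}
#' @export
readStrainComposition <- function(path, hostStrains = character()) {
  tab <- .readTsv(path)
  need <- c("strain", "chrom", "start", "end", "zone")
  if (!all(need %in% colnames(tab)))
    stop("strain composition needs: ", paste(need, collapse = ", "))
  if (!"zygosity" %in% colnames(tab)) tab$zygosity <- "homozygous"
  if (!all(tab$zone %in% c("donor", "boundary")))
    stop("unknown zone label: ",
         paste(setdiff(unique(tab$zone), c("donor", "boundary")),
               collapse = ", "))
  if (any(tab$start > tab$end)) stop("interval with start > end")
  models <- lapply(split(tab, tab$strain), function(s)
    StrainModel(s$strain[1], s$chrom, s$start, s$end, s$zone, s$zygosity))
  for (h in hostStrains) models[[h]] <- StrainModel(h)
  models
}

#' @rdname readStrainComposition
#' @param strains named list of \linkS4class{StrainModel}
#' @export
writeStrainComposition <- function(strains, path) {
  rows <- do.call(rbind, lapply(strains, function(s) {
    r <- s@regions
    if (!length(r)) return(NULL)
    data.frame(strain = strainName(s),
               chrom = as.character(GenomicRanges::seqnames(r)),
               start = GenomicRanges::start(r), end = GenomicRanges::end(r),
               zone = S4Vectors::mcols(r)$zone,
               zygosity = S4Vectors::mcols(r)$zygosity,
               stringsAsFactors = FALSE)
  }))
  .writeTsv(rows, path)
  invisible(NULL)
}

#' Read and write backcross data
#'
#' Genotypes are CSV (first column progeny id, one column per marker,
#' values 0 / 1 / NA), the marker map is TSV (\code{marker}, \code{chrom},
#' \code{bp}, \code{cM}) and traits are CSV (first column progeny id).
#'
#' @param genoPath,mapPath,traitPath file paths
#' @return \code{readBackcross}: a \linkS4class{BackcrossData}
#' @export
readBackcross <- function(genoPath, mapPath, traitPath) {
  geno <- read.csv(genoPath, check.names = FALSE)
  g <- as.matrix(geno[, -1, drop = FALSE])
  if (!all(g[!is.na(g)] %in% c(0, 1)))
    stop("genotypes must be 0, 1 or NA")
  rownames(g) <- geno[[1]]
  map <- .readTsv(mapPath)
  tr <- read.csv(traitPath, check.names = FALSE)
  traits <- tr[, -1, drop = FALSE]
  rownames(traits) <- tr[[1]]
  if (!identical(rownames(g), rownames(traits)))
    stop("progeny ids differ between genotype and trait files")
  BackcrossData(g, map, traits)
}

#' @rdname readBackcross
#' @param data a \linkS4class{BackcrossData}
#' @export
writeBackcross <- function(data, genoPath, mapPath, traitPath) {
  g <- genotypes(data)
  write.csv(data.frame(progeny = rownames(g), g, check.names = FALSE),
            genoPath, row.names = FALSE, quote = FALSE)
  .writeTsv(markerMap(data), mapPath)
  tr <- traits(data)
  write.csv(data.frame(progeny = rownames(tr), tr, check.names = FALSE),
            traitPath, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Write a per-chromosome frequency table
#'
#' Percentages are written with exactly two decimals.
#'
#' @param freqTable output of \code{\link{chromFrequencyTable}}
#' @param path TSV path
#' @export
writeFrequencyTable <- function(freqTable, path) {
  out <- freqTable
  for (cc in c("upPct", "downPct")) out[[cc]] <- sprintf("%.2f", out[[cc]])
  .writeTsv(out, path)
  invisible(NULL)
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
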