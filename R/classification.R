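#' Compare two correlations by Fisher's z
#'
#' Tests whether the correlation of the substitution strain with the donor
#' exceeds its correlation with the host, treating the two correlations as
#' independent: \code{z_i = atanh(r_i)},
#' statistic \code{(z_donor - z_host) / sqrt(2/(n-3))}, one-sided normal
#' p-value for the alternative \code{r_donor > r_host}.
#'
#' @param rHost,rDonor Pearson correlations in (-1, 1)
#' @param n number of transcripts both correlations are computed over (>= 4)
#' @return data.frame row: \code{rHost}, \code{rDonor}, \code{n},
#'   \code{statistic}, \code{p}
#' @export
fisherZCompare <- function(rHost, rDonor, n) {
  stopifnot(n >= 4, abs(rHost) < 1, abs(rDonor) < 1)
  stat <- (atanh(rDonor) - atanh(rHost)) / sqrt(2 / (n - 3))
  data.frame(rHost = rHost, rDonor = rDonor, n = n, statistic = stat,
             p = pnorm(-stat))
}

#' Which parent does the substitution strain track?
#'
#' Correlates the substitution strain's expression with each parent over a
#' transcript subset (group means, log-transformed to approximate
#' normality) and compares the two correlations with
#' \code{\link{fisherZCompare}}. A significantly higher correlation with
#' the donor indicates that donor cis-regulatory elements drive the
#' expression differences.
#'
#' @param expr a \linkS4class{CSSExperiment}
#' @param css,host,donor strain names
#' @param subset probe set ids (or logical mask) defining the transcript
#'   subset, e.g. expressed donor-region transcripts; NULL = all
#' @param age restrict to this age; NULL = all samples per strain
#' @return data.frame row as in \code{\link{fisherZCompare}}
#' @export
correlationComparison <- function(expr, css, host, donor, subset = NULL,
                                  age = NULL) {
  if (!is.null(subset)) expr <- expr[subset, ]
  if (nrow(expr) < 4) stop("subset must contain >= 4 transcripts")
  mCss <- rowMeans(.groupLog2(expr, css, age))
  mHost <- rowMeans(.groupLog2(expr, host, age))
  mDonor <- rowMeans(.groupLog2(expr, donor, age))
  if (sd(mCss) == 0 || sd(mHost) == 0 || sd(mDonor) == 0)
    stop("zero variance in an expression vector")
  fisherZCompare(cor(mCss, mHost), cor(mCss, mDonor), length(mCss))
}

#' Classify misexpressed transcripts: cis-regulated vs incompatibility
#'
#' For each significant transcript (already restricted to the donor-derived
#' region), computes the linear expression ratio of the substitution strain
#' to the donor strain (ratio of replicate-mean linear intensities). A
#' transcript that converges to within the band (strictly
#' \code{1/band < ratio < band}) is classified \code{cis_regulated}: its
#' level simply follows the donor allele. A transcript outside the band
#' matches neither parent and is classified \code{incompatibility}:
#' misregulation from the donor cis-element meeting the host trans
#' environment. The summary reports the converged fraction separately for
#' up- and downregulated transcripts.
#'
#' @param calls DE call table restricted to the donor-derived region (only
#'   rows with \code{significant == TRUE} are typed)
#' @param expr a \linkS4class{CSSExperiment} containing both strains
#' @param css,donor strain names
#' @param age restrict to this age; NULL = all samples per strain
#' @param band convergence band half-width on the linear ratio scale
#'   (default 1.5; boundary ratios count as incompatibility)
#' @return list: \code{typing} (data.frame \code{probeSet},
#'   \code{direction}, \code{ratio}, \code{type}), \code{summary}
#'   (data.frame \code{direction}, \code{n}, \code{converged},
#'   \code{convergedPct} to 1 decimal)
#' @export
classifyRegulatoryType <- function(calls, expr, css, donor, age = NULL,
                                   band = 1.5) {
  stopifnot(band > 1)
  sig <- calls[calls$significant, , drop = FALSE]
  sub <- expr[sig$probeSet, ]
  cd <- SummarizedExperiment::colData(sub)
  pick <- function(strain) {
    sel <- cd$strain == strain
    if (!is.null(age)) sel <- sel & cd$age == age
    rowMeans(intensity(sub)[, sel, drop = FALSE])
  }
  mDonor <- pick(donor)
  if (any(mDonor == 0)) stop("zero donor mean intensity")
  ratio <- pick(css) / mDonor
  type <- ifelse(ratio > 1 / band & ratio < band, "cis_regulated",
                 "incompatibility")
  typing <- data.frame(probeSet = sig$probeSet, direction = sig$direction,
                       ratio = unname(ratio), type = type,
                       stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(c("up", "down"), function(d) {
    i <- typing$direction == d
    n <- sum(i); conv <- sum(typing$type[i] == "cis_regulated")
    data.frame(direction = d, n = n, converged = conv,
               convergedPct = if (n) round(100 * conv / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(typing = typing, summary = summary)
}

#' Overlap of two differential-expression sets
#'
#' Intersects the significant probe sets of two comparisons (e.g. the
#' sub-chromosomal substitution strain vs the whole-chromosome strain) and
#' reports the share of set B found in set A, plus the genomic breakdown of
#' the common set (distal X, proximal X, autosomes) when a split point is
#' given.
#'
#' @param callsA,callsB DE call tables over the same probe universe
#' @param xSplitBp optional bp breakpoint separating proximal from distal X
#' @return list: \code{nA}, \code{nB}, \code{nCommon}, \code{pctOfB}
#'   (percentage of B's significant set shared, 1 decimal),
#'   \code{breakdown} (data.frame \code{region}, \code{n}, \code{pct})
#' @export
overlapAnalysis <- function(callsA, callsB, xSplitBp = NULL) {
  if (!length(intersect(callsA$probeSet, callsB$probeSet)))
    stop("disjoint probe universes")
  sa <- callsA$probeSet[callsA$significant]
  sb <- callsB$probeSet[callsB$significant]
  common <- intersect(sa, sb)
  pct <- if (length(sb)) round(100 * length(common) / length(sb), 1) else 0
  ann <- callsA[match(common, callsA$probeSet), , drop = FALSE]
  region <- if (is.null(xSplitBp)) {
    ifelse(ann$chrom == "X", "X", "autosomes")
  } else {
    ifelse(ann$chrom != "X", "autosomes",
           ifelse(ann$position <= xSplitBp, "proX", "disX"))
  }
  breakdown <- if (length(common)) {
    n <- table(region)
    data.frame(region = names(n), n = as.integer(n),
               pct = round(100 * as.integer(n) / length(common), 1),
               stringsAsFactors = FALSE)
  } else {
    data.frame(region = character(), n = integer(), pct = numeric(),
               stringsAsFactors = FALSE)
  }
  list(nA = length(sa), nB = length(sb), nCommon = length(common),
       pctOfB = pct, breakdown = breakdown)
}
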