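#' Log2 fold changes between two strain groups
#'
#' Difference of mean log2 intensities, test minus reference, computed per
#' probe set over the replicates of each group.
#'
#' @param expr a \linkS4class{CSSExperiment}
#' @param test,ref strain names
#' @param age restrict to this age (days postpartum); NULL uses all samples
#' @return named numeric vector of log2 fold changes
#' @export
log2FoldChanges <- function(expr, test, ref, age = NULL) {
  a <- .groupLog2(expr, test, age)
  b <- .groupLog2(expr, ref, age)
  rowMeans(a) - rowMeans(b)
}

.groupLog2 <- function(expr, strain, age = NULL) {
  cd <- SummarizedExperiment::colData(expr)
  sel <- cd$strain == strain
  if (!is.null(age)) sel <- sel & cd$age == age
  if (!any(sel)) stop("no samples for strain ", strain)
  m <- intensity(expr)[, sel, drop = FALSE]
  if (any(m <= 0)) stop("non-positive intensity")
  log2(m)
}

# Newton solve of trigamma(y) = x, vectorised (moment matching needs it)
.trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif) / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Two-sample t-statistics on log2 intensities with per-gene variances
#' shrunk toward an ensemble prior. The pooled per-gene variance
#' \eqn{s_g^2} (df \eqn{d_g = n_1+n_2-2}) is combined with a prior
#' \eqn{(d_0, s_0^2)} into the posterior variance
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}; the moderated t
#' uses \eqn{\tilde s_g^2} and is referred to a t distribution with
#' \eqn{d_0 + d_g} degrees of freedom. The prior is estimated from the
#' ensemble of gene variances by moment matching on log variances (the log
#' of a scaled chi-square has known digamma/trigamma moments; the excess
#' spread of \code{log(s^2)} beyond \code{trigamma(dg/2)} determines
#' \eqn{d_0}). When the observed spread does not exceed the sampling spread,
#' \eqn{d_0 = \infty} and all genes share \eqn{s_0^2}.
#'
#' @param x,y numeric matrices of log2 intensities (genes x replicates) for
#'   the test and reference groups; >= 2 columns each
#' @param priorDf override the estimated prior df: 0 gives the ordinary
#'   pooled-variance two-sample t; Inf gives complete shrinkage
#' @return data.frame per gene: \code{log2FC}, \code{t}, \code{df},
#'   \code{p} (two-sided), \code{s2}, \code{s2Post}, with the estimated
#'   \code{priorDf} and \code{priorVar} as attributes
#' @export
moderatedT <- function(x, y, priorDf = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) < 2 || ncol(y) < 2)
    stop("need >= 2 replicates per group")
  if (nrow(x) != nrow(y)) stop("gene sets differ between groups")
  if (nrow(x) < 1) stop("zero genes")
  n1 <- ncol(x); n2 <- ncol(y)
  dg <- n1 + n2 - 2
  mx <- rowMeans(x); my <- rowMeans(y)
  ssx <- rowSums((x - mx)^2); ssy <- rowSums((y - my)^2)
  s2 <- (ssx + ssy) / dg
  est <- .fitVariancePrior(s2, dg)
  d0 <- if (is.null(priorDf)) est$priorDf else priorDf
  s02 <- est$priorVar
  s2Post <- if (is.infinite(d0)) rep(s02, length(s2))
            else if (d0 == 0) s2
            else (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(s2Post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se == 0, 0, (mx - my) / se)
  df <- d0 + dg
  p <- 2 * pt(-abs(tstat), df = df)
  out <- data.frame(log2FC = mx - my, t = tstat, df = df, p = p, s2 = s2,
                    s2Post = s2Post, row.names = rownames(x))
  attr(out, "priorDf") <- d0
  attr(out, "priorVar") <- s02
  out
}

.fitVariancePrior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2)
    return(list(priorDf = Inf, priorVar = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- var(z) - trigamma(dg / 2)
  if (evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond sampling noise: one shared variance,
    # estimated by the (unbiased) arithmetic mean
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(priorDf = d0, priorVar = s02)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR adjustment (via \code{stats::p.adjust}) with input
#' validation: adjusted p is \code{min_k>=rank (p_(k) m / k)}, capped at 1.
#'
#' @param p vector of p-values in [0, 1]
#' @return adjusted p-values, same order as input
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differential expression
#'
#' A transcript is significant iff its BH-adjusted p is below \code{alpha}
#' and its linear fold change is at least \code{fcThreshold} in either
#' direction (i.e. \code{|log2FC| >= log2(fcThreshold)}). Direction is the
#' sign of the log2 fold change for significant transcripts, "none"
#' otherwise.
#'
#' @param log2fc vector of log2 fold changes
#' @param adjP aligned vector of adjusted p-values
#' @param fcThreshold linear fold-change threshold (default 1.50)
#' @param alpha adjusted-p threshold (default 0.05)
#' @return data.frame: \code{direction}, \code{significant}
#' @export
callDE <- function(log2fc, adjP, fcThreshold = 1.5, alpha = 0.05) {
  if (length(log2fc) != length(adjP)) stop("length mismatch")
  sig <- adjP < alpha & abs(log2fc) >= log2(fcThreshold)
  data.frame(direction = ifelse(sig & log2fc > 0, "up",
                         ifelse(sig & log2fc < 0, "down", "none")),
             significant = sig, stringsAsFactors = FALSE)
}

#' Differential-expression test between two strains
#'
#' Convenience wrapper running the moderated t-test, BH adjustment and
#' fold-change calling for one strain pair at one age, over an optional
#' pre-filter mask (the filtered probe universe defines the BH family).
#'
#' @param expr a \linkS4class{CSSExperiment}
#' @param test,ref strain names
#' @param age age (days postpartum); NULL uses all samples per strain
#' @param mask logical vector over probe sets (TRUE = analyse); NULL = all
#' @param fcThreshold,alpha calling thresholds
#' @param priorDf see \code{\link{moderatedT}}
#' @return a DE call table (data.frame): \code{probeSet}, \code{chrom},
#'   \code{position}, \code{meanLog2Test}, \code{meanLog2Ref},
#'   \code{log2FC}, \code{t}, \code{df}, \code{p}, \code{adjP},
#'   \code{direction}, \code{significant}
#' @export
deTest <- function(expr, test, ref, age = NULL, mask = NULL,
                   fcThreshold = 1.5, alpha = 0.05, priorDf = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(expr))
  sub <- expr[mask, ]
  a <- .groupLog2(sub, test, age)
  b <- .groupLog2(sub, ref, age)
  mt <- moderatedT(a, b, priorDf = priorDf)
  adjP <- bhAdjust(mt$p)
  calls <- callDE(mt$log2FC, adjP, fcThreshold, alpha)
  rd <- SummarizedExperiment::rowData(sub)
  data.frame(probeSet = rownames(sub), chrom = as.character(rd$chrom),
             position = rd$position, meanLog2Test = rowMeans(a),
             meanLog2Ref = rowMeans(b), log2FC = mt$log2FC, t = mt$t,
             df = mt$df, p = mt$p, adjP = adjP,
             direction = calls$direction, significant = calls$significant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-chromosome frequency table of DE calls
#'
#' Counts expressed probe sets and significantly up-/downregulated
#' transcripts per chromosome, with percentages of the expressed count
#' rounded to two decimals. The X chromosome can be split at a breakpoint
#' into proximal ("proX", position <= split) and distal ("disX") rows,
#' matching analyses of strains carrying only the distal X.
#'
#' @param calls DE call table from \code{\link{deTest}} (needs \code{chrom},
#'   \code{position}, \code{direction}, \code{significant})
#' @param xSplitBp optional bp breakpoint splitting the X row
#' @return data.frame: \code{chrom}, \code{expressed}, \code{up},
#'   \code{upPct}, \code{down}, \code{downPct}
#' @export
chromFrequencyTable <- function(calls, xSplitBp = NULL) {
  chrom <- as.character(calls$chrom)
  if (any(is.na(chrom) | chrom == ""))
    stop("unknown chromosome in calls")
  if (!is.null(xSplitBp)) {
    isX <- chrom == "X"
    chrom[isX] <- ifelse(calls$position[isX] <= xSplitBp, "proX", "disX")
  }
  lev <- unique(chrom)
  auto <- lev[!lev %in% c("X", "proX", "disX")]
  lev <- c(auto[order(suppressWarnings(as.numeric(auto)), auto)],
           intersect(c("X", "proX", "disX"), lev))
  up <- calls$significant & calls$direction == "up"
  down <- calls$significant & calls$direction == "down"
  tab <- do.call(rbind, lapply(lev, function(ch) {
    i <- chrom == ch
    n <- sum(i)
    data.frame(chrom = ch, expressed = n, up = sum(up[i]),
               upPct = if (n) round(100 * sum(up[i]) / n, 2) else 0,
               down = sum(down[i]),
               downPct = if (n) round(100 * sum(down[i]) / n, 2) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

#' Frequency table from published counts
#'
#' Rebuilds the percentage columns of a per-chromosome frequency table from
#' its integer counts (expressed, up, down), using the same 2-decimal
#' convention as \code{\link{chromFrequencyTable}}. Useful for re-deriving
#' published summary percentages from printed count columns.
#'
#' @param counts data.frame with columns \code{chrom}, \code{expressed},
#'   \code{up}, \code{down}
#' @return data.frame in \code{\link{chromFrequencyTable}} layout
#' @export
frequencyTableFromCounts <- function(counts) {
  need <- c("chrom", "expressed", "up", "down")
  if (!all(need %in% colnames(counts)))
    stop("counts must contain: ", paste(need, collapse = ", "))
  if (any(counts$up + counts$down > counts$expressed))
    stop("up + down exceeds expressed")
  data.frame(chrom = as.character(counts$chrom),
             expressed = counts$expressed, up = counts$up,
             upPct = round(100 * counts$up / counts$expressed, 2),
             down = counts$down,
             downPct = round(100 * counts$down / counts$expressed, 2),
             stringsAsFactors = FALSE)
}

#' Aggregate the autosome rows of a frequency table
#'
#' Two aggregation conventions are provided. \code{"pooled"} sums counts
#' over autosomes and divides (percentage of all expressed autosomal probe
#' sets); \code{"meanPct"} averages the per-chromosome percentages
#' unweighted (each chromosome contributes equally regardless of its probe
#' count) -- the convention behind published whole-autosome summary
#' percentages accompanying such tables.
#'
#' @param freqTable output of \code{\link{chromFrequencyTable}}
#' @param method \code{"pooled"} or \code{"meanPct"}
#' @return one-row data.frame: \code{expressed}, \code{up}, \code{upPct},
#'   \code{down}, \code{downPct} (counts are NA for \code{"meanPct"})
#' @export
autosomeAggregate <- function(freqTable, method = c("pooled", "meanPct")) {
  method <- match.arg(method)
  a <- freqTable[!freqTable$chrom %in% c("X", "proX", "disX"), , drop = FALSE]
  if (!nrow(a)) stop("no autosome rows")
  if (method == "pooled") {
    data.frame(expressed = sum(a$expressed), up = sum(a$up),
               upPct = round(100 * sum(a$up) / sum(a$expressed), 2),
               down = sum(a$down),
               downPct = round(100 * sum(a$down) / sum(a$expressed), 2))
  } else {
    data.frame(expressed = sum(a$expressed), up = NA_integer_,
               upPct = round(mean(a$upPct), 2), down = NA_integer_,
               downPct = round(mean(a$downPct), 2))
  }
}
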