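#' PCA of sample expression profiles
#'
#' Principal components of the gene-centred log2 expression matrix, with
#' samples as observations. Scores are deterministic up to sign; signs are
#' fixed by making the first nonzero gene loading of each component
#' non-negative.
#'
#' @param expr a \linkS4class{CSSExperiment}
#' @param k number of components (default 3; must be <= samples - 1)
#' @return list with class \code{"PCAResult"}: \code{scores} (samples x k),
#'   \code{varPct} (percentage of variance per component),
#'   \code{rotation} (gene loadings)
#' @export
pcaSamples <- function(expr, k = 3L) {
  m <- log2(intensity(expr))
  if (k > ncol(m) - 1L) stop("k exceeds sample count - 1")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    nz <- which(abs(rot[, j]) > 1e-12)[1]
    if (!is.na(nz) && rot[nz, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  varPct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, varPct = varPct[seq_len(k)],
                 rotation = rot),
            class = "PCAResult")
}

#' Restored / non-restored typing of F1 individuals
#'
#' Assigns each F1 individual to the "restored" type when its first
#' principal component score is closer to the host-strain centroid than to
#' the substitution-strain centroid by more than \code{margin}; individuals
#' inside the dead band are conservatively called non-restored. Typing uses
#' PC1 only, where the host and misexpressing clusters separate.
#'
#' @param pca a \code{"PCAResult"} from \code{\link{pcaSamples}}
#' @param hostSamples,cssSamples sample names of the two reference clusters
#'   (>= 2 each)
#' @param f1Samples sample names to type
#' @param margin dead-band half-width in PC1 score units (default 0)
#' @return data.frame: \code{sample}, \code{pc1}, \code{distHost},
#'   \code{distCss}, \code{type}
#' @export
assignRestoration <- function(pca, hostSamples, cssSamples, f1Samples,
                              margin = 0) {
  stopifnot(length(hostSamples) >= 2, length(cssSamples) >= 2)
  pc1 <- pca$scores[, 1]
  ch <- mean(pc1[hostSamples]); cc <- mean(pc1[cssSamples])
  if (any(is.na(c(ch, cc)))) stop("unknown reference sample names")
  if (ch == cc) stop("degenerate centroids: host and CSS coincide on PC1")
  s <- pc1[f1Samples]
  dHost <- abs(s - ch); dCss <- abs(s - cc)
  data.frame(sample = f1Samples, pc1 = unname(s),
             distHost = unname(dHost), distCss = unname(dCss),
             type = ifelse(dHost < dCss - margin, "restored",
                           "non_restored"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top-k ranking of differentially expressed transcripts
#'
#' Ranks significant transcripts by absolute log2 fold change (ties broken
#' by adjusted p, then probe set id) and tabulates the fold changes of the
#' same transcripts in additional comparisons, e.g. to show that the
#' strongest misexpression shrinks toward zero in a restored strain.
#'
#' @param calls DE call table defining the ranking
#' @param k table size (default 50; truncated to the number of significant
#'   transcripts)
#' @param comparisonCalls named list of DE call tables; each contributes a
#'   log2FC column matched by probe set id
#' @return data.frame: \code{rank}, \code{probeSet}, \code{chrom},
#'   \code{position}, \code{log2FC}, one extra column per comparison
#' @export
topKTable <- function(calls, k = 50L, comparisonCalls = list()) {
  sig <- calls[calls$significant, , drop = FALSE]
  ord <- order(-abs(sig$log2FC), sig$adjP, sig$probeSet)
  sig <- sig[head(ord, k), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(sig)), probeSet = sig$probeSet,
                    chrom = sig$chrom, position = sig$position,
                    log2FC = sig$log2FC, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (nm in names(comparisonCalls)) {
    cc <- comparisonCalls[[nm]]
    out[[paste0("log2FC_", nm)]] <-
      cc$log2FC[match(out$probeSet, cc$probeSet)]
  }
  out
}
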