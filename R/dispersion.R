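#' Centre values within groups
#'
#' Subtracts each group's median (or mean) from its members, so that a
#' subsequent rank test compares pure scale (dispersion) rather than
#' location. Location-invariant: adding a constant to a whole group leaves
#' the output unchanged.
#'
#' @param values numeric vector
#' @param by grouping vector of the same length
#' @param center \code{"median"} (default) or \code{"mean"}
#' @return centred vector, original order
#' @export
centralize <- function(values, by, center = c("median", "mean")) {
  center <- match.arg(center)
  by <- as.character(by)
  if (length(values) != length(by)) stop("length mismatch")
  if (any(is.na(by)) || !length(values)) stop("empty or missing group")
  f <- if (center == "median") median else mean
  centers <- tapply(values, by, f)
  if (any(is.na(centers))) stop("empty group")
  as.numeric(values - centers[by])
}

#' Ansari-Bradley two-sample dispersion test
#'
#' Rank test for a difference in scale. Over the pooled sample of size N,
#' each observation receives the score \code{min(rank, N+1-rank)} (midranks
#' under ties, which generalises to \code{(N+1)/2 - |rank - (N+1)/2|}); the
#' statistic is the sum of scores in \code{x}. Small scores sit at the
#' extremes, so a more dispersed sample collects a smaller score sum. The
#' null distribution is computed exactly by full enumeration over all
#' assignments of the pooled scores when the smaller group has at most
#' \code{exactMaxN} members (ties included); otherwise a normal
#' approximation with tie-corrected variance is used. Two-sided p-values
#' throughout; no clamping beyond numeric underflow.
#'
#' @param x,y numeric vectors (combined length >= 4)
#' @param exactMaxN exact enumeration when \code{min(n_x, n_y)} is at most
#'   this (default 10); enumeration also requires at most \code{maxCombos}
#'   combinations
#' @param maxCombos upper bound on enumerated combinations (default 5e5)
#' @return data.frame row: \code{n1}, \code{n2}, \code{statistic}, \code{p},
#'   \code{method} ("exact" or "normal")
#' @examples
#' ansariBradley(c(1, 4), c(2, 3))  # statistic 2, exact p = 1/3
#' @export
ansariBradley <- function(x, y, exactMaxN = 10L, maxCombos = 5e5) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (N < 4 || n1 < 1 || n2 < 1) stop("combined sample too small")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical; dispersion test degenerate")
    return(data.frame(n1 = n1, n2 = n2, statistic = NA_real_, p = 1,
                      method = "degenerate", stringsAsFactors = FALSE))
  }
  r <- rank(pooled, ties.method = "average")
  a <- (N + 1) / 2 - abs(r - (N + 1) / 2)
  stat <- sum(a[seq_len(n1)])
  nmin <- min(n1, n2)
  useExact <- nmin <= exactMaxN && choose(N, nmin) <= maxCombos
  if (useExact) {
    sums <- utils::combn(N, nmin, FUN = function(i) sum(a[i]))
    tsmall <- if (n1 <= n2) stat else sum(a) - stat
    eps <- 1e-9
    pLo <- mean(sums <= tsmall + eps)
    pHi <- mean(sums >= tsmall - eps)
    p <- min(1, 2 * min(pLo, pHi))
    method <- "exact"
  } else {
    e <- n1 * mean(a)
    v <- n1 * n2 * (N * sum(a^2) - sum(a)^2) / (N^2 * (N - 1))
    if (v <= 0) {
      warning("zero variance of scores; dispersion test degenerate")
      return(data.frame(n1 = n1, n2 = n2, statistic = stat, p = 1,
                        method = "degenerate", stringsAsFactors = FALSE))
    }
    z <- (stat - e) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  data.frame(n1 = n1, n2 = n2, statistic = stat, p = p, method = method,
             stringsAsFactors = FALSE)
}

#' Dispersion tests stratified by expression level
#'
#' Compares fold-change dispersion between two groups of transcripts
#' (e.g. X-linked vs autosomal), overall and within raw-intensity bands, to
#' show that a dispersion difference is not an artefact of expression level.
#' Within each band the fold changes are centred per group
#' (\code{\link{centralize}}) and the Ansari-Bradley test is run. Bands in
#' which either group has fewer than 2 members are reported as skipped
#' (e.g. when one group simply has no highly expressed transcripts).
#'
#' @param log2fc vector of log2 fold changes
#' @param rawIntensity aligned vector of raw linear intensities (used for
#'   banding; typically the reference-strain mean)
#' @param groupLabels aligned two-level grouping vector
#' @param strata ascending band edges (default c(10, 100, 1000)): bands are
#'   (s1, s2], (s2, s3], (s3, Inf), plus an "all" row over every transcript
#' @param center see \code{\link{centralize}}
#' @param exactMaxN see \code{\link{ansariBradley}}
#' @return data.frame: \code{stratum}, \code{n1}, \code{n2},
#'   \code{statistic}, \code{p}, \code{skipped}
#' @export
stratifiedDispersion <- function(log2fc, rawIntensity, groupLabels,
                                 strata = c(10, 100, 1000),
                                 center = "median", exactMaxN = 10L) {
  if (is.unsorted(strata, strictly = TRUE)) stop("strata must be ascending")
  g <- as.character(groupLabels)
  lev <- unique(g)
  if (length(lev) != 2) stop("exactly two groups required")
  edges <- c(strata, Inf)
  bands <- c("all", paste0("(", edges[-length(edges)], ",", edges[-1], "]"))
  sel <- c(list(rep(TRUE, length(log2fc))),
           lapply(seq_len(length(edges) - 1), function(i)
             rawIntensity > edges[i] & rawIntensity <= edges[i + 1]))
  out <- do.call(rbind, lapply(seq_along(bands), function(i) {
    fc <- log2fc[sel[[i]]]; gb <- g[sel[[i]]]
    n1 <- sum(gb == lev[1]); n2 <- sum(gb == lev[2])
    if (n1 < 2 || n2 < 2)
      return(data.frame(stratum = bands[i], n1 = n1, n2 = n2,
                        statistic = NA_real_, p = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    cen <- centralize(fc, gb, center = center)
    ab <- ansariBradley(cen[gb == lev[1]], cen[gb == lev[2]],
                        exactMaxN = exactMaxN)
    data.frame(stratum = bands[i], n1 = n1, n2 = n2,
               statistic = ab$statistic, p = ab$p, skipped = FALSE,
               stringsAsFactors = FALSE)
  }))
  attr(out, "groups") <- lev
  out
}
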