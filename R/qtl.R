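#' Single-marker QTL scan
#'
#' Regresses the trait on the genotype at each marker and reports
#' \code{LOD = (n/2) log10(RSS0 / RSS1)}, where RSS0 is the residual sum of
#' squares of the intercept-only model and RSS1 that of the one-marker
#' model, over the progeny with a non-missing genotype at that marker.
#' Markers at which only one genotype class is observed get a missing LOD.
#'
#' @param data a \linkS4class{BackcrossData}
#' @param trait trait column name (default first column)
#' @return a \code{"LODProfile"} data.frame: \code{position} (bp),
#'   \code{cM}, \code{lod}; attributes \code{peakBp}, \code{peakLod}
#' @export
singleMarkerScan <- function(data, trait = NULL) {
  g <- genotypes(data); map <- markerMap(data)
  y <- .pickTrait(data, trait)
  if (nrow(g) < 10) stop("need >= 10 progeny")
  lod <- vapply(seq_len(ncol(g)), function(k) {
    ok <- !is.na(g[, k])
    if (!any(ok)) stop("all genotypes missing at marker ", map$marker[k])
    gk <- g[ok, k]; yk <- y[ok]
    if (length(unique(gk)) < 2) return(NA_real_)
    .lodFromRegression(yk, gk)
  }, numeric(1))
  .lodProfile(map$bp, map$cM, lod, marker = map$marker)
}

.pickTrait <- function(data, trait) {
  tr <- traits(data)
  if (is.null(trait)) trait <- colnames(tr)[1]
  if (!trait %in% colnames(tr)) stop("unknown trait: ", trait)
  tr[[trait]]
}

# LOD of trait ~ x vs intercept-only; x may be genotype or het probability
.lodFromRegression <- function(y, x) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  sxx <- sum((x - mean(x))^2)
  if (rss0 == 0 || sxx == 0) return(0)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  rss1 <- rss0 - sxy^2 / sxx
  if (rss1 <= 0) return(Inf)
  (n / 2) * log10(rss0 / rss1)
}

.lodProfile <- function(bp, cM, lod, marker = NULL) {
  out <- data.frame(position = bp, cM = cM, lod = lod)
  if (!is.null(marker)) out$marker <- marker
  peak <- which.max(out$lod)
  attr(out, "peakBp") <- out$position[peak]
  attr(out, "peakLod") <- out$lod[peak]
  class(out) <- c("LODProfile", "data.frame")
  out
}

#' Peak of a LOD profile
#'
#' @param profile a \code{"LODProfile"}
#' @return list: \code{positionBp}, \code{lod}
#' @export
lodPeak <- function(profile) {
  list(positionBp = attr(profile, "peakBp"),
       lod = attr(profile, "peakLod"))
}

# nearest informative (non-missing) marker index at-or-before / at-or-after
# each marker, per progeny; NA where none exists
.flankIndex <- function(g) {
  n <- nrow(g); m <- ncol(g)
  left <- matrix(NA_integer_, n, m)
  right <- matrix(NA_integer_, n, m)
  cur <- rep(NA_integer_, n)
  for (k in seq_len(m)) {
    cur[!is.na(g[, k])] <- k
    left[, k] <- cur
  }
  cur <- rep(NA_integer_, n)
  for (k in rev(seq_len(m))) {
    cur[!is.na(g[, k])] <- k
    right[, k] <- cur
  }
  list(left = left, right = right)
}

#' Haley-Knott interval mapping
#'
#' Scans a position grid along the chromosome (every \code{stepBp}, plus
#' all marker positions). At each position the probability that a progeny
#' is heterozygous is computed from the genotypes at the nearest
#' informative flanking markers via Haldane recombination fractions
#' (\code{\link{haldane}}) on the genetic map; progeny with only one
#' informative flank use that flank alone, progeny with none get 0.5.
#' The trait is regressed on the expected heterozygosity (Haley-Knott
#' regression) and \code{LOD = (n/2) log10(RSS0/RSS1)}. At a fully
#' genotyped marker the flanking recombination fraction is zero, the
#' expected heterozygosity equals the observed genotype, and the profile
#' coincides with the single-marker scan.
#'
#' @param data a \linkS4class{BackcrossData}
#' @param trait trait column name (default first column)
#' @param stepBp grid walk speed in bp (default 1e6, i.e. 1 Mb)
#' @return a \code{"LODProfile"} over the grid
#' @export
intervalMappingHK <- function(data, trait = NULL, stepBp = 1e6) {
  g <- genotypes(data); map <- markerMap(data)
  if (nrow(map) < 2) stop("need >= 2 mapped markers")
  y <- .pickTrait(data, trait)
  grid <- sort(unique(c(map$bp, seq(min(map$bp), max(map$bp), by = stepBp))))
  out <- sum(grid < min(map$bp) | grid > max(map$bp))
  if (out > 0) {
    warning("clipping ", out, " grid position(s) outside the marker span")
    grid <- grid[grid >= min(map$bp) & grid <= max(map$bp)]
  }
  cmGrid <- approx(map$bp, map$cM, xout = grid)$y
  fl <- .flankIndex(g)
  lod <- numeric(length(grid))
  for (i in seq_along(grid)) {
    k <- findInterval(grid[i], map$bp)
    li <- fl$left[, k]
    ri <- if (k < ncol(g)) fl$right[, k + 1L]
          else ifelse(grid[i] == map$bp[k], fl$right[, k], NA_integer_)
    # at an exact marker position the marker itself is its own left flank
    p <- .hetProbability(g, map$cM, cmGrid[i], li, ri)
    lod[i] <- .lodFromRegression(y, p)
  }
  .lodProfile(grid, cmGrid, lod)
}

# P(heterozygous at cmPos) per progeny from flanking genotypes
.hetProbability <- function(g, cmMarkers, cmPos, li, ri) {
  n <- nrow(g)
  p <- rep(0.5, n)
  gL <- ifelse(is.na(li), NA, g[cbind(seq_len(n), li)])
  gR <- ifelse(is.na(ri), NA, g[cbind(seq_len(n), ri)])
  rL <- haldane(pmax(cmPos - cmMarkers[li], 0))
  rR <- haldane(pmax(cmMarkers[ri] - cmPos, 0))
  both <- !is.na(gL) & !is.na(gR)
  a1 <- gL * (1 - rL) + (1 - gL) * rL          # P(het | left flank)
  b1 <- gR * (1 - rR) + (1 - gR) * rR          # P(right flank | het)
  b0 <- gR * rR + (1 - gR) * (1 - rR)          # P(right flank | hom)
  p[both] <- (a1 * b1 / (a1 * b1 + (1 - a1) * b0))[both]
  onlyL <- !is.na(gL) & is.na(gR)
  p[onlyL] <- a1[onlyL]
  onlyR <- is.na(gL) & !is.na(gR)
  a1R <- gR * (1 - rR) + (1 - gR) * rR
  p[onlyR] <- a1R[onlyR]
  p[is.nan(p)] <- 0.5  # contradictory flanks at zero genetic distance
  p
}

#' Permutation significance threshold for a QTL scan
#'
#' Permutes the trait across progeny, rescans, and records the maximum LOD
#' each time; the empirical \code{1 - alpha} quantile is the genome-wide
#' (here chromosome-wide) significance threshold.
#'
#' @param data a \linkS4class{BackcrossData}
#' @param trait trait column name
#' @param nPerm number of permutations (default 1000)
#' @param alpha significance level (default 0.05)
#' @param method \code{"single"} (default, fast) or \code{"hk"}
#' @param stepBp grid step for \code{method = "hk"}
#' @param seed integer seed
#' @return list: \code{threshold}, \code{maxLod} (the permutation maxima)
#' @export
permutationThreshold <- function(data, trait = NULL, nPerm = 1000L,
                                 alpha = 0.05, method = c("single", "hk"),
                                 stepBp = 1e6, seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  tr <- traits(data)
  if (is.null(trait)) trait <- colnames(tr)[1]
  maxLod <- vapply(seq_len(nPerm), function(i) {
    perm <- data
    perm@traits[[trait]] <- sample(tr[[trait]])
    prof <- if (method == "single") singleMarkerScan(perm, trait)
            else intervalMappingHK(perm, trait, stepBp)
    max(prof$lod, na.rm = TRUE)
  }, numeric(1))
  list(threshold = unname(quantile(maxLod, 1 - alpha)), maxLod = maxLod)
}
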