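# Independent oracles used by the tests. These deliberately share no code
# with the package: scores are derived from sorted positions, the BH rule is
# the textbook step-up formula, and null distributions come from explicit
# enumeration.

# Ansari-Bradley: exact two-sided p by enumerating every assignment of the
# pooled observations to group x (midrank scores computed from scratch).
abEnumerationOracle <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  # midranks without rank(): average position of equal values when sorted
  r <- vapply(pooled, function(v)
    mean(which(sort(pooled) == v)), numeric(1))
  scores <- pmin(r, N + 1 - r)
  # with midranks min(r, N+1-r) equals (N+1)/2 - |r - (N+1)/2|
  n1 <- length(x)
  obs <- sum(scores[seq_len(n1)])
  idx <- utils::combn(N, n1)
  sums <- apply(idx, 2, function(i) sum(scores[i]))
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= obs + eps), mean(sums >= obs - eps)))
}

# textbook BH step-up: p_(k) * m / k with monotone enforcement from the top
bhStepUpOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (k in (m - 1):1) adj[k] <- min(adj[k], adj[k + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# one-marker regression LOD from explicit residual sums of squares
lodOracle <- function(y, g) {
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(unlist(lapply(split(y, g), function(v) (v - mean(v))^2)))
  (length(y) / 2) * log10(rss0 / rss1)
}

# small expression study builders ------------------------------------------

tinyLayout <- function(nAutosomes = 2, genesPerChrom = 30, seed = 7) {
  generateGenome(nAutosomes, genesPerChrom, seed = seed)
}

# strain panel: host (empty), donor (everything), cssX (whole X donor)
tinyStrains <- function(lengthBp = 1.6e8, nAutosomes = 2) {
  chroms <- c(as.character(seq_len(nAutosomes)), "X")
  list(host = StrainModel("host"),
       donor = StrainModel("donor", chroms, rep(1, length(chroms)),
                           rep(lengthBp, length(chroms)),
                           rep("donor", length(chroms))),
       cssX = StrainModel("cssX", "X", 1, lengthBp, "donor"))
}

tinyStudy <- function(arch = NULL, seed = 7, noiseSd = 0.25, replicates = 3,
                      nAutosomes = 2, genesPerChrom = 30, ages = 5, ...) {
  layout <- tinyLayout(nAutosomes, genesPerChrom, seed = seed)
  if (is.null(arch))
    arch <- sampleArchitecture(layout, seed = seed, ...)
  strains <- tinyStrains(nAutosomes = nAutosomes)
  cfg <- simulationConfig(replicates = replicates, noiseSd = noiseSd,
                          ages = ages, seed = seed)
  list(layout = layout, arch = arch, strains = strains,
       expr = generateExpressionStudy(layout, arch, strains, cfg,
                                      host = "host", donor = "donor"))
}

# architecture with every gene in one chosen class
uniformArchitecture <- function(layout, class = "conserved", cisEffect = 0,
                                incompEffect = 0) {
  data.frame(gene = layout$genes$gene, class = class,
             cisEffect = cisEffect, incompEffect = incompEffect,
             stringsAsFactors = FALSE)
}
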