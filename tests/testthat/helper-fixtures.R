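# Shared study fixtures used across test files.

.parentStudy <- function(n = 300, reps = 6, noise = 0.3, cssFrom = "donor",
                         seed = 41) {
  set.seed(seed)
  base <- rnorm(n, 6, 1.5)
  donorShift <- rnorm(n, 0, 1)          # donor diverges gene-wise from host
  mk <- function(center) sapply(seq_len(reps), function(i)
    2 ^ (center + rnorm(n, 0, noise)))
  cssCenter <- if (cssFrom == "donor") base + donorShift else base
  m <- cbind(mk(base), mk(base + donorShift), mk(cssCenter))
  rownames(m) <- paste0("g", seq_len(n))
  colnames(m) <- paste0(rep(c("H", "D", "C"), each = reps), seq_len(reps))
  CSSExperiment(m,
                colData = data.frame(
                  strain = rep(c("host", "donor", "css"), each = reps),
                  age = 5, replicate = rep(seq_len(reps), 3),
                  row.names = colnames(m)),
                rowData = data.frame(chrom = "X",
                                     position = seq_len(n) * 1e5,
                                     row.names = rownames(m)))
}

.typingFixture <- function(ratios, directions) {
  n <- length(ratios)
  ids <- paste0("g", seq_len(n))
  donorRow <- 2 ^ rnorm(n, 6, 1)
  m <- cbind(matrix(rep(donorRow * ratios, 3), n),   # css replicates
             matrix(rep(donorRow, 3), n))            # donor replicates
  rownames(m) <- ids
  colnames(m) <- paste0("s", 1:6)
  expr <- CSSExperiment(
    m,
    colData = data.frame(strain = rep(c("css", "donor"), each = 3),
                         age = 5, replicate = rep(1:3, 2),
                         row.names = colnames(m)),
    rowData = data.frame(chrom = "X", position = seq_len(n),
                         row.names = ids))
  calls <- data.frame(probeSet = ids, chrom = "X", position = seq_len(n),
                      direction = directions,
                      significant = TRUE, stringsAsFactors = FALSE)
  list(expr = expr, calls = calls)
}

.pcaStudy <- function(n = 60, seed = 51) {
  set.seed(seed)
  base <- rnorm(n, 6, 1)
  groups <- rep(c("host", "css", "F1"), each = 3)
  shift <- c(host = 0, css = 2, F1 = 1)
  m <- sapply(seq_along(groups), function(j)
    2 ^ (base + shift[groups[j]] * (seq_len(n) <= 20) + rnorm(n, 0, 0.1)))
  rownames(m) <- paste0("g", seq_len(n))
  colnames(m) <- paste0(groups, rep(1:3, 3))
  CSSExperiment(m,
                colData = data.frame(strain = groups, age = 7,
                                     replicate = rep(1:3, 3),
                                     row.names = colnames(m)),
                rowData = data.frame(chrom = "X", position = seq_len(n),
                                     row.names = rownames(m)))
}
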