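# Independent brute-force oracles and deterministic fixtures used across the
# suite. The oracles deliberately enumerate instead of reusing the package's
# search strategy.

# Exhaustive enumeration of all order-statistic index pairs (both directions).
enumMedOr <- function(a, b) {
  best <- list(confidence = 0, direction = "up_in_A", i = NA, j = NA)
  for (dir in 1:2) {
    x <- if (dir == 1) a else b
    y <- if (dir == 1) b else a
    sx <- sort(x); sy <- sort(y)
    for (i in seq_along(sx)) for (j in seq_along(sy)) {
      if (sx[i] > sy[j]) {
        co <- pbinom(i - 1, length(x), 0.5, lower.tail = FALSE) *
          pbinom(j - 1, length(y), 0.5)
        if (co > best$confidence)
          best <- list(confidence = co,
                       direction = if (dir == 1) "up_in_A" else "up_in_B",
                       i = i, j = j)
      }
    }
  }
  best
}

# Brute-force threshold search: every cut on a fine grid spanning the values,
# counting misclassifications under the same on-threshold-is-NDS rule.
bruteThresholdErrors <- function(v, isDS, orientation) {
  cuts <- sort(unique(c(v - 1e-9, v + 1e-9, v, min(v) - 1, max(v) + 1)))
  min(vapply(cuts, function(t) {
    pred <- if (orientation == "ds_high") v > t else v < t
    sum(pred != isDS)
  }, integer(1)))
}

# Deterministic 44-sample fixture whose eight informative probes carry the
# published gene names, with aberration structure forcing exactly four pairs:
# DS09 tracks the non-responders on the first three pair markers and rejoins
# the responders only on the fourth, so the composite index separates the
# groups only once all four pairs are in.
makeNamedPairFixture <- function() {
  overNames <- c("PTCHD1", "LOC100506731", "SH2D1A", "TOX")
  underNames <- c("PDXDC2P", "NEURL4", "ENST00000478672", "H2AFJ")
  samples <- c(sprintf("DS%02d", 1:9), sprintf("ND%02d", 1:35))
  nS <- 44
  mat <- matrix(NA_real_, 0, nS, dimnames = list(NULL, samples))
  dsN <- 1:8; t <- 1:35
  addRow <- function(mat, name, vals)
    rbind(mat, matrix(vals, 1, nS, dimnames = list(name, samples)))
  for (k in 1:4) {                       # over: high in DS
    ds <- 100 * (1 + dsN / 100)
    ds9 <- if (k < 4) 0.5 else 1e6
    nds <- 1 * (1 + t / 100)
    if (k == 2) nds[23] <- 200
    if (k == 3) nds[23:24] <- c(200, 210)
    if (k == 4) nds[1:11] <- 200 + t[1:11]
    mat <- addRow(mat, overNames[k], c(ds, ds9, nds))
  }
  for (k in 1:4) {                       # under: high in NDS
    ds <- 1 * (1 + dsN / 100)
    ds9 <- if (k < 4) 500 else 1.0
    nds <- 100 * (1 + t / 100)
    if (k == 2) nds[25] <- 0.5
    if (k == 3) nds[25:26] <- c(0.5, 0.45)
    if (k == 4) nds[12:22] <- 0.5 + t[12:22] / 1000
    mat <- addRow(mat, underNames[k], c(ds, ds9, nds))
  }
  for (f in 1:20)                        # constant fillers: never screened in
    mat <- addRow(mat, sprintf("FILLER%02d", f), rep(50 + f, nS))
  labels <- stats::setNames(rep(c("DS", "NDS"), c(9, 35)), samples)
  list(exprs = mat, labels = labels, over = overNames, under = underNames)
}

# Small separating two-probe cohort: one probe shifted up and one down in DS.
makeSeparatingMatrix <- function(nDS = 9, nNDS = 35, nNull = 8, seed = 1) {
  set.seed(seed)
  n <- nDS + nNDS
  samples <- c(sprintf("DS%02d", seq_len(nDS)), sprintf("ND%02d", seq_len(nNNDS <- nNDS)))
  mat <- rbind(
    UP = c(runif(nDS, 100, 110), runif(nNDS, 1, 2)),
    DOWN = c(runif(nDS, 1, 2), runif(nNDS, 100, 110)),
    matrix(2^rnorm(nNull * n, 8, 1), nNull, n,
           dimnames = list(sprintf("NULL%02d", seq_len(nNull)), NULL))
  )
  colnames(mat) <- samples
  labels <- stats::setNames(rep(c("DS", "NDS"), c(nDS, nNDS)), samples)
  list(exprs = mat, labels = labels)
}

writeTempClinical <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
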