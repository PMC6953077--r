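test_that("the composite log-index is the log ratio of marker products", {
  mat <- matrix(c(4, 2, 9, 3), 4, 1,
                dimnames = list(c("O1", "U1", "O2", "U2"), "S1"))
  m1 <- methods::new("CompositeIndexModel",
                     pairs = data.frame(over = "O1", under = "U1",
                                        over_confidence = 1, under_confidence = 1),
                     stopConfidence = 0.995, achievedConfidence = 0.998,
                     thresholdLog = 0, orientation = "ds_high",
                     converged = TRUE, groupSizes = c(1L, 1L))
  expect_equal(computeIndex(m1, mat)$log_index, log(2))

  m2 <- methods::new("CompositeIndexModel",
                     pairs = data.frame(over = c("O1", "O2"), under = c("U1", "U2"),
                                        over_confidence = 1, under_confidence = 1),
                     stopConfidence = 0.995, achievedConfidence = 0.998,
                     thresholdLog = 0, orientation = "ds_high",
                     converged = TRUE, groupSizes = c(1L, 1L))
  expect_equal(computeIndex(m2, mat)$log_index, log(6))

  # rescaling an over-marker row adds log(c) to every sample
  mat2 <- cbind(mat, S2 = c(8, 1, 3, 27))
  base <- computeIndex(m2, mat2)$log_index
  mat2["O1", ] <- mat2["O1", ] * 7
  expect_equal(computeIndex(m2, mat2)$log_index, base + log(7))

  expect_error(computeIndex(m2, mat2[-1, , drop = FALSE]), "absent.*O1")
})

test_that("threshold fitting uses the separation midpoint and minimizes errors", {
  fit <- fitThreshold(c(10, 12, 1, 2), c("DS", "DS", "NDS", "NDS"))
  expect_equal(fit$threshold, 6)
  expect_equal(fit$errors, 0L)
  expect_equal(fit$orientation, "ds_high")

  # inverted orientation
  fit <- fitThreshold(c(1, 2, 10, 12), c("DS", "DS", "NDS", "NDS"))
  expect_equal(fit$orientation, "ds_low")
  expect_equal(fit$errors, 0L)

  # overlapping toy sets against an exhaustive-cut oracle
  fit <- fitThreshold(c(3, 1, 2, 0), c("DS", "DS", "NDS", "NDS"))
  expect_equal(fit$errors,
               bruteThresholdErrors(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE),
                                    fit$orientation))
  set.seed(14)
  for (r in 1:30) {
    nDS <- sample(2:6, 1); nNDS <- sample(2:8, 1)
    v <- c(rnorm(nDS, 1), rnorm(nNDS))
    lab <- rep(c("DS", "NDS"), c(nDS, nNDS))
    fit <- fitThreshold(v, lab)
    expect_equal(fit$errors, bruteThresholdErrors(v, lab == "DS", fit$orientation))
  }

  expect_error(fitThreshold(rep(2, 4), c("DS", "DS", "NDS", "NDS")),
               "identical")
})

test_that("a single separating pair converges at the group-size bound", {
  fx <- makeSeparatingMatrix(seed = 2)
  sc <- screenMarkers(fx$exprs, fx$labels)
  md <- selectPairs(sc, fx$exprs, fx$labels)
  expect_equal(nrow(indexPairs(md)), 1L)
  expect_equal(indexPairs(md)$over, "UP")
  expect_equal(indexPairs(md)$under, "DOWN")
  expect_equal(achievedConfidence(md), (1 - 2^-9) * (1 - 2^-35))
  expect_true(isConverged(md))
  expect_equal(unname(classifySamples(md, fx$exprs)),
               factor(fx$labels, levels = c("DS", "NDS")),
               ignore_attr = TRUE)
})

test_that("selection requires markers in both directions and never reuses one", {
  fx <- makeSeparatingMatrix(seed = 3)
  up.only <- fx$exprs[c("UP", "NULL01"), , drop = FALSE]
  sc <- screenMarkers(up.only, fx$labels)
  expect_error(selectPairs(sc, up.only, fx$labels), "up_in_NDS")

  nfx <- makeNamedPairFixture()
  md <- selectPairs(screenMarkers(nfx$exprs, nfx$labels), nfx$exprs, nfx$labels)
  ids <- c(indexPairs(md)$over, indexPairs(md)$under)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("classification is invariant to rescaling a marker row after refit", {
  fx <- makeSeparatingMatrix(seed = 8)
  run <- function(mat) {
    sc <- screenMarkers(mat, fx$labels)
    md <- selectPairs(sc, mat, fx$labels)
    classifySamples(md, mat)
  }
  base <- run(fx$exprs)
  scaled <- fx$exprs
  scaled["UP", ] <- scaled["UP", ] * 1000
  expect_equal(run(scaled), base)
})

test_that("column permutation permutes predictions; on-threshold samples are NDS", {
  fx <- makeSeparatingMatrix(seed = 5)
  sc <- screenMarkers(fx$exprs, fx$labels)
  md <- selectPairs(sc, fx$exprs, fx$labels)
  perm <- sample(ncol(fx$exprs))
  expect_equal(classifySamples(md, fx$exprs[, perm]),
               classifySamples(md, fx$exprs)[perm])

  # a sample sitting exactly on the cut goes to NDS: build a model whose
  # threshold is exactly zero and a sample whose log-index is exactly zero
  m0 <- methods::new("CompositeIndexModel",
                     pairs = data.frame(over = "UP", under = "DOWN",
                                        over_confidence = 1, under_confidence = 1),
                     stopConfidence = 0.995, achievedConfidence = 0.998,
                     thresholdLog = 0, orientation = "ds_high",
                     converged = TRUE, groupSizes = c(9L, 35L))
  onThr <- matrix(c(5, 5), 2, 1, dimnames = list(c("UP", "DOWN"), "X1"))
  expect_equal(as.character(classifySamples(m0, onThr)), "NDS")
})

test_that("the forced four-pair fixture reproduces the published pairing order", {
  fx <- makeNamedPairFixture()
  sc <- screenMarkers(fx$exprs, fx$labels)
  res <- screenResults(sc)
  expect_equal(res$marker[res$direction == "up_in_DS"], fx$over)
  expect_equal(res$marker[res$direction == "up_in_NDS"], fx$under)

  md <- selectPairs(sc, fx$exprs, fx$labels)
  expect_equal(nrow(indexPairs(md)), 4L)
  expect_equal(indexPairs(md)$over, fx$over)
  expect_equal(indexPairs(md)$under, fx$under)
  expect_true(isConverged(md))
  expect_equal(achievedConfidence(md), (1 - 2^-9) * (1 - 2^-35))
  expect_equal(sum(classifySamples(md, fx$exprs) != fx$labels), 0L)
})

test_that("a fitted model survives a JSON round trip", {
  fx <- makeNamedPairFixture()
  md <- selectPairs(screenMarkers(fx$exprs, fx$labels), fx$exprs, fx$labels)
  f <- tempfile(fileext = ".json")
  writeModel(md, f)
  back <- readModel(f)
  expect_equal(indexPairs(back), indexPairs(md))
  expect_equal(modelThreshold(back), modelThreshold(md))
  expect_equal(achievedConfidence(back), achievedConfidence(md))
  expect_equal(isConverged(back), isConverged(md))
  expect_equal(classifySamples(back, fx$exprs), classifySamples(md, fx$exprs))
})

test_that("model validity rejects inconsistent objects", {
  expect_error(methods::new("CompositeIndexModel",
                            pairs = data.frame(over = "A", under = "A",
                                               over_confidence = 1,
                                               under_confidence = 1),
                            stopConfidence = 0.995, achievedConfidence = 0.9,
                            thresholdLog = 0, orientation = "ds_high",
                            converged = FALSE, groupSizes = c(2L, 2L)),
               "distinct")
})
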