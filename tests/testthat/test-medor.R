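test_that("binomial upper tail is exact", {
  expect_equal(binomialUpperTail(9, 1), 1 - 2^-9)
  expect_equal(binomialUpperTail(4, 2), 11 / 16)
  expect_equal(binomialUpperTail(7, 0), 1)
  expect_equal(binomialUpperTail(5, 6), 0)
  expect_error(binomialUpperTail(5, -1), "non-negative")
  # against direct summation of binomial coefficients
  set.seed(5)
  for (r in 1:25) {
    n <- sample(1:40, 1); k <- sample(0:n, 1)
    expect_equal(binomialUpperTail(n, k), sum(choose(n, k:n)) / 2^n)
  }
})

test_that("elementary median-ordering statements are exact", {
  r <- medianOrderConfidence(2, 1)
  expect_equal(r$direction, "up_in_A")
  expect_equal(r$confidence, 0.25)
  expect_equal(c(r$i, r$j), c(1L, 1L))

  # complete reversal: no admissible pair for A, direction flips
  r <- medianOrderConfidence(c(1, 2), c(5, 6, 7))
  expect_equal(r$direction, "up_in_B")
  expect_gt(r$confidence, 0)

  # complete separation at the study group sizes attains the bound
  r <- medianOrderConfidence(100 + 1:9, 1:35)
  expect_equal(r$confidence, (1 - 2^-9) * (1 - 2^-35))
  expect_equal(r$direction, "up_in_A")

  expect_error(medianOrderConfidence(numeric(0), 1), "non-empty")
  expect_error(medianOrderConfidence(c(1, NA), 1), "finite")
})

test_that("the search over order-statistic pairs matches exhaustive enumeration", {
  set.seed(99)
  for (r in 1:100) {
    m <- sample(1:8, 1); n <- sample(1:8, 1)
    # rounded values so ties occur regularly
    a <- round(rnorm(m), 1); b <- round(rnorm(n), 1)
    got <- medianOrderConfidence(a, b)
    ref <- enumMedOr(a, b)
    expect_equal(got$confidence, ref$confidence)
    if (got$confidence > 0) expect_equal(got$direction, ref$direction)
  }
})

test_that("the statement is rank-invariant and respects its separation bound", {
  set.seed(21)
  for (r in 1:40) {
    m <- sample(2:12, 1); n <- sample(2:12, 1)
    a <- rnorm(m, 0.3); b <- rnorm(n)
    base <- medianOrderConfidence(a, b)
    for (f in list(exp, function(x) x^3, function(x) 10 * x + 4)) {
      tr <- medianOrderConfidence(f(a), f(b))
      expect_equal(tr$confidence, base$confidence)
      expect_equal(tr$direction, base$direction)
      expect_equal(c(tr$i, tr$j), c(base$i, base$j))
    }
    bound <- (1 - 2^-m) * (1 - 2^-n)
    expect_lte(base$confidence, bound)
    sep <- min(a) > max(b) || min(b) > max(a)
    expect_equal(base$confidence == bound, sep)
  }
})

test_that("shifting one sample upward never weakens its ordering claim", {
  confA <- function(a, b) {
    r <- medianOrderConfidence(a, b)
    if (r$direction == "up_in_A") r$confidence else -r$confidence
  }
  set.seed(33)
  for (r in 1:30) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1))
    c0 <- confA(a, b)
    for (shift in c(0.1, 1, 10))
      expect_gte(confA(a + shift, b), c0)
  }
})

test_that("marker screening matches a probe-by-probe reference loop", {
  set.seed(4)
  mat <- 2^matrix(rnorm(50 * 14, 8, 1), 50, 14,
                  dimnames = list(sprintf("P%02d", 1:50), sprintf("S%02d", 1:14)))
  labels <- setNames(rep(c("DS", "NDS"), c(5, 9)), colnames(mat))
  mat["P07", labels == "DS"] <- mat["P07", labels == "DS"] * 1e4
  sc <- screenMarkers(mat, labels, threshold = 0.5)
  res <- screenResults(sc)
  expect_equal(res$marker[1], "P07")
  expect_equal(res$direction[1], "up_in_DS")
  for (k in seq_len(nrow(res))) {
    ref <- medianOrderConfidence(mat[res$marker[k], labels == "DS"],
                                 mat[res$marker[k], labels == "NDS"])
    expect_equal(res$confidence[k], ref$confidence)
    expect_equal(res$direction[k],
                 ifelse(ref$direction == "up_in_A", "up_in_DS", "up_in_NDS"))
  }
  expect_true(all(diff(res$confidence) <= 0))
  expect_true(all(res$confidence > 0.5))
})

test_that("screening degenerate or mislabeled input fails loudly", {
  mat <- matrix(5, 3, 4, dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
  labels <- setNames(c("DS", "DS", "NDS", "NDS"), colnames(mat))
  expect_equal(length(screenMarkers(mat, labels)), 0L)  # constants never screen in

  expect_error(screenMarkers(mat, setNames(rep("DS", 4), colnames(mat))),
               "NDS group is empty")
  expect_error(screenMarkers(mat, setNames(c("DS", "NDS"), c("S1", "S9"))),
               "unknown sample")
  expect_error(screenMarkers(mat - 10, labels), "positive")
})
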