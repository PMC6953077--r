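#' Exact upper tail of the symmetric binomial
#'
#' P(X >= k) for X ~ Binomial(n, 1/2), computed exactly (no normal
#' approximation). This is the building block of the median-ordering
#' confidence statement: with a sample of size n, the probability that the
#' population median lies above the i-th order statistic is P(Bin(n,1/2) >= i).
#'
#' @param n number of trials (non-negative integer)
#' @param k threshold; any integer in \code{0..n+1}
#' @return P(Binomial(n, 1/2) >= k), a probability in [0, 1]
#' @examples
#' binomialUpperTail(9, 1)   # 1 - 2^-9
#' binomialUpperTail(4, 2)   # 11/16
#' @export
binomialUpperTail <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L, is.finite(n), is.finite(k))
  if (k < 0) stop("k must be non-negative")
  if (n < 0) stop("n must be non-negative")
  pbinom(k - 1, size = n, prob = 0.5, lower.tail = FALSE)
}

## Best confidence for Md(a) > Md(b) over admissible order-statistic pairs,
## vectorised over i. Returns confidence 0 with NA witness when no pair
## (i, j) with a_(i) > b_(j) exists.
.medorOneDirection <- function(a, b) {
  m <- length(a); n <- length(b)
  sa <- sort(a); sb <- sort(b)
  # j[i] = #{ b < a_(i) }: the largest admissible j for each i
  j <- findInterval(sa, sb, left.open = TRUE)
  Q <- pbinom(0:(m - 1L), m, 0.5, lower.tail = FALSE)  # P(Bin(m,1/2) >= i)
  R <- c(0, pbinom(0:(n - 1L), n, 0.5))                # P(Bin(n,1/2) <= j-1), j=0..n
  cand <- Q * R[j + 1L]
  best <- which.max(cand)
  if (cand[best] <= 0)
    list(confidence = 0, i = NA_integer_, j = NA_integer_)
  else
    list(confidence = cand[best], i = best, j = j[best])
}

#' Confidence statement for the ordering of two medians (MedOr)
#'
#' Given independent samples \code{a} (size m) and \code{b} (size n), computes
#' a nonparametric confidence that one population median exceeds the other.
#' The confidence supporting Md(a) > Md(b) is the maximum, over order-statistic
#' index pairs (i, j) with \code{a_(i) > b_(j)} (strict, ascending, 1-based),
#' of \code{P(Bin(m,1/2) >= i) * P(Bin(n,1/2) <= j-1)}: the event
#' \{Md(a) >= a_(i)\} and \{Md(b) <= b_(j)\} then forces the ordering. Both
#' directions are evaluated; the larger is reported with its direction, ties
#' broken toward \code{up_in_A}. Under complete separation
#' (\code{min(a) > max(b)}) the confidence attains its upper bound
#' \code{(1 - 2^-m) * (1 - 2^-n)}.
#'
#' The statement depends only on ranks: any strictly increasing transform of
#' the pooled values leaves it unchanged. Equal values are never taken as
#' evidence of a strict ordering.
#'
#' @param a,b numeric vectors, each of length >= 1, all values finite
#' @return a list with elements \code{direction} (\code{"up_in_A"} or
#'   \code{"up_in_B"}), \code{confidence} in [0, 1], and the witness indices
#'   \code{i}, \code{j} (order statistics of the claimed-higher and
#'   claimed-lower sample; \code{NA} when confidence is 0)
#' @examples
#' medianOrderConfidence(c(2), c(1))          # confidence 0.25
#' medianOrderConfidence(rnorm(9, 5), rnorm(35))  # near the separation bound
#' @export
medianOrderConfidence <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("samples must be non-empty")
  if (!is.numeric(a) || !is.numeric(b) || !all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite numeric vectors")
  fwd <- .medorOneDirection(a, b)
  bwd <- .medorOneDirection(b, a)
  if (fwd$confidence >= bwd$confidence)
    list(direction = "up_in_A", confidence = fwd$confidence, i = fwd$i, j = fwd$j)
  else
    list(direction = "up_in_B", confidence = bwd$confidence, i = bwd$i, j = bwd$j)
}

## Coerce an expression input (matrix or SummarizedExperiment) to a checked
## positive matrix with unique dimnames.
.exprsMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix or a SummarizedExperiment")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (any(!is.finite(x))) stop("expression values must be finite")
  if (any(x <= 0)) stop("expression values must be positive (linear scale)")
  x
}

## Normalise a label spec against sample ids: accepts a named vector or a
## vector in column order; returns a DS/NDS factor aligned to `samples`.
.alignLabels <- function(labels, samples) {
  labels <- setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    unknown <- setdiff(names(labels), samples)
    if (length(unknown))
      stop("label(s) for unknown sample id: ", paste(unknown, collapse = ", "))
    labels <- labels[match(samples, names(labels))]
  } else if (length(labels) != length(samples)) {
    stop("need one label per sample (", length(samples), "), got ", length(labels))
  }
  if (anyNA(labels)) stop("every sample must be labeled")
  bad <- setdiff(unique(labels), c("DS", "NDS"))
  if (length(bad)) stop("labels must be DS or NDS; got: ", paste(bad, collapse = ", "))
  factor(labels, levels = c("DS", "NDS"))
}

#' Screen every marker for a median difference between DS and NDS samples
#'
#' Applies [medianOrderConfidence()] probe by probe, comparing DS against NDS
#' columns, and retains markers whose confidence statement strictly exceeds
#' \code{threshold}. Screening is two-sided: markers up in either group are
#' retained, with the direction recorded. The result is sorted by decreasing
#' confidence, ties broken by probe id, so the ordering is deterministic.
#'
#' @param x probes-by-samples matrix of positive linear-scale intensities,
#'   or a \code{SummarizedExperiment} whose first assay is such a matrix
#' @param labels per-sample \code{"DS"}/\code{"NDS"} labels: a vector in
#'   column order, or a named vector keyed by sample id. If \code{x} is a
#'   \code{SummarizedExperiment} and \code{labels} is missing, the
#'   \code{response} column of \code{colData(x)} is used.
#' @param threshold minimum confidence for retention (default 0.95)
#' @return a [MedOrScreen-class] object
#' @export
screenMarkers <- function(x, labels = NULL, threshold = 0.95) {
  if (is.null(labels) && methods::is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if (!"response" %in% names(cd))
      stop("no labels given and colData has no 'response' column")
    labels <- setNames(as.character(cd$response), colnames(x))
  }
  mat <- .exprsMatrix(x)
  lab <- .alignLabels(labels, colnames(mat))
  ds <- which(lab == "DS"); nds <- which(lab == "NDS")
  if (length(ds) == 0L) stop("DS group is empty")
  if (length(nds) == 0L) stop("NDS group is empty")
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 1)

  res <- vector("list", nrow(mat))
  for (p in seq_len(nrow(mat))) {
    r <- medianOrderConfidence(mat[p, ds], mat[p, nds])
    res[[p]] <- c(r$confidence, r$direction == "up_in_A", r$i, r$j)
  }
  res <- do.call(rbind, res)
  keep <- which(res[, 1L] > threshold)
  out <- data.frame(
    marker = rownames(mat)[keep],
    direction = ifelse(res[keep, 2L] == 1, "up_in_DS", "up_in_NDS"),
    confidence = res[keep, 1L],
    i = as.integer(res[keep, 3L]),
    j = as.integer(res[keep, 4L]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$confidence, out$marker), , drop = FALSE]
  rownames(out) <- NULL
  methods::new("MedOrScreen", results = out, threshold = threshold,
               groupSizes = c(length(ds), length(nds)))
}
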