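#' Per-sample composite log-index of a marker-pair model
#'
#' The composite index of a sample is the product of its over-marker
#' intensities divided by the product of its under-marker intensities.
#' It is computed and returned on the natural-log scale,
#' \code{sum over pairs of [ln x(over, s) - ln x(under, s)]}, which is
#' monotone-equivalent to the ratio of products and numerically safe for
#' positive intensities.
#'
#' @param model a [CompositeIndexModel-class]
#' @param x expression matrix or \code{SummarizedExperiment} (positive values)
#' @return a \code{data.frame} with columns \code{sample_id} and
#'   \code{log_index}, in the matrix's column order
#' @export
computeIndex <- function(model, x) {
  stopifnot(methods::is(model, "CompositeIndexModel"))
  mat <- .exprsMatrix(x)
  need <- c(model@pairs$over, model@pairs$under)
  absent <- setdiff(need, rownames(mat))
  if (length(absent))
    stop("marker(s) absent from expression matrix: ",
         paste(absent, collapse = ", "))
  lx <- log(mat)
  over <- lx[model@pairs$over, , drop = FALSE]
  under <- lx[model@pairs$under, , drop = FALSE]
  data.frame(sample_id = colnames(mat),
             log_index = colSums(over) - colSums(under),
             stringsAsFactors = FALSE)
}

#' Fit a classification threshold on the log-index scale
#'
#' Records the orientation (which side of the cut is DS) from the group
#' medians. If the groups are completely separated on the log-index, the
#' threshold is the midpoint of the gap between them; otherwise every
#' midpoint between adjacent distinct index values (plus cuts below and
#' above all values) is scanned and the cut minimizing training
#' misclassifications is chosen, ties broken toward the lower cut.
#' Samples exactly on the threshold classify as NDS.
#'
#' @param index a \code{data.frame} from [computeIndex()], or a numeric
#'   vector of log-index values (named by sample or in label order)
#' @param labels DS/NDS labels, one per sample (vector or named vector)
#' @return a list: \code{threshold}, \code{orientation} (\code{"ds_high"} /
#'   \code{"ds_low"}), \code{errors} (training misclassification count)
#' @export
fitThreshold <- function(index, labels) {
  if (is.data.frame(index)) {
    v <- setNames(index$log_index, index$sample_id)
  } else v <- index
  if (!is.null(names(v)) && !is.null(names(labels))) {
    lab <- .alignLabels(labels, names(v))
  } else {
    stopifnot(length(labels) == length(v))
    lab <- .alignLabels(unname(labels), as.character(seq_along(v)))
  }
  ds <- v[lab == "DS"]; nds <- v[lab == "NDS"]
  if (length(ds) == 0L || length(nds) == 0L) stop("both groups must be non-empty")
  if (length(unique(v)) == 1L)
    stop("all index values identical: no separating threshold exists")

  orientation <- if (median(ds) >= median(nds)) "ds_high" else "ds_low"
  hi <- if (orientation == "ds_high") ds else nds
  lo <- if (orientation == "ds_high") nds else ds
  if (min(hi) > max(lo)) {
    thr <- (max(lo) + min(hi)) / 2
    return(list(threshold = thr, orientation = orientation, errors = 0L))
  }
  u <- sort(unique(v))
  cand <- c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)] + 1)
  errs <- vapply(cand, function(t) {
    pred.ds <- if (orientation == "ds_high") v > t else v < t
    sum(pred.ds != (lab == "DS"))
  }, integer(1))
  best <- which.min(errs)   # which.min takes the first (lowest cut) on ties
  list(threshold = cand[best], orientation = orientation,
       errors = errs[best])
}

#' Greedy sequential selection of over/under marker pairs
#'
#' Builds the composite classification index one marker pair at a time.
#' The k-th pair joins the k-th highest-confidence unused marker
#' overexpressed in DS with the k-th highest-confidence unused marker
#' overexpressed in NDS. After each addition the per-sample log-index is
#' recomputed and the confidence statement that the DS median index exceeds
#' the NDS median is evaluated; selection stops when it reaches
#' \code{stopConfidence}, when either direction's markers are exhausted, or
#' at \code{maxPairs}. Non-convergence is reported via the model's
#' \code{converged} flag, not an error. A classification threshold is then
#' fitted on the final index ([fitThreshold()]).
#'
#' @param screen a [MedOrScreen-class] from [screenMarkers()]
#' @param x expression matrix or \code{SummarizedExperiment}
#' @param labels DS/NDS labels per sample (as in [screenMarkers()])
#' @param stopConfidence stop once the index confidence reaches this
#'   (default 0.995); must lie in (0, 1)
#' @param maxPairs hard cap on the number of pairs (default 10)
#' @return a fitted [CompositeIndexModel-class]
#' @export
selectPairs <- function(screen, x, labels, stopConfidence = 0.995,
                        maxPairs = 10L) {
  stopifnot(methods::is(screen, "MedOrScreen"))
  stopifnot(length(stopConfidence) == 1L,
            stopConfidence > 0, stopConfidence < 1)
  stopifnot(maxPairs >= 1L)
  mat <- .exprsMatrix(x)
  lab <- .alignLabels(labels, colnames(mat))
  res <- screen@results
  ups <- res[res$direction == "up_in_DS", , drop = FALSE]
  downs <- res[res$direction == "up_in_NDS", , drop = FALSE]
  if (nrow(ups) == 0L)
    stop("no marker overexpressed in DS (direction up_in_DS) in the screen")
  if (nrow(downs) == 0L)
    stop("no marker overexpressed in NDS (direction up_in_NDS) in the screen")
  absent <- setdiff(c(ups$marker, downs$marker), rownames(mat))
  if (length(absent))
    stop("screened marker(s) absent from expression matrix: ",
         paste(absent, collapse = ", "))

  dsIdx <- which(lab == "DS"); ndsIdx <- which(lab == "NDS")
  lx <- log(mat)
  kmax <- min(nrow(ups), nrow(downs), maxPairs)
  logIndex <- numeric(ncol(mat))
  achieved <- 0
  used <- 0L
  for (k in seq_len(kmax)) {
    logIndex <- logIndex + lx[ups$marker[k], ] - lx[downs$marker[k], ]
    used <- k
    achieved <- .medorOneDirection(logIndex[dsIdx], logIndex[ndsIdx])$confidence
    if (achieved >= stopConfidence) break
  }
  pairs <- data.frame(
    over = ups$marker[seq_len(used)],
    under = downs$marker[seq_len(used)],
    over_confidence = ups$confidence[seq_len(used)],
    under_confidence = downs$confidence[seq_len(used)],
    stringsAsFactors = FALSE
  )
  fit <- fitThreshold(setNames(logIndex, colnames(mat)),
                      setNames(as.character(lab), colnames(mat)))
  methods::new("CompositeIndexModel",
               pairs = pairs,
               stopConfidence = stopConfidence,
               achievedConfidence = achieved,
               thresholdLog = fit$threshold,
               orientation = fit$orientation,
               converged = achieved >= stopConfidence,
               groupSizes = c(length(dsIdx), length(ndsIdx)))
}

#' Classify samples with a fitted marker-pair model
#'
#' Computes the composite log-index of each sample and labels it by which
#' side of the model threshold it falls, using the recorded orientation.
#' A sample exactly on the threshold is assigned NDS (conservative toward
#' not over-calling response).
#'
#' @param model a fitted [CompositeIndexModel-class]
#' @param x expression matrix or \code{SummarizedExperiment}
#' @return a factor of \code{DS}/\code{NDS} labels named by sample id
#' @export
classifySamples <- function(model, x) {
  idx <- computeIndex(model, x)
  v <- idx$log_index
  pred.ds <- if (model@orientation == "ds_high") v > model@thresholdLog
             else v < model@thresholdLog
  setNames(factor(ifelse(pred.ds, "DS", "NDS"), levels = c("DS", "NDS")),
           idx$sample_id)
}

#' Serialize / restore a marker-pair model as JSON
#'
#' @param model a [CompositeIndexModel-class]
#' @param path output (input) file path
#' @return \code{writeModel}: \code{path}, invisibly. \code{readModel}:
#'   the restored \code{CompositeIndexModel}.
#' @export
writeModel <- function(model, path) {
  stopifnot(methods::is(model, "CompositeIndexModel"))
  obj <- list(
    pairs = model@pairs,
    stop_confidence = model@stopConfidence,
    achieved_confidence = model@achievedConfidence,
    threshold_log = model@thresholdLog,
    orientation = model@orientation,
    converged = model@converged,
    group_sizes = list(ds = model@groupSizes[1L], nds = model@groupSizes[2L])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("CompositeIndexModel",
               pairs = as.data.frame(obj$pairs, stringsAsFactors = FALSE),
               stopConfidence = obj$stop_confidence,
               achievedConfidence = obj$achieved_confidence,
               thresholdLog = obj$threshold_log,
               orientation = obj$orientation,
               converged = obj$converged,
               groupSizes = c(as.integer(obj$group_sizes$ds),
                              as.integer(obj$group_sizes$nds)))
}

#' Plot per-sample composite index with the classification threshold
#'
#' One point per sample on the log-index scale, colored by its DS/NDS label,
#' with the fitted threshold drawn as a horizontal red line.
#'
#' @param model a fitted [CompositeIndexModel-class]
#' @param x expression matrix or \code{SummarizedExperiment}
#' @param labels DS/NDS labels per sample
#' @param ... further arguments passed to \code{plot}
#' @return the index \code{data.frame}, invisibly
#' @importFrom graphics abline legend points
#' @export
plotIndex <- function(model, x, labels, ...) {
  idx <- computeIndex(model, x)
  lab <- .alignLabels(labels, idx$sample_id)
  ord <- order(lab, idx$log_index)
  col <- ifelse(lab[ord] == "DS", "#D62728", "#1F77B4")
  plot(seq_along(ord), idx$log_index[ord], pch = 19, col = col,
       xlab = "sample", ylab = "log composite index", ...)
  abline(h = model@thresholdLog, col = "red", lwd = 2)
  legend("topleft", legend = c("DS", "NDS"), col = c("#D62728", "#1F77B4"),
         pch = 19, bty = "n")
  invisible(idx)
}
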