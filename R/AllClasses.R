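#' @import methods
#' @importFrom stats pbinom median rnorm sd setNames
#' @importFrom utils read.csv read.delim write.csv head
NULL

#' MedOrScreen: per-marker median-ordering screen result
#'
#' Holds the outcome of screening every probe of an expression matrix for a
#' difference in group medians between downstaging (DS) and non-downstaging
#' (NDS) samples. Each retained marker carries the direction of the claimed
#' ordering, the confidence statement supporting it, and the order-statistic
#' witness pair achieving the maximum.
#'
#' @slot results a \code{data.frame} with columns \code{marker},
#'   \code{direction} (\code{"up_in_DS"} / \code{"up_in_NDS"}),
#'   \code{confidence}, \code{i}, \code{j}; sorted by decreasing confidence,
#'   ties broken by marker id.
#' @slot threshold the screening threshold: only markers with confidence
#'   strictly above it are retained.
#' @slot groupSizes integer vector \code{c(m, n)}: number of DS and NDS
#'   samples screened.
#'
#' @seealso [screenMarkers()], [medianOrderConfidence()]
#' @export
setClass("MedOrScreen",
  representation(
    results = "data.frame",
    threshold = "numeric",
    groupSizes = "integer"
  )
)

setValidity("MedOrScreen", function(object) {
  msgs <- character()
  req <- c("marker", "direction", "confidence", "i", "j")
  if (!all(req %in% names(object@results)))
    msgs <- c(msgs, paste("results must have columns:", paste(req, collapse = ", ")))
  if (length(object@threshold) != 1L ||
      object@threshold < 0 || object@threshold > 1)
    msgs <- c(msgs, "threshold must be a single number in [0, 1]")
  if (nrow(object@results) > 0) {
    if (anyDuplicated(object@results$marker))
      msgs <- c(msgs, "duplicate marker ids in results")
    if (!all(object@results$direction %in% c("up_in_DS", "up_in_NDS")))
      msgs <- c(msgs, "direction must be up_in_DS or up_in_NDS")
    if (any(object@results$confidence <= object@threshold))
      msgs <- c(msgs, "all retained confidences must exceed the threshold")
    if (is.unsorted(rev(object@results$confidence)))
      msgs <- c(msgs, "results must be sorted by decreasing confidence")
  }
  if (length(object@groupSizes) != 2L || any(object@groupSizes < 1L))
    msgs <- c(msgs, "groupSizes must be two positive integers")
  if (length(msgs)) msgs else TRUE
})

#' CompositeIndexModel: fitted over/under marker-pair classifier
#'
#' The model produced by greedy sequential pair selection: an ordered list of
#' (over, under) marker pairs, the confidence statement achieved by the
#' composite index they define, a classification threshold on the log-index
#' scale, and its orientation.
#'
#' @slot pairs a \code{data.frame} with columns \code{over}, \code{under},
#'   \code{over_confidence}, \code{under_confidence}; row k is the k-th pair
#'   added.
#' @slot stopConfidence the confidence at which pair addition stops.
#' @slot achievedConfidence confidence that the DS median log-index exceeds
#'   the NDS median, for the final index.
#' @slot thresholdLog classification cut on the log-index scale.
#' @slot orientation \code{"ds_high"} if DS samples lie above the threshold,
#'   \code{"ds_low"} otherwise (recorded from the group medians).
#' @slot converged whether \code{achievedConfidence >= stopConfidence}.
#' @slot groupSizes integer \code{c(m, n)}: DS and NDS training group sizes.
#'
#' @seealso [selectPairs()], [computeIndex()], [classifySamples()]
#' @export
setClass("CompositeIndexModel",
  representation(
    pairs = "data.frame",
    stopConfidence = "numeric",
    achievedConfidence = "numeric",
    thresholdLog = "numeric",
    orientation = "character",
    converged = "logical",
    groupSizes = "integer"
  )
)

setValidity("CompositeIndexModel", function(object) {
  msgs <- character()
  req <- c("over", "under", "over_confidence", "under_confidence")
  if (!all(req %in% names(object@pairs)))
    msgs <- c(msgs, paste("pairs must have columns:", paste(req, collapse = ", ")))
  if (nrow(object@pairs) < 1L)
    msgs <- c(msgs, "model must contain at least one pair")
  ids <- c(object@pairs$over, object@pairs$under)
  if (anyDuplicated(ids))
    msgs <- c(msgs, "marker ids must be distinct across all pairs")
  if (length(object@stopConfidence) != 1L ||
      object@stopConfidence <= 0 || object@stopConfidence >= 1)
    msgs <- c(msgs, "stopConfidence must be in (0, 1)")
  if (!object@orientation %in% c("ds_high", "ds_low"))
    msgs <- c(msgs, "orientation must be ds_high or ds_low")
  if (length(object@converged) == 1L && length(object@achievedConfidence) == 1L &&
      object@converged != (object@achievedConfidence >= object@stopConfidence))
    msgs <- c(msgs, "converged flag inconsistent with achievedConfidence")
  if (length(msgs)) msgs else TRUE
})
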