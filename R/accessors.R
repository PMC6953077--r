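#' @rdname MedOrScreen-class
#' @param object,x a \code{MedOrScreen}
#' @export
setGeneric("screenResults", function(object) standardGeneric("screenResults"))

#' @rdname MedOrScreen-class
#' @export
setMethod("screenResults", "MedOrScreen", function(object) object@results)

#' @rdname MedOrScreen-class
#' @export
setGeneric("screenThreshold", function(object) standardGeneric("screenThreshold"))

#' @rdname MedOrScreen-class
#' @export
setMethod("screenThreshold", "MedOrScreen", function(object) object@threshold)

#' @rdname MedOrScreen-class
#' @export
setMethod("length", "MedOrScreen", function(x) nrow(x@results))

setMethod("show", "MedOrScreen", function(object) {
  cat("MedOrScreen:", nrow(object@results), "marker(s) with confidence >",
      object@threshold, "\n")
  cat("  group sizes: DS =", object@groupSizes[1L],
      ", NDS =", object@groupSizes[2L], "\n")
  n.up <- sum(object@results$direction == "up_in_DS")
  cat("  up in DS:", n.up, " up in NDS:", nrow(object@results) - n.up, "\n")
  if (nrow(object@results) > 0) {
    cat("  top markers:\n")
    print(head(object@results, 5L), row.names = FALSE)
  }
})

#' @rdname CompositeIndexModel-class
#' @param object a \code{CompositeIndexModel}
#' @export
setGeneric("indexPairs", function(object) standardGeneric("indexPairs"))

#' @rdname CompositeIndexModel-class
#' @export
setMethod("indexPairs", "CompositeIndexModel", function(object) object@pairs)

#' @rdname CompositeIndexModel-class
#' @export
setGeneric("achievedConfidence",
           function(object) standardGeneric("achievedConfidence"))

#' @rdname CompositeIndexModel-class
#' @export
setMethod("achievedConfidence", "CompositeIndexModel",
          function(object) object@achievedConfidence)

#' @rdname CompositeIndexModel-class
#' @export
setGeneric("modelThreshold", function(object) standardGeneric("modelThreshold"))

#' @rdname CompositeIndexModel-class
#' @export
setMethod("modelThreshold", "CompositeIndexModel",
          function(object) object@thresholdLog)

#' @rdname CompositeIndexModel-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname CompositeIndexModel-class
#' @export
setMethod("isConverged", "CompositeIndexModel", function(object) object@converged)

setMethod("show", "CompositeIndexModel", function(object) {
  cat("CompositeIndexModel with", nrow(object@pairs), "over/under pair(s)\n")
  print(object@pairs, row.names = FALSE)
  cat(sprintf("  achieved confidence: %.4f (stop at %.4f) — %s\n",
              object@achievedConfidence, object@stopConfidence,
              if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  log-index threshold: %.4f (DS %s threshold)\n",
              object@thresholdLog,
              if (object@orientation == "ds_high") "above" else "below"))
})
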