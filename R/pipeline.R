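#' Read an expression matrix from TSV
#'
#' First column: probe id; header row: sample ids; values: positive
#' linear-scale intensities. With \code{log2 = TRUE} the file holds log2
#' values, which are exponentiated on load so all downstream computation
#' sees the linear scale.
#'
#' @param path TSV file path
#' @param log2 whether the stored values are log2-transformed
#' @return a numeric probes-by-samples matrix
#' @export
readExpressionMatrix <- function(path, log2 = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  if (log2) mat <- 2^mat
  .exprsMatrix(mat)
}

#' Write an expression matrix as TSV
#' @param x matrix or \code{SummarizedExperiment}
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeExpressionMatrix <- function(x, path) {
  mat <- .exprsMatrix(x)
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-sample DS/NDS labels (TSV: sample_id, label)
#' @param path file path
#' @return \code{readLabels}: a named character vector of labels
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "label") %in% names(df)))
  setNames(df$label, df$sample_id)
}

#' @rdname readLabels
#' @param labels a named DS/NDS vector
#' @importFrom utils write.table
#' @export
writeLabels <- function(labels, path) {
  write.table(data.frame(sample_id = names(labels),
                         label = as.character(labels)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full response-classification pipeline
#'
#' End to end: derive DS/NDS labels (directly, or from a clinical table via
#' the downstaging rule), screen all markers with the median-ordering
#' confidence statement, select over/under marker pairs greedily into a
#' composite index, fit the classification threshold, and classify the
#' training samples. Returns a structured report; optionally writes the
#' model (JSON), per-sample index (TSV), and report (JSON) to \code{outDir}.
#' Non-convergence of pair selection raises a warning, not an error.
#'
#' @param expression matrix, \code{SummarizedExperiment}, or TSV path
#' @param labels named DS/NDS vector or labels-TSV path; ignored when
#'   \code{clinical} is given
#' @param clinical optional clinical table (\code{data.frame} or CSV/TSV
#'   path); labels are derived with [classifyResponse()], matching
#'   \code{patient_id} to expression sample ids
#' @param screenThreshold marker-retention confidence (default 0.95)
#' @param stopConfidence pair-selection stop confidence (default 0.995)
#' @param maxPairs cap on selected pairs (default 10)
#' @param log2 whether an expression TSV stores log2 values
#' @param outDir optional output directory (created if absent)
#' @param seed optional integer recorded in the report's provenance (the
#'   pipeline itself is deterministic)
#' @return a list of class \code{RunReport}: \code{cohort_summary} (or
#'   \code{NULL}), \code{screen_size}, \code{model} (pairs, achieved
#'   confidence, threshold, convergence), \code{confusion} (training counts,
#'   summing to n), and \code{provenance}
#' @export
runPipeline <- function(expression, labels = NULL, clinical = NULL,
                        screenThreshold = 0.95, stopConfidence = 0.995,
                        maxPairs = 10L, log2 = FALSE, outDir = NULL,
                        seed = NULL) {
  if (is.character(expression))
    expression <- readExpressionMatrix(expression, log2 = log2)
  mat <- .exprsMatrix(expression)

  cohortSummary <- NULL
  if (!is.null(clinical)) {
    tab <- if (is.character(clinical)) readClinicalTable(clinical) else clinical
    cohortSummary <- summarizeCohort(tab)
    cl <- classifyResponse(tab)
    labels <- setNames(as.character(cl$label), cl$patient_id)
  } else if (is.character(labels) && length(labels) == 1L &&
             is.null(names(labels))) {
    labels <- readLabels(labels)
  }
  if (is.null(labels)) stop("either labels or a clinical table is required")
  lab <- .alignLabels(labels, colnames(mat))

  screen <- screenMarkers(mat, setNames(as.character(lab), colnames(mat)),
                          threshold = screenThreshold)
  model <- selectPairs(screen, mat, setNames(as.character(lab), colnames(mat)),
                       stopConfidence = stopConfidence, maxPairs = maxPairs)
  if (!isConverged(model))
    warning(sprintf(
      "pair selection stopped at %d pair(s) with confidence %.4f < %.4f",
      nrow(indexPairs(model)), achievedConfidence(model), stopConfidence))
  idx <- computeIndex(model, mat)
  pred <- classifySamples(model, mat)
  confusion <- c(
    ds_correct = sum(pred == "DS" & lab == "DS"),
    ds_missed = sum(pred == "NDS" & lab == "DS"),
    nds_correct = sum(pred == "NDS" & lab == "NDS"),
    nds_missed = sum(pred == "DS" & lab == "NDS")
  )
  report <- list(
    cohort_summary = if (is.null(cohortSummary)) NULL else unclass(cohortSummary),
    screen_size = length(screen),
    model = list(
      pairs = indexPairs(model),
      achieved_confidence = achievedConfidence(model),
      stop_confidence = stopConfidence,
      threshold_log = modelThreshold(model),
      converged = isConverged(model)
    ),
    confusion = as.list(confusion),
    provenance = list(
      seed = seed,
      screen_threshold = screenThreshold,
      stop_confidence = stopConfidence,
      max_pairs = maxPairs,
      n_probes = nrow(mat),
      n_samples = ncol(mat),
      package_version = as.character(utils::packageVersion("stromaMedOr"))
    )
  )
  class(report) <- "RunReport"
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeModel(model, file.path(outDir, "model.json"))
    write.table(idx, file.path(outDir, "index.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(unclass(report), file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  attr(report, "model") <- model
  attr(report, "index") <- idx
  report
}

#' @export
print.RunReport <- function(x, ...) {
  if (!is.null(x$cohort_summary))
    cat(sprintf("cohort: n=%d, DS=%d, pCR=%d\n", x$cohort_summary$n,
                x$cohort_summary$n_ds, x$cohort_summary$n_pcr))
  cat(sprintf("screen: %d marker(s) retained\n", x$screen_size))
  cat(sprintf("model: %d pair(s), confidence %.4f, %s\n",
              nrow(x$model$pairs), x$model$achieved_confidence,
              if (x$model$converged) "converged" else "NOT converged"))
  cf <- x$confusion
  cat(sprintf("training errors: %d of %d\n",
              cf$ds_missed + cf$nds_missed,
              cf$ds_correct + cf$ds_missed + cf$nds_correct + cf$nds_missed))
  invisible(x)
}
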