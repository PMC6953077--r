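## Post-therapy pathological T-stage vocabulary, in increasing order of
## residual disease. T1 without a suffix (unspecified) sorts above T1c.
.YPT_LEVELS <- c("T0", "Tis", "T1mi", "T1a", "T1b", "T1c", "T1", "T2", "T3", "T4")
.YPN_LEVELS <- c("N0", "N1", "N2", "N3", "Nx")

.HISTOLOGY_LEVELS <- c("ductal", "lobular", "mixed", "other", "in_situ_component")

.stripYp <- function(tok) sub("^\\s*[yY][pP]\\s*", "", trimws(tok))

## Parse one ypT (and optionally combined ypTN) token; returns c(ypt, ypn-or-NA).
.parseStaging <- function(tok, row) {
  s <- .stripYp(tok)
  pat <- "^(T0|Tis|T1mi|T1a|T1b|T1c|T1|T2|T3|T4)((N0|N1|N2|N3|Nx))?$"
  m <- regexec(pat, s, ignore.case = FALSE)
  g <- regmatches(s, m)[[1]]
  if (length(g) == 0L)
    stop("row ", row, ": unknown ypT/ypN token '", tok, "'")
  c(g[2L], if (nzchar(g[3L])) g[3L] else NA_character_)
}

.parseYpn <- function(tok, row) {
  s <- .stripYp(tok)
  if (!s %in% .YPN_LEVELS)
    stop("row ", row, ": unknown ypN token '", tok, "'")
  s
}

#' Read a clinical cohort table
#'
#' Parses a delimited text file (CSV or TSV, sniffed from the header line)
#' whose header names the clinical record fields: \code{patient_id},
#' \code{age_group} (\code{le40}/\code{gt40}), \code{histology}, \code{er},
#' \code{pr}, \code{her2} (\code{pos}/\code{neg}/\code{nd}), \code{ki67_pct}
#' (may be empty: missing, not zero), \code{tdim_pre_cm}, \code{tdim_post_cm},
#' and pathological staging either as separate \code{ypt}/\code{ypn} columns
#' or a combined \code{yptn} column (tokens accepted with or without the
#' \code{yp} prefix, e.g. \code{ypT2N0} or \code{T2N0}).
#'
#' @param path path to the file
#' @return a \code{data.frame}, one row per patient, with \code{ypt} an
#'   ordered factor over \code{T0 < Tis < T1mi < T1a < T1b < T1c <
#'   T1 < T2 < T3 < T4} and \code{ypn} a factor; row order preserved
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character", strip.white = TRUE)
  if (nrow(df) == 0L) {
    df$ypt <- factor(character(), levels = .YPT_LEVELS, ordered = TRUE)
    df$ypn <- factor(character(), levels = .YPN_LEVELS)
    return(df)
  }
  need <- c("patient_id", "er")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))

  if ("yptn" %in% names(df)) {
    st <- t(vapply(seq_len(nrow(df)),
                   function(r) .parseStaging(df$yptn[r], r), character(2)))
    ypt <- st[, 1L]; ypn <- st[, 2L]
    if (anyNA(ypn)) stop("row ", which(is.na(ypn))[1L], ": ypN missing from combined token")
  } else if (all(c("ypt", "ypn") %in% names(df))) {
    ypt <- vapply(seq_len(nrow(df)),
                  function(r) .parseStaging(df$ypt[r], r)[1L], character(1))
    ypn <- vapply(seq_len(nrow(df)), function(r) .parseYpn(df$ypn[r], r), character(1))
  } else stop("staging columns not found: need 'yptn' or both 'ypt' and 'ypn'")
  df$ypt <- factor(ypt, levels = .YPT_LEVELS, ordered = TRUE)
  df$ypn <- factor(ypn, levels = .YPN_LEVELS)

  for (col in c("er", "pr")) if (col %in% names(df)) {
    bad <- setdiff(unique(df[[col]]), c("pos", "neg"))
    if (length(bad)) stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "))
  }
  if ("her2" %in% names(df)) {
    bad <- setdiff(unique(df$her2), c("pos", "neg", "nd"))
    if (length(bad)) stop("invalid her2 value(s): ", paste(bad, collapse = ", "))
  }
  if ("histology" %in% names(df)) {
    bad <- setdiff(unique(df$histology), .HISTOLOGY_LEVELS)
    if (length(bad)) stop("invalid histology value(s): ", paste(bad, collapse = ", "))
  }
  if ("age_group" %in% names(df)) {
    bad <- setdiff(unique(df$age_group), c("le40", "gt40"))
    if (length(bad)) stop("invalid age_group value(s): ", paste(bad, collapse = ", "))
  }
  for (col in c("ki67_pct", "tdim_pre_cm", "tdim_post_cm")) if (col %in% names(df)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    blank <- !nzchar(trimws(df[[col]])) | toupper(trimws(df[[col]])) == "NA"
    if (any(is.na(v) & !blank))
      stop("non-numeric ", col, " at row ", which(is.na(v) & !blank)[1L])
    df[[col]] <- v
  }
  if ("ki67_pct" %in% names(df) &&
      any(!is.na(df$ki67_pct) & (df$ki67_pct < 0 | df$ki67_pct > 100)))
    stop("ki67_pct must lie in [0, 100]")
  for (col in c("tdim_pre_cm", "tdim_post_cm")) if (col %in% names(df) &&
      any(!is.na(df[[col]]) & df[[col]] < 0))
    stop(col, " must be non-negative")
  df
}

#' Derive response labels from pathological staging
#'
#' A tumor is classified as downstaging (\code{DS}) when residual disease
#' after neoadjuvant chemotherapy is at most ypT1a-b with ypN0 — that is,
#' ypT no worse than T1b in the stage ordering, and node-negative.
#' Pathological complete response (pCR) additionally requires no residual
#' invasive disease: ypT0 or ypTis, with ypN0. \code{Nx} (nodes not
#' assessable) is treated conservatively as not N0. pCR always implies DS.
#'
#' @param table a clinical table from [readClinicalTable()], or any
#'   \code{data.frame} with \code{ypt} (character or factor over the stage
#'   vocabulary) and \code{ypn} columns
#' @return \code{table} with two columns appended: \code{label} (factor
#'   \code{DS}/\code{NDS}) and \code{pcr} (logical)
#' @examples
#' classifyResponse(data.frame(ypt = "T0", ypn = "N0"))     # DS, pCR
#' classifyResponse(data.frame(ypt = "T1c", ypn = "N0"))    # NDS
#' @export
classifyResponse <- function(table) {
  stopifnot(is.data.frame(table), all(c("ypt", "ypn") %in% names(table)))
  ypt <- as.character(table$ypt); ypn <- as.character(table$ypn)
  bad <- setdiff(unique(ypt), .YPT_LEVELS)
  if (length(bad)) stop("unknown ypT token: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ypn), .YPN_LEVELS)
  if (length(bad)) stop("unknown ypN token: ", paste(bad, collapse = ", "))
  rank <- match(ypt, .YPT_LEVELS)
  ds <- rank <= match("T1b", .YPT_LEVELS) & ypn == "N0"
  pcr <- ypt %in% c("T0", "Tis") & ypn == "N0"
  table$label <- factor(ifelse(ds, "DS", "NDS"), levels = c("DS", "NDS"))
  table$pcr <- pcr
  table
}

#' Summarize a clinical cohort
#'
#' Counts and continuous summaries of a parsed cohort table: sample size,
#' response and pCR counts, ER status split, and mean/sd (n-1 denominator)
#' of pre- and post-chemotherapy tumor dimension. Values are not rounded;
#' rounding belongs to presentation.
#'
#' @param table a table from [readClinicalTable()]
#' @return a named list (class \code{CohortSummary}): \code{n}, \code{n_ds},
#'   \code{n_nds}, \code{n_pcr}, \code{n_er_pos}, \code{n_er_neg},
#'   \code{mean_tdim_pre}, \code{sd_tdim_pre}, \code{mean_tdim_post},
#'   \code{sd_tdim_post} (sd is \code{NA} for a single record)
#' @export
summarizeCohort <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("cohort table is empty")
  cl <- classifyResponse(table)
  s <- list(
    n = nrow(table),
    n_ds = sum(cl$label == "DS"),
    n_nds = sum(cl$label == "NDS"),
    n_pcr = sum(cl$pcr),
    n_er_pos = sum(table$er == "pos"),
    n_er_neg = sum(table$er == "neg"),
    mean_tdim_pre = mean(table$tdim_pre_cm),
    sd_tdim_pre = if (nrow(table) > 1L) sd(table$tdim_pre_cm) else NA_real_,
    mean_tdim_post = mean(table$tdim_post_cm),
    sd_tdim_post = if (nrow(table) > 1L) sd(table$tdim_post_cm) else NA_real_
  )
  class(s) <- "CohortSummary"
  s
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients: %d downstaging (%d pCR), %d NDS\n",
              x$n, x$n_ds, x$n_pcr, x$n_nds))
  cat(sprintf("  ER status: %d positive / %d negative\n", x$n_er_pos, x$n_er_neg))
  cat(sprintf("  tumor dimension pre-CT:  %.1f cm (sd %.1f)\n",
              x$mean_tdim_pre, x$sd_tdim_pre))
  cat(sprintf("  tumor dimension post-CT: %.1f cm (sd %.1f)\n",
              x$mean_tdim_post, x$sd_tdim_post))
  invisible(x)
}

#' Path to the packaged 44-patient cohort fixture
#'
#' The clinical characteristics table of the 44-patient locally advanced
#' breast cancer cohort (age group, histology, ER/PR/HER2, Ki67, tumor
#' dimensions pre/post chemotherapy, and ypTN staging), shipped as CSV.
#'
#' @return path to the CSV file
#' @export
cohortFixturePath <- function() {
  system.file("extdata", "cohort_table1.csv", package = "stromaMedOr",
              mustWork = TRUE)
}

#' Summarize the packaged cohort fixture
#'
#' Convenience wrapper: parse the packaged cohort table and summarize it.
#' @return a \code{CohortSummary}; see [summarizeCohort()]
#' @export
summarizeFixture <- function() {
  summarizeCohort(readClinicalTable(cohortFixturePath()))
}

#' Write a cohort summary as JSON
#' @param summary a \code{CohortSummary}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeCohortSummary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
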