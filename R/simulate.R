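## Truncated normal via inverse-CDF: deterministic given the RNG stream.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate a two-group microarray expression cohort with planted markers
#'
#' Generates a probes-by-samples matrix of positive linear-scale intensities
#' emulating a normalized two-channel microarray cohort. Intensities are
#' lognormal: \code{2^(baseline + group effect + noise)} with per-probe
#' baselines \code{N(baselineLog2Mean, baselineLog2Sd)} and iid
#' \code{N(0, noiseSdLog2)} noise on the log2 scale. A configurable set of
#' planted probes receives a location shift of \code{+effectLog2} (planted
#' up) or \code{-effectLog2} (planted down) in the DS group only, so that
#' "group medians differ" is exactly the property the median-ordering screen
#' detects. Defaults mirror the study cohort: 9 downstaging and 35
#' non-downstaging samples.
#'
#' @param nProbes number of probes
#' @param nDS,nNDS group sizes (defaults 9 and 35)
#' @param nPlantedUp,nPlantedDown number of probes shifted up / down in DS
#' @param effectLog2 planted median shift in log2 units (default 3,
#'   i.e. 8-fold)
#' @param noiseSdLog2 noise standard deviation, log2 units (default 1)
#' @param baselineLog2Mean,baselineLog2Sd per-probe baseline distribution on
#'   the log2 scale (defaults 8 and 2, spanning typical array intensities)
#' @param seed integer seed; the output is reproducible given the seed
#' @param probeNames optional character vector of probe ids (length
#'   \code{nProbes}); planted probes are taken from its head, up markers
#'   first
#' @return a \code{SummarizedExperiment}: assay \code{exprs} (positive
#'   linear-scale matrix), \code{colData$response} holding DS/NDS labels,
#'   \code{rowData$planted} in \code{\{"up","down","none"\}}, and
#'   \code{metadata(se)$truth} listing \code{planted_up}, \code{planted_down},
#'   \code{effect_log2}
#' @importFrom stats pnorm qnorm runif
#' @export
simulateExpression <- function(nProbes = 1000L, nDS = 9L, nNDS = 35L,
                               nPlantedUp = 1L, nPlantedDown = 1L,
                               effectLog2 = 3, noiseSdLog2 = 1,
                               baselineLog2Mean = 8, baselineLog2Sd = 2,
                               seed = NULL, probeNames = NULL) {
  if (nDS < 1L || nNDS < 1L) stop("group sizes must be >= 1")
  if (nPlantedUp + nPlantedDown > nProbes)
    stop("planted probe count exceeds nProbes")
  if (noiseSdLog2 <= 0) stop("noiseSdLog2 must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- nDS + nNDS
  if (is.null(probeNames)) {
    probeNames <- sprintf("P%05d", seq_len(nProbes))
  } else stopifnot(length(probeNames) == nProbes, !anyDuplicated(probeNames))
  samples <- c(sprintf("DS%02d", seq_len(nDS)), sprintf("NDS%02d", seq_len(nNDS)))
  labels <- factor(rep(c("DS", "NDS"), c(nDS, nNDS)), levels = c("DS", "NDS"))

  up <- probeNames[seq_len(nPlantedUp)]
  down <- probeNames[nPlantedUp + seq_len(nPlantedDown)]
  baseline <- rnorm(nProbes, baselineLog2Mean, baselineLog2Sd)
  log2mat <- matrix(baseline, nProbes, n) +
    matrix(rnorm(nProbes * n, 0, noiseSdLog2), nProbes, n)
  dsCols <- which(labels == "DS")
  log2mat[match(up, probeNames), dsCols] <-
    log2mat[match(up, probeNames), dsCols] + effectLog2
  log2mat[match(down, probeNames), dsCols] <-
    log2mat[match(down, probeNames), dsCols] - effectLog2
  mat <- 2^log2mat
  dimnames(mat) <- list(probeNames, samples)

  planted <- rep("none", nProbes)
  planted[match(up, probeNames)] <- "up"
  planted[match(down, probeNames)] <- "down"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(response = labels, row.names = samples),
    rowData = S4Vectors::DataFrame(planted = planted, row.names = probeNames)
  )
  S4Vectors::metadata(se)$truth <- list(planted_up = up, planted_down = down,
                                        effect_log2 = effectLog2)
  se
}

#' Simulate a clinical cohort table
#'
#' Generates a cohort table with the schema of the packaged fixture, with
#' staging drawn so that exactly \code{nDS} records satisfy the downstaging
#' rule (ypT at most T1b with ypN0) and the remainder do not. ER status
#' follows the study's 29/15 split in expectation; tumor dimensions are
#' drawn from truncated normals spanning the ranges seen in the cohort
#' (pre-chemotherapy around 7 cm, post-chemotherapy smaller in responders).
#'
#' @param n cohort size (default 44)
#' @param nDS number of downstaging records (default 9)
#' @param seed integer seed; same seed, same table
#' @return a \code{data.frame} in the parsed clinical-table layout
#'   (including \code{ypt}/\code{ypn} factors)
#' @export
simulateClinical <- function(n = 44L, nDS = 9L, seed = NULL) {
  if (nDS > n) stop("nDS exceeds cohort size")
  if (!is.null(seed)) set.seed(seed)
  dsT <- c("T0", "Tis", "T1mi", "T1a", "T1b")
  ndsT <- c("T1c", "T1", "T2", "T3", "T4")
  ypt <- ypn <- character(n)
  isDS <- seq_len(n) <= nDS
  ypt[isDS] <- sample(dsT, nDS, replace = TRUE)
  ypn[isDS] <- "N0"
  nN <- n - nDS
  if (nN > 0) {
    # a non-responder fails the rule by T-stage, by nodes, or both
    mode <- sample(c("t", "n", "tn"), nN, replace = TRUE, prob = c(.4, .2, .4))
    ypt[!isDS] <- ifelse(mode == "n", sample(dsT, nN, replace = TRUE),
                         sample(ndsT, nN, replace = TRUE))
    ypn[!isDS] <- ifelse(mode == "t", "N0",
                         sample(c("N1", "N2", "N3", "Nx"), nN, replace = TRUE,
                                prob = c(.3, .35, .25, .1)))
  }
  preDim <- round(.rtruncnorm(n, 7.0, 2.0, 3, 15), 1)
  postDim <- numeric(n)
  postDim[isDS] <- round(.rtruncnorm(nDS, 0.8, 0.8, 0, 2.5), 1)
  if (nN > 0) postDim[!isDS] <- round(.rtruncnorm(nN, 5.0, 3.0, 0, 18), 1)
  df <- data.frame(
    patient_id = sprintf("S%03d", seq_len(n)),
    age_group = sample(c("le40", "gt40"), n, TRUE, prob = c(.35, .65)),
    histology = sample(.HISTOLOGY_LEVELS, n, TRUE,
                       prob = c(.85, .07, .04, .02, .02)),
    er = sample(c("pos", "neg"), n, TRUE, prob = c(29, 15) / 44),
    pr = sample(c("pos", "neg"), n, TRUE),
    her2 = sample(c("pos", "neg", "nd"), n, TRUE, prob = c(.25, .7, .05)),
    ki67_pct = ifelse(runif(n) < .2, NA_real_,
                      round(.rtruncnorm(n, 50, 35, 1, 100))),
    tdim_pre_cm = preDim,
    tdim_post_cm = postDim,
    ypt = factor(ypt, levels = .YPT_LEVELS, ordered = TRUE),
    ypn = factor(ypn, levels = .YPN_LEVELS),
    stringsAsFactors = FALSE
  )
  df
}

#' Write a clinical table in the package's CSV layout
#'
#' Staging is written as a combined \code{yptn} token with the \code{yp}
#' prefix (e.g. \code{ypT1bN0}), as in the packaged fixture; the file round
#' trips through [readClinicalTable()].
#'
#' @param table a parsed or simulated clinical table
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeClinicalTable <- function(table, path) {
  out <- table[, setdiff(names(table), c("ypt", "ypn", "label", "pcr")),
               drop = FALSE]
  out$yptn <- paste0("yp", as.character(table$ypt), as.character(table$ypn))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
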