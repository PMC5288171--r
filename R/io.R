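readDelimited <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a long-format transition table
#'
#' Reads the canonical interchange file (comma- or tab-delimited,
#' auto-detected): one row per XIC area with columns \code{sample},
#' \code{group}, \code{replicate}, \code{protein}, \code{peptide},
#' \code{label}, \code{ion}, \code{area} (an optional \code{censored} column
#' is honoured). Duplicate keys, missing columns and negative or unparseable
#' areas are hard errors naming the offending rows.
#'
#' @param path file path
#' @return a \code{\link{TransitionExperiment}}
#' @export
readTransitionTable <- function(path) {
  df <- readDelimited(path)
  miss <- setdiff(REQUIRED_TRANSITION_COLS, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df$area <- suppressWarnings(as.numeric(df$area))
  bad <- which(!is.finite(df$area))
  if (length(bad))
    stop("unparseable area at data row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  neg <- which(df$area < 0)
  if (length(neg))
    stop("negative area at data row(s): ", paste(utils::head(neg, 5), collapse = ", "))
  key <- paste(df$sample, df$replicate, df$peptide, df$label, df$ion)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate key at data row(s): ", paste(utils::head(dup, 5), collapse = ", "))
  if (!is.null(df$censored)) df$censored <- as.logical(df$censored)
  TransitionExperiment(df)
}

#' @rdname readTransitionTable
#' @param te a \code{TransitionExperiment}
#' @details \code{writeTransitionTable} writes areas at full double
#'   precision so that write/read round-trips are exact.
#' @export
writeTransitionTable <- function(te, path) {
  rec <- transitions(te)
  rec$area <- sprintf("%.17g", rec$area)
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a reference spectral library
#'
#' Tab-delimited with columns \code{peptide}, \code{ion},
#' \code{relative_area}.
#'
#' @param path file path
#' @return \code{readReferenceLibrary}: a \code{\link{ReferenceLibrary}}
#' @export
readReferenceLibrary <- function(path) {
  df <- readDelimited(path)
  need <- c("peptide", "ion", "relative_area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ReferenceLibrary(df)
}

#' @rdname readReferenceLibrary
#' @param library a \code{ReferenceLibrary}
#' @export
writeReferenceLibrary <- function(library, path) {
  sp <- refSpectra(library)
  sp$relative_area <- sprintf("%.17g", sp$relative_area)
  utils::write.table(sp, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a blood spike-in series
#'
#' Comma- or tab-delimited with columns \code{patient}, \code{peptide},
#' \code{fraction}, \code{replicate}, \code{area}.
#'
#' @param path file path
#' @return data.frame suitable for \code{\link{bloodFilter}}
#' @export
readBloodSeries <- function(path) {
  df <- readDelimited(path)
  need <- c("patient", "peptide", "fraction", "replicate", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$area < 0)) stop("negative areas")
  df
}

#' @rdname readBloodSeries
#' @param series blood series data.frame
#' @export
writeBloodSeries <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable thresholds of the verification pipeline in one validated
#' object; the defaults reproduce the published rules (cosine > 0.98, >= 4
#' ions, removal when below-LOD in more than 50\% of samples, adjusted
#' p < 0.05 with fold change > 3, sensitivity read at 95\% specificity).
#'
#' @param cosThreshold spectral-contrast acceptance threshold
#' @param minIons minimum ions per measurement
#' @param detectFactor interference detection factor
#' @param lodFloor,lodCriterion censoring floor and summed-area LOD rule
#'   (both \code{NULL} = take from generator provenance / derive as
#'   \code{nIons * lodFloor})
#' @param lodRemovalFraction below-LOD sample fraction above which a peptide
#'   is removed
#' @param fcThreshold,alpha significance gate
#' @param fixedSpecificity fixed-specificity ROC operating point
#' @param fcMethod fold-change central value
#' @param bloodSlopeTolerance minimum slope counting as blood-positive
#' @param seed integer seed echoed into the run log
#' @return object of class \code{PipelineConfig}
#' @export
pipelineConfig <- function(cosThreshold = 0.98, minIons = 4L, detectFactor = 3,
                           lodFloor = NULL, lodCriterion = NULL,
                           lodRemovalFraction = 0.5, fcThreshold = 3,
                           alpha = 0.05, fixedSpecificity = 0.95,
                           fcMethod = c("median", "mean"),
                           bloodSlopeTolerance = 0, seed = 1L) {
  fcMethod <- match.arg(fcMethod)
  stopifnot(cosThreshold > 0, cosThreshold <= 1, minIons >= 1,
            detectFactor > 1, lodRemovalFraction >= 0, lodRemovalFraction <= 1,
            fcThreshold >= 0, alpha > 0, alpha < 1,
            fixedSpecificity > 0, fixedSpecificity <= 1)
  structure(list(cosThreshold = cosThreshold, minIons = as.integer(minIons),
                 detectFactor = detectFactor, lodFloor = lodFloor,
                 lodCriterion = lodCriterion,
                 lodRemovalFraction = lodRemovalFraction,
                 fcThreshold = fcThreshold, alpha = alpha,
                 fixedSpecificity = fixedSpecificity, fcMethod = fcMethod,
                 bloodSlopeTolerance = bloodSlopeTolerance,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

signifCols <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' Run the full verification pipeline
#'
#' Chains the stages end to end: optional blood-contamination screen,
#' spectral-contrast QC with interference substitution and background
#' imputation, LOD-based peptide removal, light/heavy quantification with
#' duplicate averaging, and the group-comparison statistics. Each stage logs
#' the counts entering and leaving its filter.
#'
#' @param te a \code{\link{TransitionExperiment}} or path to a transition
#'   table
#' @param library a \code{\link{ReferenceLibrary}} or path
#' @param bloodSeries optional blood spike-in data.frame or path
#' @param config a \code{\link{pipelineConfig}}
#' @param outputDir when given, the QC report, ratio matrix, CV report,
#'   result table and run log are written there as delimited text
#' @return list with \code{qc}, \code{qcSummary}, \code{lod} (kept/removed),
#'   \code{blood} (screen table or \code{NULL}), \code{ratios}
#'   (\code{SummarizedExperiment}), \code{results}, \code{significant},
#'   \code{siblingR}, \code{log}
#' @export
runPipeline <- function(te, library, bloodSeries = NULL,
                        config = pipelineConfig(), outputDir = NULL) {
  if (is.character(te)) te <- readTransitionTable(te)
  if (is.character(library)) library <- readReferenceLibrary(library)
  if (is.character(bloodSeries)) bloodSeries <- readBloodSeries(bloodSeries)
  log <- c(sprintf("pipeline seed=%d cosThreshold=%g fcThreshold=%g alpha=%g",
                   config$seed, config$cosThreshold, config$fcThreshold,
                   config$alpha))

  blood <- NULL
  if (!is.null(bloodSeries)) {
    blood <- bloodFilter(bloodSeries, tolerance = config$bloodSlopeTolerance)
    rejected <- blood$peptide[blood$decision == "reject"]
    n0 <- length(peptides(te))
    rec <- transitions(te)
    te <- TransitionExperiment(rec[!rec$peptide %in% rejected, ],
                               provenance = provenance(te))
    log <- c(log, sprintf(
      "blood_filter: %d candidates screened, %d rejected; %d -> %d panel peptides",
      nrow(blood), length(rejected), n0, length(peptides(te))))
  }

  qc <- runSpectralQC(te, library, cosThreshold = config$cosThreshold,
                      detectFactor = config$detectFactor,
                      lodFloor = config$lodFloor,
                      lodCriterion = config$lodCriterion,
                      minIons = config$minIons)
  lod <- filterPeptidesByLod(qc, removalFraction = config$lodRemovalFraction)
  sm <- qcSummary(qc, removedPeptides = lod$removed)
  log <- c(log, sprintf(
    "spectral_qc: %d pairs, %.1f%% matched, %.1f%% below LOD, %.1f%% unresolved; %d peptide(s) removed by LOD rule",
    sm$total_pairs, 100 * sm$fraction_matched, 100 * sm$fraction_below_lod,
    100 * sm$fraction_unresolved, length(lod$removed)))

  rr <- computeRatios(qc)
  se <- buildRatioMatrix(rr, keptPeptides = lod$kept)
  sib <- suppressMessages(siblingCorrelation(se))
  log <- c(log, sprintf("quantification: %d peptides x %d samples averaged over duplicates",
                        nrow(se), ncol(se)))

  results <- compareGroups(se, alpha = config$alpha,
                           fcThreshold = config$fcThreshold,
                           fcMethod = config$fcMethod,
                           fixedSpecificity = config$fixedSpecificity)
  sig <- selectSignificant(results, config$alpha, config$fcThreshold)
  log <- c(log, sprintf("biomarker_stats: %d peptides tested, %d significant (adj p < %g, FC > %g)",
                        nrow(results), nrow(sig), config$alpha, config$fcThreshold))

  out <- list(qc = qc, qcSummary = sm, lod = lod, blood = blood,
              ratios = se, results = results, significant = sig,
              siblingR = sib, log = log)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f, sep = "\t")
      utils::write.table(signifCols(df), file.path(outputDir, f), sep = sep,
                         row.names = FALSE, quote = FALSE)
    w(qc, "qc_report.tsv")
    ratio <- as.data.frame(SummarizedExperiment::assay(se, "ratio"))
    ratio <- cbind(peptide = rownames(ratio), signifCols(ratio))
    utils::write.table(ratio, file.path(outputDir, "ratio_matrix.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cvdf <- as.data.frame(SummarizedExperiment::assay(se, "cv"))
    cvdf <- cbind(peptide = rownames(cvdf), signifCols(cvdf))
    utils::write.table(cvdf, file.path(outputDir, "cv_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    w(results, "results.tsv")
    if (!is.null(blood)) w(blood, "blood_decisions.tsv")
    writeLines(log, file.path(outputDir, "run_log.txt"))
  }
  out
}
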