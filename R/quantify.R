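#' Light/heavy ratio of one measurement
#'
#' The relative abundance of the endogenous peptide: summed light XIC areas
#' divided by summed heavy XIC areas over the ions retained by QC.
#'
#' @param light,heavy area vectors restricted to the ions used
#' @return the dimensionless light/heavy ratio
#' @export
computeRatio <- function(light, heavy) {
  if (sum(heavy) <= 0) stop("zero heavy sum: corrupt internal standard")
  sum(light) / sum(heavy)
}

#' Per-replicate ratio records from a QC report
#'
#' Builds one light/heavy ratio per non-unresolved (sample, replicate,
#' peptide) measurement, using the summed areas over the retained ions
#' (background-imputed for below-LOD measurements) carried in the QC report.
#'
#' @param qc QC report from \code{\link{runSpectralQC}}
#' @return data.frame of ratio records with keys, \code{ratio} and
#'   \code{status}
#' @export
computeRatios <- function(qc) {
  keep <- qc$status != "unresolved"
  sub <- qc[keep, ]
  if (any(sub$heavy_sum <= 0)) stop("zero heavy sum: corrupt internal standard")
  data.frame(sample = sub$sample, group = sub$group, replicate = sub$replicate,
             protein = sub$protein, peptide = sub$peptide,
             ratio = sub$light_sum / sub$heavy_sum, status = sub$status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Average full-process duplicates
#'
#' @param ratios numeric ratios of the usable (non-unresolved) replicates of
#'   one sample and peptide
#' @return list with the arithmetic \code{mean} and \code{cv} (percent,
#'   sample standard deviation over mean; \code{NA} for a single replicate)
#' @examples
#' averageDuplicates(c(0.9, 1.1))   # mean 1, cv ~14.1%
#' @export
averageDuplicates <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0L) stop("no usable replicate")
  m <- mean(ratios)
  cv <- if (length(ratios) >= 2L) 100 * sd(ratios) / m else NA_real_
  list(mean = m, cv = cv)
}

#' Duplicate-averaged ratio matrix
#'
#' Assembles the peptide x sample matrix of duplicate-averaged light/heavy
#' ratios, with the per-cell duplicate CV\%, as a
#' \code{SummarizedExperiment} (assays \code{ratio} and \code{cv}; sample
#' group labels in \code{colData}, protein map in \code{rowData}). Peptides
#' removed by the LOD rule are excluded. Background imputation upstream
#' guarantees a value for every remaining cell unless every replicate of a
#' cell was unresolved (then \code{NA}, with a warning).
#'
#' @param ratioRecords output of \code{\link{computeRatios}}
#' @param keptPeptides peptides to retain (default: all present)
#' @return a \code{SummarizedExperiment}
#' @export
buildRatioMatrix <- function(ratioRecords, keptPeptides = NULL) {
  rr <- ratioRecords
  if (!is.null(keptPeptides)) rr <- rr[rr$peptide %in% keptPeptides, ]
  peps <- unique(rr$peptide)
  samps <- unique(rr$sample)
  fp <- factor(rr$peptide, levels = peps)
  fs <- factor(rr$sample, levels = samps)
  ratio <- tapply(rr$ratio, list(fp, fs), mean)
  cvm <- tapply(rr$ratio, list(fp, fs), function(v)
    if (length(v) >= 2L) 100 * sd(v) / mean(v) else NA_real_)
  dimnames(ratio) <- dimnames(cvm) <- list(peps, samps)
  if (anyNA(ratio))
    warning("ratio matrix has ", sum(is.na(ratio)),
            " cell(s) with no usable replicate")
  grp <- rr$group[match(samps, rr$sample)]
  prot <- rr$protein[match(peps, rr$peptide)]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = ratio, cv = cvm),
    rowData = S4Vectors::DataFrame(protein = prot, row.names = peps),
    colData = S4Vectors::DataFrame(group = grp, row.names = samps))
}

#' Pearson correlation between sibling peptides of one protein
#'
#' For every protein monitored with exactly two kept peptides, computes the
#' Pearson correlation across samples between the two peptides'
#' duplicate-averaged ratios — a consistency check of protein-level
#' quantification. Proteins with one kept peptide are skipped with a notice;
#' proteins with more than two are skipped likewise.
#'
#' @param se ratio matrix from \code{\link{buildRatioMatrix}}
#' @param logScale correlate log-ratios instead of raw ratios
#' @return data.frame with columns \code{protein}, \code{peptide1},
#'   \code{peptide2}, \code{r}
#' @export
siblingCorrelation <- function(se, logScale = FALSE) {
  ratio <- SummarizedExperiment::assay(se, "ratio")
  if (ncol(ratio) < 3L) stop("need at least 3 samples")
  prot <- SummarizedExperiment::rowData(se)$protein
  out <- list()
  for (p in unique(prot)) {
    rows <- which(prot == p)
    if (length(rows) != 2L) {
      message("protein ", p, " monitored with ", length(rows),
              " kept peptide(s); skipped")
      next
    }
    x <- ratio[rows[1L], ]; y <- ratio[rows[2L], ]
    if (logScale) { x <- log(x); y <- log(y) }
    out[[p]] <- data.frame(protein = p,
                           peptide1 = rownames(ratio)[rows[1L]],
                           peptide2 = rownames(ratio)[rows[2L]],
                           r = cor(x, y, use = "complete.obs"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
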