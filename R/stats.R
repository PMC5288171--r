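#' Mann-Whitney U test between tumor and control values
#'
#' U counts tumor-over-control pairs with ties counted one-half (midrank
#' construction). The two-sided p-value comes from the exact distribution for
#' small untied samples (combined n <= 12) and from the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param tumor,control non-empty numeric vectors
#' @return list with \code{U} and two-sided \code{p}
#' @examples
#' mannWhitney(c(5, 6, 7), c(1, 2, 3))$U   # 9, complete separation
#' @export
mannWhitney <- function(tumor, control) {
  if (length(tumor) == 0L || length(control) == 0L) stop("empty group")
  n1 <- length(tumor); n2 <- length(control)
  r <- rank(c(tumor, control))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(tumor, control)) > 0L
  exact <- (n1 + n2) <= 12L && !ties
  p <- suppressWarnings(
    wilcox.test(tumor, control, exact = exact, correct = TRUE)$p.value)
  list(U = U, p = p)
}

#' Rank-based area under the ROC curve
#'
#' The empirical probability that a random tumor value exceeds a random
#' control value, ties counted one-half: \eqn{AUC = U / (n_1 n_2)}.
#'
#' @param tumor,control non-empty numeric vectors
#' @return AUC in [0, 1]
#' @export
aucStat <- function(tumor, control) {
  if (length(tumor) == 0L || length(control) == 0L) stop("empty group")
  mannWhitney(tumor, control)$U / (length(tumor) * length(control))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in [0, 1]
#' @return adjusted p-values (monotone step-up, capped at 1)
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fold change between groups
#'
#' Ratio of the tumor central value to the control central value; the median
#' is the default central value, consistent with the nonparametric test and
#' the quartile-based reporting.
#'
#' @param tumor,control non-empty numeric vectors
#' @param method \code{"median"} (default) or \code{"mean"}
#' @return the fold change
#' @export
foldChange <- function(tumor, control, method = c("median", "mean")) {
  method <- match.arg(method)
  f <- if (method == "median") median else mean
  denom <- f(control)
  if (denom <= 0) stop("non-positive control central value: unquantifiable fold change")
  f(tumor) / denom
}

#' Empirical ROC operating points
#'
#' Sweeps decision thresholds midway between adjacent pooled values (a value
#' above the threshold is called tumor). Reports the Youden-optimal point
#' (maximizing sensitivity + specificity - 1, ties resolved toward higher
#' specificity) and the maximum sensitivity among thresholds whose
#' specificity is at least \code{fixedSpecificity}.
#'
#' @param tumor,control non-empty numeric vectors
#' @param fixedSpecificity the fixed-specificity operating point (default
#'   0.95)
#' @return list with \code{sensitivity}, \code{specificity} (percent, Youden
#'   point), \code{threshold}, and \code{sens_at_fixed_spec} (percent)
#' @export
rocOperatingPoints <- function(tumor, control, fixedSpecificity = 0.95) {
  if (length(tumor) == 0L || length(control) == 0L) stop("empty group")
  v <- sort(unique(c(tumor, control)))
  thr <- c(v[1L] - 1, if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2, v[length(v)] + 1)
  sens <- vapply(thr, function(t) mean(tumor > t), numeric(1))
  spec <- vapply(thr, function(t) mean(control <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  okspec <- spec >= fixedSpecificity
  s95 <- if (any(okspec)) max(sens[okspec]) else 0
  list(sensitivity = 100 * sens[best], specificity = 100 * spec[best],
       threshold = thr[best], sens_at_fixed_spec = 100 * s95)
}

#' Group comparison statistics for every peptide
#'
#' Produces the verification result table: per peptide the fold change,
#' Mann-Whitney U and p, BH-adjusted p (across all tested peptides jointly),
#' the group ratio quartiles, AUC, the Youden operating point, sensitivity at
#' fixed specificity, and the significance flag (\code{p_adj < alpha} and
#' \code{FC > fcThreshold}, both strict).
#'
#' @param se duplicate-averaged ratio matrix from
#'   \code{\link{buildRatioMatrix}} with a \code{group} column in its
#'   \code{colData} containing \code{"tumor"} and \code{"control"}
#' @param alpha adjusted-p significance level (default 0.05)
#' @param fcThreshold fold-change gate (default 3)
#' @param fcMethod central value for the fold change (\code{"median"} or
#'   \code{"mean"})
#' @param fixedSpecificity fixed-specificity operating point (default 0.95)
#' @return data.frame, one row per peptide, ordered by adjusted p
#' @export
compareGroups <- function(se, alpha = 0.05, fcThreshold = 3,
                          fcMethod = c("median", "mean"),
                          fixedSpecificity = 0.95) {
  fcMethod <- match.arg(fcMethod)
  ratio <- SummarizedExperiment::assay(se, "ratio")
  grp <- SummarizedExperiment::colData(se)$group
  if (!all(c("tumor", "control") %in% grp))
    stop("colData group must contain both 'tumor' and 'control'")
  prot <- SummarizedExperiment::rowData(se)$protein
  rows <- lapply(seq_len(nrow(ratio)), function(i) {
    x <- ratio[i, grp == "tumor"]; x <- x[!is.na(x)]
    y <- ratio[i, grp == "control"]; y <- y[!is.na(y)]
    mw <- mannWhitney(x, y)
    roc <- rocOperatingPoints(x, y, fixedSpecificity)
    qx <- quantile(x, c(0.25, 0.75), names = FALSE)
    qy <- quantile(y, c(0.25, 0.75), names = FALSE)
    data.frame(protein = prot[i], peptide = rownames(ratio)[i],
               fc = foldChange(x, y, fcMethod), U = mw$U, p = mw$p,
               tumor_q1 = qx[1], tumor_q3 = qx[2],
               control_q1 = qy[1], control_q3 = qy[2],
               auc = aucStat(x, y),
               sensitivity = roc$sensitivity, specificity = roc$specificity,
               sens_at_95spec = roc$sens_at_fixed_spec,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bhAdjust(res$p)
  res$significant <- res$p_adj < alpha & res$fc > fcThreshold
  res <- res[order(res$p_adj, res$p), ]
  rownames(res) <- NULL
  res[, c("protein", "peptide", "fc", "U", "p", "p_adj", "tumor_q1",
          "tumor_q3", "control_q1", "control_q3", "auc", "sensitivity",
          "specificity", "sens_at_95spec", "significant")]
}

#' Significant subset of a verification result table
#'
#' @param results output of \code{\link{compareGroups}}
#' @param alpha adjusted-p level (strict \code{<}, default 0.05)
#' @param fcThreshold fold-change gate (strict \code{>}, default 3)
#' @return the significant rows, order preserved
#' @export
selectSignificant <- function(results, alpha = 0.05, fcThreshold = 3) {
  results[results$p_adj < alpha & results$fc > fcThreshold, , drop = FALSE]
}
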