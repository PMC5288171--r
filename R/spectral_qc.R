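#' Cosine of the spectral contrast angle
#'
#' Similarity between an experimental fragment-ion intensity vector and its
#' reference profile:
#' \deqn{\cos\theta = \frac{\sum_i A_{exp,i} A_{ref,i}}
#'   {\sqrt{\sum_i A_{exp,i}^2 \; \sum_i A_{ref,i}^2}}}
#' Scale-invariant in each argument; 1 iff the profiles are proportional.
#' An all-zero experimental vector returns 0 by convention (such a
#' measurement carries no identity information and is handled as below the
#' limit of detection downstream).
#'
#' @param areasExp non-negative experimental XIC areas
#' @param areasRef reference areas of the same ions, not all zero
#' @return cosine score in [0, 1]
#' @examples
#' spectralContrastCosine(c(90, 85, 55, 45, 25), c(90, 85, 55, 45, 25)) # 1
#' @export
spectralContrastCosine <- function(areasExp, areasRef) {
  if (length(areasExp) != length(areasRef))
    stop("experimental and reference vectors differ in length")
  if (length(areasExp) < 1L) stop("empty vectors")
  if (any(areasExp < 0) || any(areasRef < 0)) stop("negative XIC area")
  if (all(areasRef == 0)) stop("reference vector is all zero")
  if (all(areasExp == 0)) return(0)
  # clamp roundoff: proportional vectors can land a hair above 1
  min(1, sum(areasExp * areasRef) / sqrt(sum(areasExp^2) * sum(areasRef^2)))
}

#' Per-ion background estimate
#'
#' For one (peptide, label), returns per ion half of the smallest
#' non-censored area observed across all samples and replicates; ions with no
#' non-censored observation fall back to \code{lodFloor / 2}. Used to impute
#' below-LOD light measurements so the ratio matrix has no missing values.
#'
#' @param te a \code{\link{TransitionExperiment}}
#' @param peptide peptide sequence present in \code{te}
#' @param label \code{"light"} or \code{"heavy"}
#' @param lodFloor censoring floor; taken from the generator provenance when
#'   available
#' @return named numeric vector, one background area per ion
#' @export
estimateBackground <- function(te, peptide, label = "light", lodFloor = NULL) {
  rec <- transitions(te)
  if (!peptide %in% rec$peptide) stop("unknown peptide: ", peptide)
  if (is.null(lodFloor))
    lodFloor <- if (!is.null(provenance(te)$config)) provenance(te)$config$lodFloor else 0
  sub <- rec[rec$peptide == peptide & rec$label == label, ]
  cens <- if (!is.null(sub$censored)) sub$censored else sub$area < lodFloor
  ions <- unique(sub$ion)
  vapply(ions, function(io) {
    a <- sub$area[sub$ion == io & !cens]
    if (length(a)) min(a) / 2 else lodFloor / 2
  }, numeric(1))
}

#' Evaluate one PRM measurement through the QC cascade
#'
#' Applies the acceptance cascade to one (sample, replicate, peptide)
#' light/heavy measurement: (1) accept when \eqn{\cos\theta} of both the
#' endogenous and the labeled trace against the reference exceeds the
#' threshold on all ions; (2) otherwise, when exactly one ion is interfered —
#' its observed/reference intensity ratio exceeds \code{detectFactor} times
#' the median such ratio of the trace — drop that ion from both labels
#' and re-score on the remaining ions, never fewer than \code{minIons}; (3)
#' otherwise, when the summed light area falls below \code{lodCriterion},
#' replace the light areas by the background estimate and flag below-LOD;
#' (4) otherwise the measurement is unresolved.
#'
#' @param light,heavy non-negative area vectors aligned on the reference ions
#' @param reference positive reference relative areas (names = ion ids)
#' @param threshold cosine acceptance threshold (strict \code{>}), default
#'   0.98
#' @param background per-ion background vector used for below-LOD imputation
#' @param lodCriterion summed-light-area floor under which a failing
#'   measurement counts as below the limit of detection
#' @param detectFactor interference detection factor: an ion is a candidate
#'   when its observed/reference ratio exceeds this multiple of the trace's
#'   median observed/reference ratio
#' @param minIons minimum ions retained after substitution (default 4)
#' @return list with \code{status} (one of \code{accepted},
#'   \code{accepted_after_substitution}, \code{below_lod},
#'   \code{unresolved}), \code{cosLight}, \code{cosHeavy}, \code{ionsUsed},
#'   \code{lightUsed}, \code{heavyUsed}, \code{backgroundSubstituted}
#' @export
evaluateMeasurement <- function(light, heavy, reference, threshold = 0.98,
                                background = NULL, lodCriterion = 0,
                                detectFactor = 3, minIons = 4L) {
  n <- length(reference)
  if (length(light) != n || length(heavy) != n)
    stop("light/heavy/reference ion sets are misaligned")
  ions <- names(reference)
  if (is.null(ions)) ions <- sprintf("i%d", seq_len(n))
  ref <- as.numeric(reference)

  cl <- spectralContrastCosine(light, ref)
  ch <- spectralContrastCosine(heavy, ref)
  res <- list(status = "unresolved", cosLight = cl, cosHeavy = ch,
              ionsUsed = ions, lightUsed = light, heavyUsed = heavy,
              backgroundSubstituted = FALSE)
  if (cl > threshold && ch > threshold) {
    res$status <- "accepted"
    return(res)
  }

  ## (2) single-ion interference: one ion's observed/reference intensity
  ## ratio stands far above the others (scale-free, so detection is
  ## invariant to rescaling the trace), on either label
  if (n - 1L >= minIons) {
    cand <- integer(0)
    for (v in list(light, heavy)) {
      if (sum(v) > 0) {
        q <- v / ref
        cand <- union(cand, which(q > detectFactor * median(q)))
      }
    }
    if (length(cand) == 1L) {
      keep <- setdiff(seq_len(n), cand)
      cl4 <- spectralContrastCosine(light[keep], ref[keep])
      ch4 <- spectralContrastCosine(heavy[keep], ref[keep])
      if (cl4 > threshold && ch4 > threshold) {
        res$status <- "accepted_after_substitution"
        res$cosLight <- cl4; res$cosHeavy <- ch4
        res$ionsUsed <- ions[keep]
        res$lightUsed <- light[keep]; res$heavyUsed <- heavy[keep]
        return(res)
      }
    }
  }

  ## (3) below the limit of detection: impute background
  if (sum(light) < lodCriterion || all(light == 0)) {
    res$status <- "below_lod"
    res$backgroundSubstituted <- TRUE
    if (!is.null(background)) {
      bg <- background[ions]
      bg[is.na(bg)] <- 0
      res$lightUsed <- as.numeric(bg)
    }
    return(res)
  }
  res
}

#' Run spectral-contrast QC over a transition dataset
#'
#' Scores every (sample, replicate, peptide) measurement through
#' \code{\link{evaluateMeasurement}}. The summed light and heavy areas over
#' the retained ions (after any substitution or background imputation) are
#' carried along for quantification.
#'
#' @param te a \code{\link{TransitionExperiment}}
#' @param library the \code{\link{ReferenceLibrary}} used as \eqn{A_{ref}}
#' @param cosThreshold cosine acceptance threshold (default 0.98)
#' @param detectFactor interference detection factor (default 3)
#' @param lodFloor per-transition censoring floor; defaults to the generator
#'   provenance value, else 0
#' @param lodCriterion summed-light-area LOD rule; defaults to
#'   \code{nIons * lodFloor}
#' @param minIons minimum ions used per measurement (default 4)
#' @return data.frame, one row per measurement: keys, \code{cos_light},
#'   \code{cos_heavy}, \code{status}, \code{ions_used} (comma-separated),
#'   \code{background_substituted}, \code{light_sum}, \code{heavy_sum}
#' @export
runSpectralQC <- function(te, library, cosThreshold = 0.98, detectFactor = 3,
                          lodFloor = NULL, lodCriterion = NULL, minIons = 4L) {
  rec <- transitions(te)
  sp <- refSpectra(library)
  if (is.null(lodFloor))
    lodFloor <- if (!is.null(provenance(te)$config)) provenance(te)$config$lodFloor else 0
  out <- vector("list", length(unique(rec$peptide)))
  names(out) <- unique(rec$peptide)

  for (pep in unique(rec$peptide)) {
    prf <- sp[sp$peptide == pep, ]
    if (nrow(prf) == 0L) stop("peptide absent from reference library: ", pep)
    ref <- setNames(prf$relative_area, prf$ion)
    n <- length(ref)
    crit <- if (is.null(lodCriterion)) n * lodFloor else lodCriterion
    sub <- rec[rec$peptide == pep, ]
    ## align ions to reference order and reshape to ion x measurement matrices
    sub <- sub[order(sub$label, sub$sample, sub$replicate,
                     match(sub$ion, prf$ion)), ]
    li <- sub[sub$label == "light", ]
    he <- sub[sub$label == "heavy", ]
    mk <- function(d) {
      key <- paste(d$sample, d$replicate, sep = "\r")
      u <- unique(key)
      m <- matrix(d$area, nrow = n,
                  dimnames = list(prf$ion, u))
      m
    }
    L <- mk(li); H <- mk(he)
    if (!identical(colnames(L), colnames(H)))
      stop("light/heavy measurements misaligned for peptide ", pep)
    M <- ncol(L)
    cl <- pmin(1, colSums(L * ref) / sqrt(colSums(L^2) * sum(ref^2)))
    cl[colSums(L) == 0] <- 0
    ch <- pmin(1, colSums(H * ref) / sqrt(colSums(H^2) * sum(ref^2)))
    ch[colSums(H) == 0] <- 0
    pass <- cl > cosThreshold & ch > cosThreshold

    meta <- unique(li[, c("sample", "replicate", "group", "protein")])
    key <- paste(meta$sample, meta$replicate, sep = "\r")
    meta <- meta[match(colnames(L), key), ]
    df <- data.frame(sample = meta$sample, group = meta$group,
                     replicate = meta$replicate, protein = meta$protein,
                     peptide = pep, cos_light = cl, cos_heavy = ch,
                     status = ifelse(pass, "accepted", "unresolved"),
                     ions_used = paste(prf$ion, collapse = ","),
                     background_substituted = FALSE,
                     light_sum = colSums(L), heavy_sum = colSums(H),
                     stringsAsFactors = FALSE, row.names = NULL)
    if (any(!pass)) {
      bg <- estimateBackground(te, pep, "light", lodFloor = lodFloor)
      for (j in which(!pass)) {
        ev <- evaluateMeasurement(L[, j], H[, j], ref,
                                  threshold = cosThreshold, background = bg,
                                  lodCriterion = crit,
                                  detectFactor = detectFactor, minIons = minIons)
        df$status[j] <- ev$status
        df$cos_light[j] <- ev$cosLight
        df$cos_heavy[j] <- ev$cosHeavy
        df$ions_used[j] <- paste(ev$ionsUsed, collapse = ",")
        df$background_substituted[j] <- ev$backgroundSubstituted
        df$light_sum[j] <- sum(ev$lightUsed)
        df$heavy_sum[j] <- sum(ev$heavyUsed)
      }
    }
    out[[pep]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize QC outcomes
#'
#' @param qc QC report from \code{\link{runSpectralQC}}
#' @param removedPeptides peptides removed by \code{\link{filterPeptidesByLod}}
#' @return list with total pair count, per-status counts, the fraction of
#'   pairs positively matched (accepted before or after substitution), the
#'   below-LOD and unresolved fractions, and the removed peptides
#' @export
qcSummary <- function(qc, removedPeptides = character(0)) {
  n <- nrow(qc)
  cnt <- table(factor(qc$status, levels = c("accepted",
        "accepted_after_substitution", "below_lod", "unresolved")))
  list(total_pairs = n,
       counts = as.list(cnt),
       fraction_matched = unname((cnt[["accepted"]] +
                                  cnt[["accepted_after_substitution"]]) / n),
       fraction_below_lod = unname(cnt[["below_lod"]] / n),
       fraction_unresolved = unname(cnt[["unresolved"]] / n),
       removed_peptides = removedPeptides)
}

#' Remove peptides below the limit of detection in most samples
#'
#' A sample counts as below-LOD for a peptide when every one of its
#' preparation replicates was flagged \code{below_lod}; a peptide is removed
#' when the fraction of such samples strictly exceeds
#' \code{removalFraction}.
#'
#' @param qc QC report from \code{\link{runSpectralQC}}
#' @param removalFraction removal rule threshold (default 0.5, strict
#'   \code{>})
#' @return list with disjoint, jointly exhaustive character vectors
#'   \code{kept} and \code{removed}
#' @export
filterPeptidesByLod <- function(qc, removalFraction = 0.5) {
  peps <- unique(qc$peptide)
  below <- vapply(peps, function(p) {
    sub <- qc[qc$peptide == p, ]
    sampBelow <- tapply(sub$status == "below_lod", sub$sample, all)
    mean(sampBelow)
  }, numeric(1))
  removed <- peps[below > removalFraction]
  list(kept = setdiff(peps, removed), removed = removed)
}

#' Advisory MS1 total-ion-chromatogram check
#'
#' Flags samples whose summed MS1 signal deviates from the cohort median by
#' more than \code{k} median absolute deviations — a sanity check that a
#' constant amount of protein was injected. Advisory only: no sample is ever
#' dropped.
#'
#' @param tic positive per-sample summed MS1 intensities (named)
#' @param k outlier multiplier (default 5)
#' @return named logical vector of flags
#' @export
ms1TicCheck <- function(tic, k = 5) {
  if (length(tic) < 3L) stop("need at least 3 samples")
  if (any(tic <= 0)) stop("TIC values must be positive")
  md <- median(tic)
  dev <- abs(tic - md)
  setNames(dev > k * mad(tic), names(tic))
}
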