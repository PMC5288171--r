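#' @import methods
#' @importFrom stats coef cor lm mad median p.adjust pnorm quantile rbinom
#'   rlnorm runif sd setNames wilcox.test
NULL

REQUIRED_TRANSITION_COLS <- c("sample", "group", "replicate", "protein",
                              "peptide", "label", "ion", "area")

#' Reference spectral library
#'
#' Per-peptide relative intensities of the top product ions, as measured in a
#' matrix-free acquisition of the synthetic (isotope-labeled) peptide mix.
#' These reference profiles are the \eqn{A_{ref}} vectors against which the
#' spectral contrast angle of every experimental measurement is scored.
#'
#' @slot spectra data.frame with columns \code{peptide}, \code{ion},
#'   \code{relative_area}; per peptide the relative areas are positive,
#'   non-increasing in ion rank, and sum to 1.
#' @export
setClass("ReferenceLibrary", representation(spectra = "data.frame"))

setValidity("ReferenceLibrary", function(object) {
  sp <- object@spectra
  need <- c("peptide", "ion", "relative_area")
  if (!all(need %in% names(sp)))
    return(paste("spectra must have columns:", paste(need, collapse = ", ")))
  if (nrow(sp) == 0L) return("library is empty")
  if (any(sp$relative_area <= 0)) return("relative areas must be > 0")
  for (pep in unique(sp$peptide)) {
    v <- sp$relative_area[sp$peptide == pep]
    if (length(v) < 4L) return(sprintf("peptide %s has < 4 ions", pep))
    if (abs(sum(v) - 1) > 1e-8) return(sprintf("peptide %s: areas do not sum to 1", pep))
    if (is.unsorted(rev(v))) return(sprintf("peptide %s: areas not non-increasing", pep))
  }
  TRUE
})

#' PRM transition dataset
#'
#' Long-format container for extracted-ion-chromatogram (XIC) peak areas: one
#' row per (sample, replicate, peptide, isotope label, product ion). This is
#' the atomic input of the pipeline, mirroring a transition-results export
#' from a chromatogram-integration tool.
#'
#' @slot records data.frame with columns \code{sample}, \code{group},
#'   \code{replicate}, \code{protein}, \code{peptide}, \code{label}
#'   (\code{"light"} or \code{"heavy"}), \code{ion}, \code{area} and an
#'   optional logical \code{censored} flag for areas below the detection
#'   floor.
#' @slot provenance list; for simulated data holds the generator
#'   configuration, the reference library, the drawn true ratios and the
#'   injected interference coordinates. Empty for real data.
#' @export
setClass("TransitionExperiment",
         representation(records = "data.frame", provenance = "list"))

setValidity("TransitionExperiment", function(object) {
  rec <- object@records
  miss <- setdiff(REQUIRED_TRANSITION_COLS, names(rec))
  if (length(miss))
    return(paste("records missing columns:", paste(miss, collapse = ", ")))
  if (nrow(rec)) {
    if (any(rec$area < 0)) return("negative XIC areas")
    if (!all(rec$label %in% c("light", "heavy")))
      return("label must be 'light' or 'heavy'")
    key <- paste(rec$sample, rec$replicate, rec$peptide, rec$label, rec$ion)
    if (anyDuplicated(key))
      return("duplicate (sample, replicate, peptide, label, ion) keys")
    grp <- unique(rec[, c("sample", "group")])
    if (anyDuplicated(grp$sample))
      return("group label not constant within sample")
  }
  TRUE
})

#' @describeIn TransitionExperiment construct from a record data.frame
#' @param records data.frame of transition records
#' @param provenance optional provenance list
#' @export
TransitionExperiment <- function(records, provenance = list()) {
  records <- as.data.frame(records)
  if (is.null(records$censored)) records$censored <- FALSE
  new("TransitionExperiment", records = records, provenance = provenance)
}

#' @describeIn ReferenceLibrary construct from a spectra data.frame
#' @param spectra data.frame with columns peptide, ion, relative_area
#' @export
ReferenceLibrary <- function(spectra) {
  new("ReferenceLibrary", spectra = as.data.frame(spectra))
}

#' Accessors for PRM containers
#'
#' @param object a \code{TransitionExperiment} or \code{ReferenceLibrary}
#' @return \code{transitions}: the record data.frame; \code{refSpectra}: the
#'   spectra data.frame; \code{provenance}: the provenance list;
#'   \code{peptides}/\code{samples}: character vectors of unique keys.
#' @name prm-accessors
NULL

#' @rdname prm-accessors
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))
#' @rdname prm-accessors
#' @export
setMethod("transitions", "TransitionExperiment", function(object) object@records)

#' @rdname prm-accessors
#' @export
setGeneric("refSpectra", function(object) standardGeneric("refSpectra"))
#' @rdname prm-accessors
#' @export
setMethod("refSpectra", "ReferenceLibrary", function(object) object@spectra)

#' @rdname prm-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname prm-accessors
#' @export
setMethod("provenance", "TransitionExperiment", function(object) object@provenance)

#' @rdname prm-accessors
#' @export
setGeneric("peptides", function(object) standardGeneric("peptides"))
#' @rdname prm-accessors
#' @export
setMethod("peptides", "TransitionExperiment",
          function(object) unique(object@records$peptide))
#' @rdname prm-accessors
#' @export
setMethod("peptides", "ReferenceLibrary",
          function(object) unique(object@spectra$peptide))

#' @rdname prm-accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname prm-accessors
#' @export
setMethod("samples", "TransitionExperiment",
          function(object) unique(object@records$sample))

setMethod("show", "TransitionExperiment", function(object) {
  rec <- object@records
  cat("TransitionExperiment with", nrow(rec), "XIC records\n")
  if (nrow(rec)) {
    cat(" ", length(unique(rec$sample)), "samples,",
        length(unique(rec$peptide)), "peptides,",
        max(rec$replicate), "replicate(s)\n")
    tab <- table(unique(rec[, c("sample", "group")])$group)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (length(object@provenance))
    cat("  simulated (provenance:",
        paste(names(object@provenance), collapse = ", "), ")\n")
})

setMethod("show", "ReferenceLibrary", function(object) {
  sp <- object@spectra
  cat("ReferenceLibrary:", length(unique(sp$peptide)), "peptides,",
      nrow(sp), "reference ion intensities\n")
})
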