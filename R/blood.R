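#' Ordinary least-squares slope of area on blood fraction
#'
#' @param fractions blood volume fractions, at least two distinct values
#' @param areas non-negative mean peptide areas, one per fraction
#' @return the OLS slope (area units per unit blood fraction)
#' @examples
#' linearSlope(c(0, 0.1, 0.2, 0.4), c(0, 1, 2, 4))   # 10
#' @export
linearSlope <- function(fractions, areas) {
  if (length(fractions) != length(areas))
    stop("fractions and areas differ in length")
  if (length(unique(fractions)) < 2L) stop("need at least 2 distinct fractions")
  if (any(areas < 0)) stop("negative areas")
  fm <- fractions - mean(fractions)
  sum(fm * (areas - mean(areas))) / sum(fm^2)
}

#' Classify a peptide as blood-derived from its per-patient slopes
#'
#' A candidate is rejected when its regression slope against the spiked blood
#' fraction is positive in every patient; peptides showing no effect or
#' diminished levels in at least one patient are kept.
#'
#' @param slopes numeric vector, one fitted slope per patient
#' @param tolerance minimum slope that counts as "positive" (default 0,
#'   i.e. strictly greater than zero)
#' @return \code{"reject"} or \code{"keep"}
#' @export
classifyBloodDerived <- function(slopes, tolerance = 0) {
  if (length(slopes) < 1L || anyNA(slopes)) stop("missing patient slope")
  if (all(slopes > tolerance)) "reject" else "keep"
}

#' Screen a candidate panel against blood contamination
#'
#' Averages injection replicates per (patient, peptide, fraction), fits the
#' per-patient OLS slope of mean area on blood fraction, and classifies each
#' peptide via \code{\link{classifyBloodDerived}}.
#'
#' @param series blood spike-in data.frame with columns \code{patient},
#'   \code{peptide}, \code{fraction}, \code{replicate}, \code{area}
#' @param tolerance passed to \code{\link{classifyBloodDerived}}
#' @return data.frame with one row per peptide: per-patient slope columns
#'   (\code{slope_<patient>}) and a \code{decision} column
#' @export
bloodFilter <- function(series, tolerance = 0) {
  need <- c("patient", "peptide", "fraction", "replicate", "area")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("series missing columns: ", paste(miss, collapse = ", "))
  agg <- stats::aggregate(area ~ patient + peptide + fraction, data = series, FUN = mean)
  pats <- sort(unique(agg$patient))
  peps <- unique(series$peptide)
  slopes <- sapply(pats, function(pt) {
    vapply(peps, function(pp) {
      sub <- agg[agg$patient == pt & agg$peptide == pp, ]
      if (nrow(sub) == 0L) return(NA_real_)
      linearSlope(sub$fraction, sub$area)
    }, numeric(1))
  })
  slopes <- matrix(slopes, nrow = length(peps),
                   dimnames = list(peps, paste0("slope_", pats)))
  if (anyNA(slopes)) stop("missing patient series for some peptides")
  out <- data.frame(peptide = peps, slopes, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$decision <- apply(slopes, 1L, classifyBloodDerived, tolerance = tolerance)
  out
}
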