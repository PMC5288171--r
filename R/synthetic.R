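# Quartile of the standard normal at p = 0.75, used to convert printed
# interquartile ranges into log-normal parameters.
Z75 <- stats::qnorm(0.75)

# Evaluate expr under a derived seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed per operation label; stays below 2^31.
subSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (abs(seed) %% 1e6 * 2039 + h * 9973) %% 2147483629
}

#' Fit a log-normal distribution to printed quartiles
#'
#' Inverts a (Q1, Q3) pair into the unique log-normal with those quartiles:
#' \eqn{\mu = (\ln Q1 + \ln Q3)/2}, \eqn{\sigma = (\ln Q3 - \ln Q1)/(2
#' z_{0.75})} with \eqn{z_{0.75} = 0.6744898}. Used to turn the published
#' per-group interquartile ranges of light/heavy ratios into generative
#' distributions.
#'
#' @param q1,q3 25th and 75th percentiles; require \code{0 < q1 <= q3}.
#' @return object of class \code{LogNormalParams}: list with \code{meanlog}
#'   and \code{sdlog}.
#' @examples
#' p <- fitLognormalFromQuartiles(0.56, 2.18)
#' lognormalQuartiles(p)   # recovers c(0.56, 2.18)
#' @export
fitLognormalFromQuartiles <- function(q1, q3) {
  stopifnot(is.numeric(q1), is.numeric(q3), length(q1) == 1L, length(q3) == 1L)
  if (!is.finite(q1) || !is.finite(q3) || q1 <= 0 || q3 < q1)
    stop("quartiles must satisfy 0 < q1 <= q3")
  structure(list(meanlog = (log(q1) + log(q3)) / 2,
                 sdlog   = (log(q3) - log(q1)) / (2 * Z75)),
            class = "LogNormalParams")
}

#' @rdname fitLognormalFromQuartiles
#' @param params a \code{LogNormalParams} object
#' @export
lognormalQuartiles <- function(params) {
  exp(params$meanlog + c(-1, 1) * Z75 * params$sdlog)
}

#' @export
print.LogNormalParams <- function(x, ...) {
  cat(sprintf("LogNormalParams: meanlog = %.4f, sdlog = %.4f (Q1-Q3 %.3g-%.3g)\n",
              x$meanlog, x$sdlog, lognormalQuartiles(x)[1], lognormalQuartiles(x)[2]))
  invisible(x)
}

#' Validate a peptide panel for the cohort generator
#'
#' A peptide panel holds one row per target peptide with the group-wise
#' light/heavy ratio quartiles from which true sample ratios are drawn.
#'
#' @param panel data.frame with columns \code{protein}, \code{peptide},
#'   \code{tumor_q1}, \code{tumor_q3}, \code{control_q1}, \code{control_q3}
#'   and optionally logical \code{detectable} (default \code{TRUE};
#'   \code{FALSE} emulates peptides whose endogenous signal never rises
#'   above the detection floor).
#' @return the validated panel with a \code{detectable} column.
#' @export
peptidePanel <- function(panel) {
  panel <- as.data.frame(panel)
  need <- c("protein", "peptide", "tumor_q1", "tumor_q3", "control_q1", "control_q3")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$peptide)) stop("duplicate peptide sequences in panel")
  if (is.null(panel$detectable)) panel$detectable <- TRUE
  ok <- panel$tumor_q1 > 0 & panel$tumor_q3 >= panel$tumor_q1 &
        panel$control_q1 > 0 & panel$control_q3 >= panel$control_q1
  if (!all(ok))
    stop("invalid quartiles (need 0 < q1 <= q3) for peptide(s): ",
         paste(panel$peptide[!ok], collapse = ", "))
  panel
}

#' Default peptide panel emulating the verification study design
#'
#' Combines the 48 published significant peptides (quartiles from
#' \code{\link{table1Stats}}) with synthetic null proteins whose tumor and
#' control distributions coincide, reaching the study's scale of 52 proteins
#' and ~100 light/heavy pairs. Printed quartiles of 0.00 are floored at
#' \code{minQuartile} (the printed values are rounded to two decimals, so
#' 0.00 means "below 0.005").
#'
#' @param nNullProteins number of two-peptide null proteins to append
#' @param nullQ1,nullQ3 shared group quartiles of the null peptides
#' @param minQuartile floor applied to printed quartiles of 0.00
#' @return a validated peptide panel (see \code{\link{peptidePanel}})
#' @export
defaultPeptidePanel <- function(nNullProteins = 26, nullQ1 = 0.4, nullQ3 = 1.2,
                                minQuartile = 0.005) {
  tab <- table1Stats()
  sig <- data.frame(protein = tab$protein, peptide = tab$peptide,
                    tumor_q1 = pmax(tab$tumor_q1, minQuartile),
                    tumor_q3 = pmax(tab$tumor_q3, minQuartile),
                    control_q1 = pmax(tab$control_q1, minQuartile),
                    control_q3 = pmax(tab$control_q3, minQuartile),
                    stringsAsFactors = FALSE)
  if (nNullProteins > 0) {
    prot <- rep(sprintf("NUL%02d", seq_len(nNullProteins)), each = 2L)
    pep <- paste0(prot, c("_PEPA", "_PEPB"))
    nul <- data.frame(protein = prot, peptide = pep,
                      tumor_q1 = nullQ1, tumor_q3 = nullQ3,
                      control_q1 = nullQ1, control_q3 = nullQ3,
                      stringsAsFactors = FALSE)
    sig <- rbind(sig, nul)
  }
  peptidePanel(sig)
}

#' Cohort generator configuration
#'
#' Bundles the design of a simulated PRM verification cohort: group sizes,
#' full-process replicates, ions per precursor, the peptide panel, and the
#' noise/censoring model.
#'
#' @param peptideSpecs a peptide panel (see \code{\link{peptidePanel}})
#' @param nTumor,nControl group sample counts
#' @param nReplicates full-process preparation replicates per sample
#' @param nIons product ions monitored per precursor
#' @param heavyTotalArea expected summed heavy XIC area per injection
#'   (arbitrary area units)
#' @param prepCv multiplicative preparation noise, as a coefficient of
#'   variation (fraction; 0.036 emulates the reported average duplicate CV)
#' @param interferenceRate probability that a (sample, replicate, peptide)
#'   light measurement receives a single interfered ion
#' @param interferenceFactor multiplicative inflation of the interfered ion
#' @param lodFloor area below which a transition is flagged censored (kept in
#'   the table at its simulated value)
#' @param seed integer RNG seed
#' @return object of class \code{GeneratorConfig} (a validated list)
#' @export
generatorConfig <- function(peptideSpecs = defaultPeptidePanel(),
                            nTumor = 20L, nControl = 18L, nReplicates = 2L,
                            nIons = 5L, heavyTotalArea = 1e6, prepCv = 0.036,
                            interferenceRate = 0.02, interferenceFactor = 20,
                            lodFloor = 100, seed = 1L) {
  stopifnot(nTumor >= 1, nControl >= 1, nReplicates >= 1, nIons >= 1,
            prepCv >= 0, interferenceRate >= 0, interferenceRate <= 1,
            interferenceFactor > 1, lodFloor >= 0, heavyTotalArea > 0)
  structure(list(peptideSpecs = peptidePanel(peptideSpecs),
                 nTumor = as.integer(nTumor), nControl = as.integer(nControl),
                 nReplicates = as.integer(nReplicates), nIons = as.integer(nIons),
                 heavyTotalArea = heavyTotalArea, prepCv = prepCv,
                 interferenceRate = interferenceRate,
                 interferenceFactor = interferenceFactor,
                 lodFloor = lodFloor, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Generate a reference spectral library
#'
#' Draws, for each peptide, \code{nIons} strictly positive relative
#' product-ion intensities, sorted non-increasing and normalized to sum 1 —
#' the profile a matrix-free acquisition of the synthetic peptide mix would
#' yield.
#'
#' @param peptides character vector of peptide sequences, or a peptide panel
#' @param nIons ions per precursor (>= 4)
#' @param seed integer seed; identical seeds give identical libraries
#' @return a \code{\link{ReferenceLibrary}}
#' @export
generateReferenceLibrary <- function(peptides, nIons = 5L, seed = 1L) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  if (length(peptides) == 0L) stop("empty peptide list")
  if (nIons < 4L) stop("nIons must be >= 4")
  withSeed(subSeed(seed, "reflib"), {
    rel <- lapply(peptides, function(p) {
      v <- sort(stats::runif(nIons, min = 0.05, max = 1), decreasing = TRUE)
      v / sum(v)
    })
    ReferenceLibrary(data.frame(
      peptide = rep(peptides, each = nIons),
      ion = rep(sprintf("i%d", seq_len(nIons)), times = length(peptides)),
      relative_area = unlist(rel), stringsAsFactors = FALSE))
  })
}

#' Simulate a PRM verification cohort
#'
#' Generates the full long-format transition table of a tumor/control cohort.
#' For every (sample, peptide) one true light/heavy ratio is drawn from the
#' sample's group log-normal (shared by all preparation replicates of that
#' sample); heavy ion areas are \code{heavyTotalArea * p_i * eps} and light
#' ion areas \code{r * heavyTotalArea * p_i * eps'}, where \code{p_i} are the
#' reference relative intensities and \code{eps, eps'} are unit-mean
#' multiplicative log-normal preparation noises of coefficient of variation
#' \code{prepCv}, one per (sample, replicate, peptide, label). Single-ion
#' interference and below-floor censor flags are then applied per the
#' configuration. The drawn true ratios and interference coordinates are kept
#' in the provenance for parameter-recovery testing.
#'
#' @param config a \code{\link{generatorConfig}}
#' @param library a \code{\link{ReferenceLibrary}} covering every panel
#'   peptide; generated from \code{config} when \code{NULL}
#' @return a \code{\link{TransitionExperiment}}
#' @export
simulateCohort <- function(config, library = NULL) {
  stopifnot(inherits(config, "GeneratorConfig"))
  panel <- config$peptideSpecs
  if (is.null(library))
    library <- generateReferenceLibrary(panel$peptide, config$nIons, config$seed)
  sp <- refSpectra(library)
  miss <- setdiff(panel$peptide, sp$peptide)
  if (length(miss))
    stop("peptides absent from reference library: ", paste(miss, collapse = ", "))
  if (any(table(sp$peptide[sp$peptide %in% panel$peptide]) != config$nIons))
    stop("reference library ion count does not match config nIons")

  samp <- c(sprintf("T%02d", seq_len(config$nTumor)),
            sprintf("C%02d", seq_len(config$nControl)))
  grp <- rep(c("tumor", "control"), c(config$nTumor, config$nControl))
  nPep <- nrow(panel); nS <- length(samp)
  nIons <- config$nIons; nRep <- config$nReplicates

  withSeed(subSeed(config$seed, "cohort"), {
    ## one true ratio per (sample, peptide); sibling peptides of a protein
    ## share the sample's latent abundance draw so their ratios co-vary, as
    ## surrogates of one protein do
    truth <- expand.grid(sample = samp, peptide = panel$peptide,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$group <- grp[match(truth$sample, samp)]
    idx <- match(truth$peptide, panel$peptide)
    q1 <- ifelse(truth$group == "tumor", panel$tumor_q1[idx], panel$control_q1[idx])
    q3 <- ifelse(truth$group == "tumor", panel$tumor_q3[idx], panel$control_q3[idx])
    mu <- (log(q1) + log(q3)) / 2
    sg <- (log(q3) - log(q1)) / (2 * Z75)
    truth$protein <- panel$protein[idx]
    zkey <- unique(data.frame(sample = truth$sample, protein = truth$protein,
                              stringsAsFactors = FALSE))
    zkey$z <- stats::rnorm(nrow(zkey))
    z <- zkey$z[match(paste(truth$sample, truth$protein),
                      paste(zkey$sample, zkey$protein))]
    truth$true_ratio <- exp(mu + sg * z)

    ## measurement grid: sample x replicate x peptide x label
    meas <- expand.grid(sample = samp, replicate = seq_len(nRep),
                        peptide = panel$peptide, label = c("heavy", "light"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meas$group <- grp[match(meas$sample, samp)]
    meas$protein <- panel$protein[match(meas$peptide, panel$peptide)]
    s2 <- log(1 + config$prepCv^2)
    eps <- stats::rlnorm(nrow(meas), -s2 / 2, sqrt(s2))
    tkey <- paste(meas$sample, meas$peptide)
    r <- truth$true_ratio[match(tkey, paste(truth$sample, truth$peptide))]
    detect <- panel$detectable[match(meas$peptide, panel$peptide)]
    total <- ifelse(meas$label == "heavy", config$heavyTotalArea,
                    r * config$heavyTotalArea)
    ## undetectable peptides: endogenous signal pinned below the floor
    low <- meas$label == "light" & !detect
    total[low] <- config$lodFloor * 0.3

    ## expand to ions
    rec <- meas[rep(seq_len(nrow(meas)), each = nIons), ]
    rec$ion <- rep(sprintf("i%d", seq_len(nIons)), times = nrow(meas))
    pidx <- match(paste(rec$peptide, rec$ion), paste(sp$peptide, sp$ion))
    rec$area <- rep(total * eps, each = nIons) * sp$relative_area[pidx]
    rownames(rec) <- NULL
    rec <- rec[, c("sample", "group", "replicate", "protein", "peptide",
                   "label", "ion", "area")]
    rec$censored <- rec$area < config$lodFloor

    te <- TransitionExperiment(rec, provenance = list(
      config = config, library = library,
      truth = truth[, c("sample", "group", "peptide", "true_ratio")],
      interference = data.frame()))
    if (config$interferenceRate > 0)
      te <- injectInterference(te, config$interferenceRate,
                               config$interferenceFactor,
                               seed = subSeed(config$seed, "interf"))
    te
  })
}

#' Inject single-ion interference into light measurements
#'
#' For a Bernoulli(\code{rate}) subset of (sample, replicate, peptide) light
#' measurements, multiplies exactly one randomly chosen ion's area by
#' \code{factor}, emulating a co-eluting contaminant inflating one fragment
#' trace. Affected coordinates are appended to the provenance.
#'
#' @param te a \code{\link{TransitionExperiment}}
#' @param rate probability in [0,1] that a measurement is interfered
#' @param factor multiplicative inflation (> 1)
#' @param seed integer seed
#' @return the modified \code{TransitionExperiment}
#' @export
injectInterference <- function(te, rate, factor, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1, factor > 1)
  if (rate == 0) return(te)
  rec <- transitions(te)
  light <- rec$label == "light"
  key <- paste(rec$sample, rec$replicate, rec$peptide)
  meas <- unique(key[light])
  withSeed(subSeed(seed, "inject"), {
    hit <- meas[stats::runif(length(meas)) < rate]
    coords <- data.frame(sample = character(0), replicate = integer(0),
                         peptide = character(0), ion = character(0))
    for (m in hit) {
      rows <- which(light & key == m)
      j <- rows[sample.int(length(rows), 1L)]
      rec$area[j] <- rec$area[j] * factor
      coords <- rbind(coords, data.frame(
        sample = rec$sample[j], replicate = rec$replicate[j],
        peptide = rec$peptide[j], ion = rec$ion[j]))
    }
    prov <- provenance(te)
    if (!is.null(prov$config))
      rec$censored <- rec$area < prov$config$lodFloor
    prov$interference <- rbind(
      if (is.null(prov$interference)) data.frame() else prov$interference, coords)
    TransitionExperiment(rec, provenance = prov)
  })
}

#' Blood spike-in series configuration
#'
#' Design of the blood-contamination dilution experiment: aspirates of
#' \code{nPatients} patients split into aliquots spiked with increasing
#' volume fractions of whole blood, each injected \code{nReplicates} times.
#'
#' @param bloodFractions strictly increasing volume fractions in [0,1)
#' @param nPatients number of patients
#' @param nReplicates injections per aliquot
#' @param panel data.frame with columns \code{protein}, \code{peptide},
#'   logical \code{blood_derived}, and \code{profile} in
#'   \code{c("dilution","flat")} describing how a non-blood peptide responds
#'   to blood dilution; defaults to \code{\link{defaultBloodPanel}}
#' @param baseArea typical peptide area at 0\% blood (arbitrary units)
#' @param bloodGain relative slope of blood-derived peptides: their area is
#'   \code{a * (1 + bloodGain * f)} at blood fraction \code{f}
#' @param noiseCv multiplicative measurement noise (fraction)
#' @param seed integer seed
#' @return object of class \code{BloodSeriesConfig}
#' @export
bloodSeriesConfig <- function(bloodFractions = c(0, 0.10, 0.20, 0.40),
                              nPatients = 2L, nReplicates = 2L,
                              panel = defaultBloodPanel(),
                              baseArea = 1e5, bloodGain = 5, noiseCv = 0.05,
                              seed = 1L) {
  stopifnot(length(bloodFractions) >= 2, all(diff(bloodFractions) > 0),
            all(bloodFractions >= 0 & bloodFractions < 1),
            nPatients >= 1, nReplicates >= 1, noiseCv >= 0, bloodGain > 0)
  need <- c("protein", "peptide", "blood_derived", "profile")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("blood panel missing columns: ", paste(miss, collapse = ", "))
  structure(list(bloodFractions = bloodFractions, nPatients = as.integer(nPatients),
                 nReplicates = as.integer(nReplicates), panel = as.data.frame(panel),
                 baseArea = baseArea, bloodGain = bloodGain, noiseCv = noiseCv,
                 seed = as.integer(seed)),
            class = "BloodSeriesConfig")
}

#' Default blood-screening panel
#'
#' A candidate panel at the scale of the published blood screen: 129
#' peptides, 32 of which are blood-derived; non-blood peptides alternate
#' between the dilution and the flat response profile.
#'
#' @param nBlood,nOther counts of blood-derived and non-blood peptides
#' @return panel data.frame for \code{\link{bloodSeriesConfig}}
#' @export
defaultBloodPanel <- function(nBlood = 32L, nOther = 97L) {
  n <- nBlood + nOther
  pep <- sprintf("CAND%03d_PEP", seq_len(n))
  data.frame(protein = sprintf("CAND%03d", seq_len(n)), peptide = pep,
             blood_derived = rep(c(TRUE, FALSE), c(nBlood, nOther)),
             profile = rep_len(c("dilution", "flat"), n),
             stringsAsFactors = FALSE)
}

#' Simulate a blood spike-in dilution series
#'
#' Generates per-injection MS1 peptide areas across the blood-fraction
#' series. Blood-derived peptides increase linearly with blood fraction
#' (\code{a * (1 + bloodGain * f)}); non-blood peptides either dilute
#' (\code{a * (1 - f)}) or stay flat, matching the "no effect or diminished
#' levels" behaviours retained by the screen. Truth flags are carried in the
#' \code{truth} element for recovery tests.
#'
#' @param config a \code{\link{bloodSeriesConfig}}
#' @return list with \code{series} (data.frame: patient, peptide, fraction,
#'   replicate, area) and \code{truth} (the panel with its flags)
#' @export
simulateBloodSeries <- function(config) {
  stopifnot(inherits(config, "BloodSeriesConfig"))
  panel <- config$panel
  grid <- expand.grid(patient = sprintf("P%d", seq_len(config$nPatients)),
                      peptide = panel$peptide,
                      fraction = config$bloodFractions,
                      replicate = seq_len(config$nReplicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$peptide, panel$peptide)
  withSeed(subSeed(config$seed, "blood"), {
    ## per (patient, peptide) baseline abundance
    base_key <- unique(grid[, c("patient", "peptide")])
    base_key$a <- config$baseArea * stats::rlnorm(nrow(base_key), 0, 0.5)
    a <- base_key$a[match(paste(grid$patient, grid$peptide),
                          paste(base_key$patient, base_key$peptide))]
    mu <- ifelse(panel$blood_derived[i], a * (1 + config$bloodGain * grid$fraction),
          ifelse(panel$profile[i] == "dilution", a * (1 - grid$fraction), a))
    if (config$noiseCv > 0) {
      s2 <- log(1 + config$noiseCv^2)
      mu <- mu * stats::rlnorm(length(mu), -s2 / 2, sqrt(s2))
    }
    grid$area <- mu
    list(series = grid, truth = panel)
  })
}
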