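test_that("spectral contrast cosine matches hand computations", {
  ref <- c(90, 85, 55, 45, 25)
  expect_equal(spectralContrastCosine(ref, ref), 1)
  expect_equal(spectralContrastCosine(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0)), 0)
  # independent dot-product / norm computation
  expect_equal(spectralContrastCosine(c(100, 80, 60, 40, 20), ref),
               0.9956181, tolerance = 1e-6)
  expect_equal(spectralContrastCosine(rep(0, 5), ref), 0)
  expect_error(spectralContrastCosine(1:4, 1:5), "length")
  expect_error(spectralContrastCosine(c(-1, 1), c(1, 1)), "negative")
  expect_error(spectralContrastCosine(c(1, 1), c(0, 0)), "all zero")
})

test_that("cosine is bounded, proportional-iff-one, and scale invariant", {
  set.seed(7)
  for (i in 1:100) {
    x <- runif(5); r <- runif(5, 0.1, 1)
    s <- spectralContrastCosine(x, r)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(spectralContrastCosine(3.7 * x, r), s)
    expect_equal(spectralContrastCosine(x, 0.2 * r), s)
    expect_equal(spectralContrastCosine(5 * r, r), 1)
  }
})

test_that("background estimate halves the smallest accepted area", {
  rec <- expand.grid(sample = c("S1", "S2", "S3"), replicate = 1L,
                     label = "light", ion = "i1", stringsAsFactors = FALSE)
  rec$group <- "tumor"; rec$protein <- "P"; rec$peptide <- "PEP"
  rec$area <- c(10, 20, 50); rec$censored <- FALSE
  te <- TransitionExperiment(rec)
  expect_equal(unname(estimateBackground(te, "PEP", "light", lodFloor = 1)), 5)

  rec$censored <- TRUE
  te <- TransitionExperiment(rec)
  expect_equal(unname(estimateBackground(te, "PEP", "light", lodFloor = 8)), 4)

  # a censored value below every accepted one is ignored
  rec$censored <- c(TRUE, FALSE, FALSE); rec$area <- c(2, 20, 50)
  te <- TransitionExperiment(rec)
  expect_equal(unname(estimateBackground(te, "PEP", "light", lodFloor = 5)), 10)

  expect_error(estimateBackground(te, "NOPE"), "unknown peptide")
})

test_that("QC cascade resolves interference by 4-ion substitution", {
  ref <- setNames(c(90, 85, 55, 45, 25) / 300, paste0("i", 1:5))
  heavy <- c(90, 85, 55, 45, 25) * 100
  clean <- evaluateMeasurement(heavy * 0.5, heavy, ref)
  expect_equal(clean$status, "accepted")
  expect_length(clean$ionsUsed, 5)

  light <- c(100, 80, 60, 40, 2000)
  ev <- evaluateMeasurement(light, heavy, ref)
  expect_equal(ev$status, "accepted_after_substitution")
  expect_equal(ev$ionsUsed, paste0("i", 1:4))
  # recomputed cosines frozen from brute-force hand computation
  expect_equal(ev$cosLight, 0.9962552, tolerance = 1e-6)
  expect_equal(sum(ev$lightUsed), 280)

  # all-floor light trace goes to background imputation
  bg <- setNames(rep(2.5, 5), paste0("i", 1:5))
  low <- evaluateMeasurement(rep(1, 5), heavy, ref, background = bg,
                             lodCriterion = 25)
  expect_equal(low$status, "below_lod")
  expect_true(low$backgroundSubstituted)
  expect_equal(low$lightUsed, rep(2.5, 5))

  expect_error(evaluateMeasurement(1:4, 1:5, setNames(1:5, paste0("i", 1:5))),
               "misaligned")
})

test_that("QC statuses partition the measurements of a simulated cohort", {
  cfg <- generatorConfig(smallPanel(), nTumor = 5, nControl = 5,
                         interferenceRate = 0.2, seed = 21)
  te <- simulateCohort(cfg)
  qc <- runSpectralQC(te, provenance(te)$library)
  expect_equal(nrow(qc), 10 * 2 * 6)
  expect_true(all(qc$status %in% c("accepted", "accepted_after_substitution",
                                   "below_lod", "unresolved")))
  sm <- qcSummary(qc)
  expect_equal(sm$fraction_matched + sm$fraction_below_lod +
               sm$fraction_unresolved, 1)
})

test_that("substitution restores interfered ratios to the interference-free truth", {
  cfg <- generatorConfig(smallPanel()[1:4, ], nTumor = 10, nControl = 10,
                         prepCv = 0.036, interferenceRate = 0.5,
                         interferenceFactor = 20, lodFloor = 0, seed = 31)
  te <- simulateCohort(cfg)
  hit <- provenance(te)$interference
  qc <- runSpectralQC(te, provenance(te)$library)
  qkey <- paste(qc$sample, qc$replicate, qc$peptide)
  hkey <- paste(hit$sample, hit$replicate, hit$peptide)
  st <- qc$status[match(hkey, qkey)]
  expect_gte(mean(st == "accepted_after_substitution"), 0.99)

  # recomputed ratios near the replicate's interference-free value
  rr <- computeRatios(qc)
  rec <- transitions(te)
  for (i in seq_len(nrow(hit))) {
    sub <- rec[rec$sample == hit$sample[i] & rec$replicate == hit$replicate[i] &
               rec$peptide == hit$peptide[i], ]
    li <- sub$area[sub$label == "light"]
    li[sub$ion[sub$label == "light"] == hit$ion[i]] <-
      li[sub$ion[sub$label == "light"] == hit$ion[i]] / 20
    free <- sum(li) / sum(sub$area[sub$label == "heavy"])
    got <- rr$ratio[rr$sample == hit$sample[i] & rr$replicate == hit$replicate[i] &
                    rr$peptide == hit$peptide[i]]
    expect_equal(got, free, tolerance = 0.02)
  }
})

test_that("LOD-based peptide removal counts samples, not replicates, strictly", {
  mk <- function(nBelow, nSamples = 38) {
    expand.grid(sample = sprintf("S%02d", 1:nSamples), replicate = 1:2,
                stringsAsFactors = FALSE) |>
      transform(peptide = "PEP", status = ifelse(
        as.integer(sub("S", "", sample)) <= nBelow, "below_lod", "accepted"))
  }
  expect_equal(filterPeptidesByLod(mk(20))$removed, "PEP")   # 20/38 > 0.5
  expect_equal(filterPeptidesByLod(mk(19))$removed, character(0))  # exactly 0.5
  # below-LOD in one replicate only does not count the sample
  qc <- mk(20)
  qc$status[qc$replicate == 2] <- "accepted"
  expect_equal(filterPeptidesByLod(qc)$removed, character(0))
})

test_that("MS1 TIC check flags gross outliers and is scale invariant", {
  expect_false(any(ms1TicCheck(rep(5, 10))))
  tic <- c(rep(1, 9), 10)
  expect_identical(unname(ms1TicCheck(tic, k = 5)), c(rep(FALSE, 9), TRUE))
  set.seed(12)
  for (i in 1:20) {
    v <- rlnorm(10, 10, 0.2)
    expect_identical(ms1TicCheck(v), ms1TicCheck(v * 137.5))
  }
  expect_error(ms1TicCheck(c(1, 2)), "3 samples")
})
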