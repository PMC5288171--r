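test_that("log-normal fit inverts printed quartiles", {
  # degenerate spread
  p <- fitLognormalFromQuartiles(2, 2)
  expect_equal(p$meanlog, log(2))
  expect_equal(p$sdlog, 0)
  # closed form checked by reconstructing exp(mu +/- z75 * sigma)
  p <- fitLognormalFromQuartiles(0.56, 2.18)
  expect_equal(p$meanlog, 0.09975, tolerance = 1e-4)
  expect_equal(p$sdlog, 1.00750, tolerance = 1e-4)
  expect_equal(lognormalQuartiles(p), c(0.56, 2.18), tolerance = 1e-12)
  p <- fitLognormalFromQuartiles(0.04, 0.13)
  expect_equal(p$meanlog, -2.6296, tolerance = 1e-4)
  expect_equal(p$sdlog, 0.8737, tolerance = 1e-4)

  expect_error(fitLognormalFromQuartiles(0, 1), "quartiles")
  expect_error(fitLognormalFromQuartiles(2, 1), "quartiles")
  expect_error(fitLognormalFromQuartiles(-1, 1), "quartiles")
})

test_that("quartile round-trip is the identity for random valid pairs", {
  set.seed(42)
  for (i in 1:200) {
    q1 <- exp(runif(1, -5, 3))
    q3 <- q1 * exp(runif(1, 0, 3))
    q <- lognormalQuartiles(fitLognormalFromQuartiles(q1, q3))
    expect_lt(max(abs(q - c(q1, q3)) / c(q1, q3)), 1e-9)
  }
})

test_that("reference library generation is normalized, shaped, deterministic", {
  lib <- generateReferenceLibrary("PEPTIDEK", nIons = 5, seed = 3)
  expect_equal(sum(refSpectra(lib)$relative_area), 1)
  lib2 <- generateReferenceLibrary("PEPTIDEK", nIons = 5, seed = 3)
  expect_identical(refSpectra(lib), refSpectra(lib2))

  peps <- sprintf("PEP%03dK", 1:100)
  lib <- generateReferenceLibrary(peps, nIons = 5, seed = 1)
  sp <- refSpectra(lib)
  expect_equal(nrow(sp), 500)
  expect_true(all(sp$relative_area > 0))
  # non-increasing within each peptide
  for (pp in peps[1:5])
    expect_false(is.unsorted(rev(sp$relative_area[sp$peptide == pp])))

  expect_error(generateReferenceLibrary(character(0)), "empty")
  expect_error(generateReferenceLibrary("A", nIons = 3), ">= 4")
})

test_that("noise-free cohort measurements reproduce true ratios exactly", {
  cfg <- generatorConfig(smallPanel(), nTumor = 3, nControl = 3,
                         prepCv = 0, interferenceRate = 0, lodFloor = 0,
                         seed = 11)
  te <- simulateCohort(cfg)
  rec <- transitions(te)
  truth <- provenance(te)$truth
  key <- paste(rec$sample, rec$replicate, rec$peptide)
  for (k in unique(key)) {
    sub <- rec[key == k, ]
    r <- sum(sub$area[sub$label == "light"]) / sum(sub$area[sub$label == "heavy"])
    tr <- truth$true_ratio[truth$sample == sub$sample[1] &
                           truth$peptide == sub$peptide[1]]
    expect_equal(r, tr, tolerance = 1e-12)
  }
})

test_that("default cohort has the full factorial record grid and is deterministic", {
  te <- simulateCohort(generatorConfig(seed = 5))
  rec <- transitions(te)
  # 38 samples x 2 replicates x 100 peptides x 2 labels x 5 ions
  expect_equal(nrow(rec), 38 * 2 * 100 * 2 * 5)
  expect_equal(length(unique(rec$sample)), 38)
  expect_setequal(unique(rec$group), c("tumor", "control"))
  te2 <- simulateCohort(generatorConfig(seed = 5))
  expect_identical(transitions(te), transitions(te2))
})

test_that("true-ratio draws converge to the configured group quartiles", {
  pan <- peptidePanel(data.frame(protein = "PERM", peptide = "IANVFTNAFR",
                                 tumor_q1 = 0.56, tumor_q3 = 2.18,
                                 control_q1 = 0.04, control_q3 = 0.13))
  cfg <- generatorConfig(pan, nTumor = 10000, nControl = 10000,
                         nReplicates = 1, interferenceRate = 0, seed = 8)
  truth <- provenance(simulateCohort(cfg))$truth
  tq <- quantile(truth$true_ratio[truth$group == "tumor"], c(.25, .5, .75))
  cq <- quantile(truth$true_ratio[truth$group == "control"], c(.25, .5, .75))
  expect_equal(unname(tq[c(1, 3)]), c(0.56, 2.18), tolerance = 0.05)
  expect_equal(unname(cq[c(1, 3)]), c(0.04, 0.13), tolerance = 0.05)
  # group median within 2% of exp(mu)
  expect_equal(unname(tq[2]), exp(fitLognormalFromQuartiles(0.56, 2.18)$meanlog),
               tolerance = 0.02)
  expect_equal(unname(cq[2]), exp(fitLognormalFromQuartiles(0.04, 0.13)$meanlog),
               tolerance = 0.02)
})

test_that("interference injection hits the configured fraction of light measurements", {
  cfg <- generatorConfig(smallPanel(), nTumor = 4, nControl = 4,
                         interferenceRate = 0, seed = 2)
  te <- simulateCohort(cfg)

  te0 <- injectInterference(te, rate = 0, factor = 20)
  expect_identical(transitions(te0), transitions(te))

  te1 <- injectInterference(te, rate = 1, factor = 20, seed = 4)
  rec0 <- transitions(te)
  rec1 <- transitions(te1)
  changed <- rec0$area != rec1$area
  expect_true(all(rec0$label[changed] == "light"))
  # exactly one inflated ion per light measurement
  key <- paste(rec0$sample, rec0$replicate, rec0$peptide)[changed]
  expect_equal(sort(unique(table(key))), 1)
  expect_equal(length(unique(key)),
               nrow(unique(rec0[rec0$label == "light",
                                c("sample", "replicate", "peptide")])))
  expect_equal(rec1$area[changed], 20 * rec0$area[changed])

  # binomial expectation on a larger grid
  cfgB <- generatorConfig(defaultPeptidePanel(), interferenceRate = 0, seed = 3)
  teB <- simulateCohort(cfgB)
  teB <- injectInterference(teB, rate = 0.05, factor = 20, seed = 9)
  nMeas <- 38 * 2 * 100
  hits <- nrow(provenance(teB)$interference)
  expect_lt(abs(hits - 0.05 * nMeas), 3 * sqrt(nMeas * 0.05 * 0.95))
})

test_that("blood series profiles are monotone without noise and flags round-trip", {
  cfg <- bloodSeriesConfig(noiseCv = 0, seed = 6)
  sim <- simulateBloodSeries(cfg)
  agg <- aggregate(area ~ patient + peptide + fraction, sim$series, mean)
  truth <- sim$truth
  for (pp in truth$peptide[c(1, 40, 41)]) {   # one blood, one dilution, one flat
    a <- agg[agg$patient == "P1" & agg$peptide == pp, ]
    a <- a[order(a$fraction), ]
    if (truth$blood_derived[truth$peptide == pp]) {
      expect_true(all(diff(a$area) > 0))
    } else if (truth$profile[truth$peptide == pp] == "dilution") {
      expect_true(all(diff(a$area) < 0))
    } else {
      expect_equal(diff(a$area), rep(0, 3))
    }
  }
  dec <- bloodFilter(sim$series)
  expect_identical(dec$decision == "reject",
                   truth$blood_derived[match(dec$peptide, truth$peptide)])
})

test_that("generator config and panel validation reject invalid inputs", {
  expect_error(generatorConfig(smallPanel(), prepCv = -1))
  expect_error(generatorConfig(smallPanel(), interferenceRate = 2))
  expect_error(generatorConfig(smallPanel(), interferenceFactor = 1))
  bad <- smallPanel(); bad$tumor_q1[1] <- 5   # q1 > q3
  expect_error(peptidePanel(bad), "invalid quartiles")
  # library mismatch
  cfg <- generatorConfig(smallPanel(), seed = 1)
  lib <- generateReferenceLibrary("OTHERPEPTIDE", seed = 1)
  expect_error(simulateCohort(cfg, lib), "absent")
})
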