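test_that("Mann-Whitney U counts tumor-over-control pairs with midrank ties", {
  expect_equal(mannWhitney(c(5, 6, 7), c(1, 2, 3))$U, 9)
  mw <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw$U, 4.5)            # n1 n2 / 2 under exchangeability
  expect_gt(mw$p, 0.9)
  expect_equal(mannWhitney(c(1, 3, 5), c(2, 4, 6))$U, 3)  # brute-force pair count
  expect_error(mannWhitney(numeric(0), 1:3), "empty group")

  set.seed(8)
  for (i in 1:50) {
    x <- sample(1:6, 7, replace = TRUE); y <- sample(1:6, 5, replace = TRUE)
    expect_equal(mannWhitney(x, y)$U, uOracle(x, y))
  }
})

test_that("AUC equals U/(n1 n2), flips under label exchange, respects shifts", {
  expect_equal(aucStat(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(aucStat(1:5, 1:5), 0.5)
  expect_equal(aucStat(c(1, 3, 5), c(2, 4, 6)), 3 / 9)
  set.seed(9)
  for (i in 1:100) {
    x <- sample(1:8, 6, replace = TRUE); y <- sample(1:8, 9, replace = TRUE)
    a <- aucStat(x, y)
    expect_equal(a, aucOracle(x, y))
    expect_equal(a + aucStat(y, x), 1)
    expect_gte(aucStat(x + runif(1, 0, 3), y), a)   # monotone in tumor shift
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:20) {
    x <- rlnorm(20, 1, 1); y <- rlnorm(18, 0, 1)
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(c(rep(1, 20), rep(0, 18)), c(x, y), quiet = TRUE,
                          levels = c(0, 1), direction = "<"))))
    expect_equal(aucStat(x, y), ref, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bhOracle(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))   # order-preserving
  }
})

test_that("fold change is the ratio of group central values", {
  expect_equal(foldChange(1:5, 1:5), 1)
  expect_equal(foldChange(c(2, 4, 6), c(1, 2, 3)), 2)
  x <- c(2, 4, 6)
  expect_equal(foldChange(2 * x, c(1, 2, 3)), 2 * foldChange(x, c(1, 2, 3)))
  expect_equal(foldChange(c(1, 10), c(1, 3), method = "mean"), 5.5 / 2)
  expect_error(foldChange(1:3, c(0, 0, 0)), "unquantifiable")
})

test_that("ROC operating points: Youden with specificity tie-break, fixed-spec sweep", {
  sep <- rocOperatingPoints(c(5, 6, 7), c(1, 2, 3))
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)
  expect_equal(sep$sens_at_fixed_spec, 100)

  same <- rocOperatingPoints(rep(1:6, 3), rep(1:6, 3))
  expect_lte(same$sens_at_fixed_spec, 100 / 18)

  # exhaustive hand sweep: Youden ties at J=0.5 resolved to threshold 4.5
  op <- rocOperatingPoints(c(3, 4, 5, 6), c(1, 2, 3, 4))
  expect_equal(op$sensitivity, 50)
  expect_equal(op$specificity, 100)
  expect_equal(op$threshold, 4.5)
})

test_that("the significance gate is strict on both conditions", {
  res <- data.frame(peptide = c("a", "b", "c"),
                    p_adj = c(0.04, 0.04, 0.05), fc = c(3.5, 3.0, 10))
  sig <- selectSignificant(res)
  expect_equal(sig$peptide, "a")
})

test_that("group comparison assembles the verification table", {
  set.seed(14)
  ratio <- rbind(UP_PEP = c(rlnorm(10, 2, 0.3), rlnorm(8, 0, 0.3)),
                 NULL_PEP = rlnorm(18, 0, 0.3))
  colnames(ratio) <- sprintf("S%02d", 1:18)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = ratio, cv = ratio * 0),
    rowData = S4Vectors::DataFrame(protein = c("UP", "NULL")),
    colData = S4Vectors::DataFrame(group = rep(c("tumor", "control"), c(10, 8)),
                                   row.names = colnames(ratio)))
  res <- compareGroups(se)
  expect_setequal(res$peptide, c("UP_PEP", "NULL_PEP"))
  up <- res[res$peptide == "UP_PEP", ]
  expect_true(up$significant)
  expect_gt(up$auc, 0.95)
  expect_equal(up$tumor_q1, unname(quantile(ratio[1, 1:10], 0.25)))
  expect_false(res$significant[res$peptide == "NULL_PEP"])
  expect_true(all(res$p_adj >= res$p))
})
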