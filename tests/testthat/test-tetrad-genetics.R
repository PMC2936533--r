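test_that("enumeration matches an independent brute-force oracle for every carriage", {
  for (carriers in 0:4) {
    for (mode in c("inter_spore", "self")) {
      expected <- brute_mode_probs(carriers, mode)
      got <- enumerateMatingOutcomes(carriers, mode)
      expect_equal(as.numeric(got), as.numeric(expected), tolerance = 1e-12,
                   info = paste("carriers", carriers, mode))
      # exact rational bookkeeping is self-consistent
      expect_identical(sum(attr(got, "numerators")),
                       attr(got, "denominator"))
    }
  }
  # landmark values: a 2:2 mutation under pure inter-spore mating
  expect_equal(as.numeric(enumerateMatingOutcomes(2, "inter_spore")),
               c(1 / 6, 2 / 3, 1 / 6))
  expect_equal(unname(enumerateMatingOutcomes(0, "inter_spore")[["lost"]]), 1)
  expect_equal(unname(enumerateMatingOutcomes(4, "self")[["fixed"]]), 1)
})

test_that("MAT-pair and any-pair inter-spore mating are equivalent for unlinked mutations", {
  for (carriers in 0:4) {
    expect_equal(
      as.numeric(enumerateMatingOutcomes(carriers, "inter_spore", "mat_pairs")),
      as.numeric(enumerateMatingOutcomes(carriers, "inter_spore", "any_pair")),
      tolerance = 1e-12)
  }
})

test_that("analytic fate probabilities equal the enumeration mixture at every s", {
  for (s in seq(0, 1, by = 0.1)) {
    for (carriers in 1:2) {
      got <- analyticFateProbs(carriers, s)
      expect_equal(as.numeric(got), as.numeric(brute_fate_probs(carriers, s)),
                   tolerance = 1e-12, info = paste("carriers", carriers, "s", s))
      expect_equal(sum(got), 1, tolerance = 1e-12)
      expect_true(all(got >= 0 & got <= 1))
    }
    # 2:2 segregation is symmetric: P_F = P_L
    p2 <- analyticFateProbs(2, s)
    expect_equal(p2[["pFix"]], p2[["pLoss"]], tolerance = 1e-12)
  }
})

test_that("fate probability landmarks hold", {
  expect_equal(as.numeric(analyticFateProbs(2, 0)), c(1 / 6, 2 / 3, 1 / 6))
  expect_equal(as.numeric(analyticFateProbs(2, 1)), c(1 / 2, 0, 1 / 2))
  expect_equal(as.numeric(analyticFateProbs(1, 0)), c(0, 1 / 2, 1 / 2))
  expect_equal(analyticFateProbs(2, 0.17)[["pHet"]], 0.83 * 2 / 3,
               tolerance = 1e-12)
  expect_error(analyticFateProbs(3, 0.1), "unsupported carriage")
  expect_error(analyticFateProbs(2, 1.2), "probability")
})

test_that("resolution probability over n meioses follows 1 - ((1-s) 2/3)^n", {
  # landmark: >99% resolved after nine bottlenecks at s = 0.17
  expect_gt(fixOrLossProbAfterN(9, 0.17), 0.99)
  expect_equal(fixOrLossProbAfterN(9, 0.17), 1 - (2 / 3 * 0.83)^9)
  expect_equal(fixOrLossProbAfterN(0, 0.17), 0)
  expect_equal(fixOrLossProbAfterN(1, 0.17), 1 - 0.83 * 2 / 3,
               tolerance = 1e-12)
  # identity with the single-meiosis heterozygosity probability
  for (s in c(0, 0.17, 0.5, 1)) {
    pH <- analyticFateProbs(2, s)[["pHet"]]
    expect_equal(fixOrLossProbAfterN(0:6, s), 1 - pH^(0:6), tolerance = 1e-12)
  }
  # monotone non-decreasing in n
  expect_true(!is.unsorted(fixOrLossProbAfterN(0:30, 0.17)))
  expect_error(fixOrLossProbAfterN(-1, 0.17), "non-negative")
})

test_that("Perkins distance reproduces hand-computed values and scaling invariance", {
  expect_equal(perkinsDistance(tetradClassCounts(100, 0, 0)), 0)
  expect_equal(perkinsDistance(tetradClassCounts(0, 100, 0)), 50)
  expect_equal(perkinsDistance(tetradClassCounts(95, 4, 1)), 5.0)
  for (k in c(2L, 7L)) {
    expect_equal(perkinsDistance(tetradClassCounts(95L * k, 4L * k, 1L * k)),
                 perkinsDistance(tetradClassCounts(95, 4, 1)))
  }
  expect_error(perkinsDistance(tetradClassCounts(0, 0, 0)), "empty")
  expect_error(tetradClassCounts(-1, 5, 0))
})

test_that("crossover correction solves the misclassification model", {
  corr <- correctMatingFrequencies(0.82, 0.18, rf = 0.01)
  expect_equal(round(100 * corr$fInter), 83)
  expect_equal(round(100 * corr$fSelf), 17)
  expect_equal(corr$fSelf, (0.18 - 0.01) / 0.99, tolerance = 1e-12)
  # rf = 0 is the identity
  ident <- correctMatingFrequencies(0.7, 0.3, rf = 0)
  expect_equal(ident$fSelf, 0.3)
  # observed self at the misclassification floor collapses to s = 0
  floor <- correctMatingFrequencies(0.99, 0.01, rf = 0.01)
  expect_equal(floor$fSelf, 0)
  expect_true(floor$atFloor)
  expect_warning(correctMatingFrequencies(0.995, 0.005, rf = 0.01),
                 "floor")
  expect_error(correctMatingFrequencies(0.9, 0.2, rf = 0.01), "equal 1")
  expect_error(correctMatingFrequencies(0.8, 0.2, rf = 0.6), "0.5")
})

test_that("tetrad class counts round-trip through TSV", {
  x <- tetradClassCounts(95, 4, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTetradClasses(x, path)
  y <- readTetradClasses(path)
  expect_equal(c(y@pd, y@tt, y@npd), c(95L, 4L, 1L))
  expect_equal(perkinsDistance(y), 5.0)
})
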