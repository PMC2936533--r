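test_that("rate estimators reproduce the printed per-line rates at 2 s.f.", {
  expect_equal(signif(mutationRate(vegetativeRateFromSpore(8, g = 1740)), 2),
               3.8e-10)
  expect_equal(signif(mutationRate(vegetativeRateFromSpore(6, g = 1740)), 2),
               2.8e-10)
  expect_equal(signif(mutationRate(vegetativeRateFromDiploid(5, g = 1040)), 2),
               2.0e-10)
  expect_equal(signif(mutationRate(meioticLineRate(5)), 2), 3.9e-10)
  # zero counts give zero rates
  expect_equal(mutationRate(vegetativeRateFromSpore(0, g = 1740)), 0)
  expect_equal(mutationRate(meioticLineRate(0)), 0)
})

test_that("rate estimators are linear in k and inverse in G and g", {
  r1 <- mutationRate(vegetativeRateFromDiploid(5, g = 1040))
  expect_equal(mutationRate(vegetativeRateFromDiploid(10, g = 2080)), r1)
  expect_equal(mutationRate(vegetativeRateFromDiploid(10, g = 1040)), 2 * r1)
  expect_equal(mutationRate(vegetativeRateFromDiploid(
    5, G = yeastDiploidGenomeSize / 2, g = 1040)), 2 * r1)
  # spore correction doubles relative to diploid at equal inputs
  expect_equal(mutationRate(vegetativeRateFromSpore(5, g = 1040)), 2 * r1)
  # optional coverage adjustment inflates the rate by 1/coverage
  expect_equal(mutationRate(vegetativeRateFromSpore(8, g = 1740,
                                                    coverage = 0.96)),
               mutationRate(vegetativeRateFromSpore(8, g = 1740)) / 0.96)
  expect_error(vegetativeRateFromSpore(3, g = 0), "positive")
  expect_error(vegetativeRateFromSpore(-1, g = 100), "non-negative")
})

test_that("average rate reproduces the printed 2.9e-10 under printed arithmetic", {
  ests <- list(vegetativeRateFromSpore(8, g = 1740),
               vegetativeRateFromSpore(6, g = 1740),
               vegetativeRateFromDiploid(5, g = 1040))
  expect_equal(averageRate(ests), 2.845e-10, tolerance = 1e-3)
  expect_equal(signif(averageRate(ests, sigfigs = 2), 2), 2.9e-10)
  one <- list(meioticLineRate(5))
  expect_equal(averageRate(one), mutationRate(one[[1]]))
  same <- list(meioticLineRate(5), meioticLineRate(5))
  expect_equal(averageRate(same), mutationRate(same[[1]]))
  expect_error(averageRate(list()), "empty")
})

test_that("in-del bound reproduces the printed homopolymeric-tract limit", {
  expect_equal(signif(indelRateBound(154850, 1740), 2), 3.7e-9)
  expect_equal(indelRateBound(1, 1), 1)
  expect_lt(indelRateBound(1e12, 1740), 1e-15)
  expect_error(indelRateBound(0, 1740), "positive")
})

test_that("lower-tail empirical P-value is inclusive and matches the Poisson law", {
  degenerate <- simulateEnsemble(simConfigNew(m = 0, muMultiplier = 0,
                                              nReplicates = 100, seed = 1))
  expect_equal(ensemblePValue(degenerate, 0), 1)
  ens <- simulateEnsemble(simConfigNew(nReplicates = 5000, seed = 13))
  expect_equal(ensemblePValue(ens, max(finalHom(ens))), 1)
  # fate thinning of Poisson inputs makes the final hom count exactly Poisson
  lam <- expected_final_counts(2.9e-10, yeastDiploidGenomeSize, 20, 50,
                               0.17)[["hom"]]
  pExact <- stats::ppois(5, lam)
  expect_equal(pExact, 0.865, tolerance = 0.005)
  p <- ensemblePValue(ens, 5)
  expect_lt(abs(p - pExact), 3 * sqrt(pExact * (1 - pExact) / 5000))
  # inclusiveness: observed = 5 counts replicates with exactly 5
  expect_gt(ensemblePValue(ens, 5), ensemblePValue(ens, 4))
})

test_that("P-values decrease as the meiotic rate grows", {
  ps <- vapply(c(0, 25, 50, 80), function(mult) {
    ensemblePValue(simulateEnsemble(simConfigNew(
      muMultiplier = mult, nReplicates = 3000, seed = 700 + mult)), 5)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0.02))  # monotone within Monte-Carlo error
  expect_lt(ps[4], ps[1])
})

test_that("the upper-limit scan brackets the alpha crossing", {
  base <- simConfigNew(nReplicates = 1500, seed = 5)
  # single-point grid at mu = 0 is consistent with the observations
  s0 <- scanUpperLimit(base, multipliers = 0, observedHom = 5, refine = FALSE)
  expect_gt(pValues(s0)[1], 0.8)
  expect_equal(s0@largestConsistent, 0)
  expect_true(is.na(s0@smallestInconsistent))
  # a wide coarse grid finds the crossing and refines it to step 1
  scan <- scanUpperLimit(base, multipliers = seq(0, 120, by = 10),
                         observedHom = 5, alpha = 0.05)
  expect_equal(length(pValues(scan)), length(multipliers(scan)))
  expect_false(is.na(scan@smallestInconsistent))
  expect_false(is.na(scan@largestConsistent))
  expect_true(any(diff(multipliers(scan)) == 1))  # refinement happened
  expect_equal(scan@smallestInconsistent,
               min(multipliers(scan)[pValues(scan) < 0.05]))
  expect_equal(scan@largestConsistent,
               max(multipliers(scan)[pValues(scan) >= 0.05]))
  expect_equal(scan@muMax, scan@largestConsistent * base@m)
  # alpha so small nothing is inconsistent: the largest grid value is returned
  lax <- scanUpperLimit(base, multipliers = c(0, 10), observedHom = 5,
                        alpha = 1e-6, refine = FALSE)
  expect_equal(lax@largestConsistent, 10)
  expect_error(scanUpperLimit(base, multipliers = numeric(0)), "empty")
  expect_error(scanUpperLimit(simConfigNew(scenario = "vegetative_only",
                                           nReplicates = 10)),
               "meiotic")
})
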