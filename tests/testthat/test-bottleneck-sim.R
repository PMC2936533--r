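test_that("mutation draws have the Poisson means implied by rate x genome x divisions", {
  cfg <- simConfigNew(nReplicates = 1)
  set.seed(42)
  n <- 40000
  # one bottleneck's worth of mitotic divisions: mean 20 * m * G = 0.142
  draws <- drawMitoticMutations(cfg, nDivisions = 20, n = n)
  lam <- 20 * cfg@m * cfg@genomeSize
  expect_equal(lam, 0.142, tolerance = 0.002)
  expect_lt(abs(mean(draws) - lam), 3 * sqrt(lam / n))
  # the whole vegetative design: 1740 divisions, mean 12.4
  lamB <- 1740 * cfg@m * cfg@genomeSize
  expect_equal(lamB, 12.35, tolerance = 0.005)
  drawsB <- drawMitoticMutations(cfg, nDivisions = 1740, n = n)
  expect_lt(abs(mean(drawsB) - lamB), 3 * sqrt(lamB / n))
  # meiotic draws at 30x the mitotic rate: mean 0.213 per meiosis
  cfg30 <- simConfigNew(muMultiplier = 30, nReplicates = 1)
  set.seed(1)
  drawsM <- drawMeioticMutations(cfg30, n = n)
  lamM <- 30 * cfg30@m * cfg30@genomeSize
  expect_equal(lamM, 0.213, tolerance = 0.002)
  expect_lt(abs(mean(drawsM) - lamM), 3 * sqrt(lamM / n))
  expect_equal(attr(drawsM, "carriage"), 2L)
  post <- simConfigNew(scenario = "post_replication", nReplicates = 1)
  set.seed(1)
  expect_equal(attr(drawMeioticMutations(post), "carriage"), 1L)
  # zero rates draw nothing
  zero <- simConfigNew(m = 0, nReplicates = 1)
  expect_true(all(drawMitoticMutations(zero, n = 100) == 0))
  expect_error(drawMeioticMutations(simConfigNew(scenario = "vegetative_only",
                                                 nReplicates = 1)),
               "not applicable")
})

test_that("single meiotic bottlenecks resolve lines as the tetrad model dictates", {
  cfg <- simConfigNew(nReplicates = 1)
  empty <- new("LineState", nHet = 0L, nFixed = 0L, bottleneckIndex = 3L,
               nGenerated = 0L, nLost = 0L)
  set.seed(1)
  out <- applyMeioticBottleneck(empty, cfg)
  expect_equal(out@bottleneckIndex, 4L)
  expect_equal(out@nHet, 0L)
  expect_equal(out@nFixed, 0L)
  # s = 1: self-mating resolves every heterozygous mutation immediately
  s1 <- simConfigNew(s = 1, nReplicates = 1)
  line <- new("LineState", nHet = 40L, nFixed = 0L, bottleneckIndex = 0L,
              nGenerated = 40L, nLost = 0L)
  set.seed(2)
  res <- applyMeioticBottleneck(line, s1)
  expect_equal(res@nHet, 0L)
  expect_equal(res@nFixed + res@nLost, 40L)
})

test_that("degenerate simulator configurations are exact no-ops", {
  zero <- simConfigNew(m = 0, muMultiplier = 0, nReplicates = 50, seed = 5)
  ens <- simulateEnsemble(zero)
  expect_true(all(finalHom(ens) == 0L) && all(finalHet(ens) == 0L))
  # zero divisions per bottleneck and mu = 0: nothing can ever be generated
  noop <- simConfigNew(divisionsPerBottleneck = 0, muMultiplier = 0,
                       nReplicates = 50, seed = 5)
  ensNoop <- simulateEnsemble(noop)
  expect_true(all(ensNoop@nGenerated == 0L))
})

test_that("ensembles are reproducible given the seed and conserve every mutation", {
  cfg <- simConfigNew(muMultiplier = 10, nReplicates = 400, seed = 99)
  a <- simulateEnsemble(cfg)
  b <- simulateEnsemble(cfg)
  expect_identical(finalHom(a), finalHom(b))
  expect_identical(finalHet(a), finalHet(b))
  cfg2 <- simConfigNew(muMultiplier = 10, nReplicates = 400, seed = 100)
  expect_false(identical(finalHom(a), finalHom(simulateEnsemble(cfg2))))
  # conservation: generated = hom + het + lost in every replicate
  expect_true(all(a@nGenerated == finalHom(a) + finalHet(a) + a@nLost))
})

test_that("T-line ensemble means match the closed-form expectation oracle", {
  # mu = 0, defaults: fixation of vegetative-phase mutations only
  cfg <- simConfigNew(nReplicates = 6000, seed = 7)
  ens <- simulateEnsemble(cfg)
  exp0 <- expected_final_counts(cfg@m, cfg@genomeSize, 20, 50, 0.17)
  expect_equal(exp0[["hom"]], 3.46, tolerance = 0.002)
  se <- stats::sd(finalHom(ens)) / sqrt(cfg@nReplicates)
  expect_lt(abs(mean(finalHom(ens)) - exp0[["hom"]]), 3 * se)
  seh <- stats::sd(finalHet(ens)) / sqrt(cfg@nReplicates)
  expect_lt(abs(mean(finalHet(ens)) - exp0[["het"]]), 3 * seh)
  # s = 1: every bottleneck resolves all hets with even odds; mean hom
  # = 1000 m G / 2 = 3.55 and no heterozygote survives
  cfgS1 <- simConfigNew(s = 1, nReplicates = 6000, seed = 8)
  ensS1 <- simulateEnsemble(cfgS1)
  expS1 <- expected_final_counts(cfgS1@m, cfgS1@genomeSize, 20, 50, 1)
  expect_equal(expS1[["hom"]], 3.55, tolerance = 0.002)
  expect_true(all(finalHet(ensS1) == 0L))
  seS1 <- stats::sd(finalHom(ensS1)) / sqrt(cfgS1@nReplicates)
  expect_lt(abs(mean(finalHom(ensS1)) - expS1[["hom"]]), 3 * seS1)
})

test_that("B-line ensembles only accumulate heterozygous mutations", {
  cfg <- simConfigNew(scenario = "vegetative_only", nReplicates = 3000,
                      seed = 21)
  expect_equal(cfg@nBottlenecks, 87L)
  ens <- simulateEnsemble(cfg)
  expect_true(all(finalHom(ens) == 0L))
  expect_true(all(ens@nLost == 0L))
  lam <- 87 * 20 * cfg@m * cfg@genomeSize
  se <- stats::sd(finalHet(ens)) / sqrt(cfg@nReplicates)
  expect_lt(abs(mean(finalHet(ens)) - lam), 3 * se)
  # single line, m = 0
  set.seed(1)
  lineZero <- simulateBLine(simConfigNew(m = 0, scenario = "vegetative_only",
                                         nReplicates = 1))
  expect_equal(lineZero@nGenerated, 0L)
  expect_error(simulateBLine(simConfigNew(nReplicates = 1)), "vegetative_only")
  expect_error(simulateTLine(simConfigNew(scenario = "vegetative_only",
                                          nReplicates = 1)), "simulateBLine")
})

test_that("mean homozygous output is monotone in the meiotic rate and ordered by scenario", {
  means <- vapply(c(0, 20, 40), function(mult) {
    mean(finalHom(simulateEnsemble(simConfigNew(
      muMultiplier = mult, nReplicates = 3000, seed = 400 + mult))))
  }, numeric(1))
  expect_true(!is.unsorted(means))
  # at equal mu, pre-replication mutations (carriage 2) fix far more often
  # than post-replication ones (immediate fixation 0.223 vs 0.0425 at s=0.17)
  pre <- simulateEnsemble(simConfigNew(muMultiplier = 40,
                                       scenario = "pre_replication",
                                       nReplicates = 3000, seed = 31))
  post <- simulateEnsemble(simConfigNew(muMultiplier = 40,
                                        scenario = "post_replication",
                                        nReplicates = 3000, seed = 32))
  expect_gt(mean(finalHom(pre)), mean(finalHom(post)))
  expect_equal(analyticFateProbs(2, 0.17)[["pFix"]], 0.223, tolerance = 0.002)
  expect_equal(analyticFateProbs(1, 0.17)[["pFix"]], 0.0425,
               tolerance = 1e-12)
})

test_that("joint spore-genotype and independent-resolution engines agree", {
  for (scen in c("pre_replication", "post_replication")) {
    ind <- simulateEnsemble(simConfigNew(
      muMultiplier = 20, scenario = scen, nReplicates = 1200, seed = 55,
      matingModel = "independent"))
    jnt <- simulateEnsemble(simConfigNew(
      muMultiplier = 20, scenario = scen, nReplicates = 1200, seed = 56,
      matingModel = "joint"))
    seDiff <- sqrt(stats::var(finalHom(ind)) / 1200 +
                   stats::var(finalHom(jnt)) / 1200)
    expect_lt(abs(mean(finalHom(ind)) - mean(finalHom(jnt))), 3 * seDiff)
    seDiffHet <- sqrt(stats::var(finalHet(ind)) / 1200 +
                      stats::var(finalHet(jnt)) / 1200)
    expect_lt(abs(mean(finalHet(ind)) - mean(finalHet(jnt))), 3 * seDiffHet)
    # conservation holds replicate-by-replicate in both engines
    expect_true(all(jnt@nGenerated ==
                    finalHom(jnt) + finalHet(jnt) + jnt@nLost))
  }
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simConfigNew(s = 1.5), "s")
  expect_error(simConfigNew(m = -1), "m")
  expect_error(simConfigNew(nBottlenecks = 0), "nBottlenecks")
  expect_error(simConfigNew(scenario = "during_meiosis"))
})
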