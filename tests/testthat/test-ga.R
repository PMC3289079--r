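smallCfg <- function(...) {
  gaConfig(populationSize = 20L, maxGenerations = 15L, ...)
}

test_that("initial populations are uniform, sorted and seed-reproducible", {
  s <- HPSequence("HPHHPHPHPH")
  p1 <- initializePopulation(s, smallCfg(), seed = 5)
  p2 <- initializePopulation(s, smallCfg(), seed = 5)
  expect_identical(p1@folds, p2@folds)
  expect_false(is.unsorted(p1@fitness))
  expect_equal(ncol(p1@folds), 9L)
  # two-residue chains have no non-adjacent pairs: every fitness is zero
  p0 <- initializePopulation(HPSequence("HH"),
                             gaConfig(populationSize = 4L,
                                      maxGenerations = 15L))
  expect_equal(p0@fitness, rep(0, 4))
  # gene marginals are uniform over the six symbols
  big <- initializePopulation(HPSequence("HPHPHPHPHP"),
                              gaConfig(populationSize = 5000L), seed = 9)
  counts <- table(factor(big@folds, levels = latticeDirections()))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("two-point crossover splices between the cuts and conserves loci", {
  a <- Conformation(rep("R", 4))
  b <- Conformation(rep("L", 4))
  expect_equal(folds(twoPointCrossover(a, b, cuts = c(1, 3))$children[[1]]),
               c("R", "L", "L", "R"))
  same <- twoPointCrossover(a, a, seed = 3)$children
  expect_equal(folds(same[[1]]), folds(a))
  expect_equal(folds(same[[2]]), folds(a))
  set.seed(11)
  for (i in 1:25) {
    pa <- randomFoldConformation(8)
    pb <- randomFoldConformation(8)
    kids <- twoPointCrossover(pa, pb)$children
    for (locus in 1:8) {
      expect_setequal(c(folds(kids[[1]])[locus], folds(kids[[2]])[locus]),
                      c(folds(pa)[locus], folds(pb)[locus]))
    }
  }
  expect_error(twoPointCrossover(a, Conformation(rep("L", 3))),
               "equal length")
})

test_that("uniform mutation respects its rate at both extremes and in bulk", {
  conf <- randomFoldConformation(20)
  expect_equal(folds(uniformMutation(conf, 0, seed = 1)), folds(conf))
  one <- Conformation("R")
  for (s in 1:20) {
    expect_false(folds(uniformMutation(one, 1, scope = "gene",
                                       seed = s)) == "R")
  }
  set.seed(12)
  flips <- 0L
  trials <- 4000L
  for (i in seq_len(trials)) {
    mut <- uniformMutation(conf, 0.4, scope = "gene")
    flips <- flips + sum(folds(mut) != folds(conf))
  }
  expect_equal(flips / (trials * 20), 0.4, tolerance = 0.05)
  # chromosome scope changes at most one gene
  set.seed(13)
  for (i in 1:50) {
    mut <- uniformMutation(conf, 1, scope = "chromosome")
    expect_lte(sum(folds(mut) != folds(conf)), 1L)
  }
})

test_that("elite reproduction copies the population when rates are zero", {
  # with the literal bottom-half parent pool, zero-rate reproduction clones
  # the bottom half onto itself: the population is copied as a multiset
  s <- HPSequence("HPHHPHPH")
  cfg <- smallCfg(parentPool = "bottom_half")
  pop <- initializePopulation(s, cfg, seed = 2)
  nxt <- eliteReproduction(pop, smallCfg(parentPool = "bottom_half",
                                         crossoverRate = 0,
                                         mutationRate = 0), seed = 3)
  asStrings <- function(p) sort(apply(p@folds, 1, paste, collapse = "-"))
  expect_equal(asStrings(nxt), asStrings(pop))
  expect_equal(sort(nxt@fitness), sort(pop@fitness))
  # the whole-population pool still preserves every elite chromosome
  nxtW <- eliteReproduction(pop, smallCfg(crossoverRate = 0,
                                          mutationRate = 0), seed = 3)
  elite <- apply(pop@folds[1:10, , drop = FALSE], 1, paste, collapse = "-")
  expect_true(all(elite %in% apply(nxtW@folds, 1, paste, collapse = "-")))
})

test_that("the elite half survives verbatim and best fitness never worsens", {
  s <- HPSequence("HPHHPHPHHP")
  cfg <- smallCfg()
  pop <- initializePopulation(s, cfg, seed = 4)
  for (step in 1:10) {
    nxt <- eliteReproduction(pop, cfg, seed = step)
    eliteStrings <- apply(pop@folds[1:10, , drop = FALSE], 1, paste,
                          collapse = "-")
    nextStrings <- apply(nxt@folds, 1, paste, collapse = "-")
    expect_true(all(eliteStrings %in% nextStrings))
    expect_lte(nxt@fitness[1], pop@fitness[1])
    pop <- nxt
  }
})

test_that("runs are bit-reproducible and their best trace is monotone", {
  s <- parseHP("(HP)^5")
  r1 <- runERSGA(s, smallCfg(), seed = 77)
  r2 <- runERSGA(s, smallCfg(), seed = 77)
  expect_identical(folds(bestConformation(r1)), folds(bestConformation(r2)))
  expect_identical(generationLog(r1), generationLog(r2))
  expect_false(is.unsorted(rev(generationLog(r1)$best))) # non-increasing
  expect_true(isSelfAvoiding(bestConformation(r1)))
  expect_equal(hpEnergy(s, bestConformation(r1)), bestEnergy(r1))
})

test_that("tiny instances are solved to optimality by the default ERS-GA", {
  s <- HPSequence("HHHH")
  for (sd in 1:5) {
    expect_equal(bestEnergy(runERSGA(s, gaConfig(), seed = sd)), -2L)
  }
  allP <- HPSequence("PPPPPPPP")
  r <- runERSGA(allP, smallCfg(), seed = 1)
  expect_true(r@feasible)
  expect_equal(bestEnergy(r), 0L)
})

test_that("config validation rejects out-of-contract settings", {
  expect_error(gaConfig(populationSize = 7), "even")
  expect_error(gaConfig(crossoverRate = 1.2), "\\[0, 1\\]")
  expect_error(gaConfig(penaltyPerCollision = -1), "positive")
  expect_error(runERSGA(HPSequence("H"), smallCfg()), "at least two")
})
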