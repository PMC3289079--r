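test_that("local search I with zero passes is the identity", {
  s <- HPSequence("HPHHPH")
  conf <- randomFoldConformation(5)
  out <- localSearchOne(s, conf, passes = 0, seed = 1)
  expect_equal(folds(out), folds(conf))
})

test_that("neither local-search operator ever worsens the fitness", {
  set.seed(21)
  for (i in 1:150) {
    n <- sample(4:18, 1)
    s <- HPSequence(randomHPString(n))
    conf <- randomFoldConformation(n - 1L)
    f0 <- hpFitness(s, conf)
    expect_lte(hpFitness(s, localSearchOne(s, conf, passes = 2)), f0)
    expect_lte(hpFitness(s, localSearchTwo(s, conf)), f0)
  }
})

test_that("local search I finds improvements on the straight HHHH chain", {
  s <- HPSequence("HHHH")
  straight <- Conformation(c("R", "R", "R")) # fitness 0
  set.seed(22)
  fits <- replicate(100, hpFitness(s, localSearchOne(s, straight)))
  expect_true(all(fits <= 0))
  expect_lt(mean(fits), 0)
})

test_that("local search II rotates the tail rigidly about the pivot", {
  set.seed(23)
  rot60 <- function(xy, k) {
    a <- k * pi / 3
    Rm <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    t(Rm %*% t(xy))
  }
  for (i in 1:20) {
    n <- sample(6:14, 1)
    m <- n - 1L
    conf <- randomFoldConformation(m)
    p <- sample(seq_len(m - 1L), 1) # 0-based pivot gene index in 1..m-1
    base <- toEuclidean(decodeConformation(conf))
    f <- folds(conf)
    for (k in 1:5) {
      rotated <- Conformation(c(f[seq_len(p)],
                                rotateDirection(f[(p + 1L):m], k)))
      got <- toEuclidean(decodeConformation(rotated))
      # head fixed, tail rotated about the pivot residue's position
      expect_equal(got[1:(p + 1L), ], base[1:(p + 1L), ], tolerance = 1e-9)
      pivotPt <- base[p + 1L, ]
      expTail <- sweep(rot60(sweep(base[(p + 2L):n, , drop = FALSE], 2,
                                   pivotPt), k), 2, -pivotPt)
      expect_equal(got[(p + 2L):n, , drop = FALSE], expTail,
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("local search II keeps the best strict improvement among 5 rotations", {
  s <- HPSequence("HHHH")
  straight <- Conformation(c("R", "R", "R"))
  # pivot gene index 1: five tail rotations, evaluated by the R surface
  f <- folds(straight)
  rotFits <- sapply(1:5, function(k) {
    hpFitness(s, Conformation(c(f[1], rotateDirection(f[2:3], k))))
  })
  out <- localSearchTwo(s, straight, pivot = 1)
  expect_equal(hpFitness(s, out), min(c(0, rotFits)))
  expect_equal(hpFitness(s, out), -1) # bending the tail creates one contact
  # all-P chains admit no strict improvement: input returned unchanged
  pSeq <- HPSequence("PPPPP")
  pConf <- Conformation(rep("R", 4))
  expect_equal(folds(localSearchTwo(pSeq, pConf, seed = 5)), folds(pConf))
  # chromosomes too short for a proper suffix pass through untouched
  expect_equal(folds(localSearchTwo(HPSequence("HH"), Conformation("R"))),
               "R")
})

test_that("HHGA with zero local-search budgets reproduces ERS-GA exactly", {
  s <- parseHP("(HP)^4")
  cfg0 <- gaConfig(populationSize = 20, maxGenerations = 20,
                   ls1Passes = 0, ls2Trials = 0)
  cfg <- gaConfig(populationSize = 20, maxGenerations = 20)
  a <- runHHGA(s, cfg0, seed = 9)
  b <- runERSGA(s, cfg, seed = 9)
  expect_identical(folds(bestConformation(a)), folds(bestConformation(b)))
  expect_identical(generationLog(a), generationLog(b))
})

test_that("hybrid runs return feasible, monotone, reproducible results", {
  s <- parseHP("H^2(PH)^3")
  r1 <- runHHGA(s, gaConfig(populationSize = 20, maxGenerations = 15),
                seed = 31)
  r2 <- runHHGA(s, gaConfig(populationSize = 20, maxGenerations = 15),
                seed = 31)
  expect_identical(folds(bestConformation(r1)), folds(bestConformation(r2)))
  expect_true(isSelfAvoiding(bestConformation(r1)))
  expect_false(is.unsorted(rev(generationLog(r1)$best)))
  expect_equal(hpEnergy(s, bestConformation(r1)), bestEnergy(r1))
})
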