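test_that("decoding walks the fold string from the origin", {
  expect_equal(unname(decodeConformation(Conformation(c("R", "RU")))),
               rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L)))
  expect_equal(unname(decodeConformation(Conformation())),
               rbind(c(0L, 0L)))
  expect_equal(unname(decodeConformation(Conformation(c("R", "L")))),
               rbind(c(0L, 0L), c(1L, 0L), c(0L, 0L)))
})

test_that("self-avoidance detects revisits, including non-adjacent ones", {
  expect_true(isSelfAvoiding(Conformation(c("R", "RU"))))
  expect_false(isSelfAvoiding(Conformation(c("R", "L"))))
  # R, RU, L, LD closes a rhombus back onto the origin
  expect_false(isSelfAvoiding(Conformation(c("R", "RU", "L", "LD"))))
})

test_that("contact counting excludes chain neighbours and ignores P", {
  expect_equal(countHHContacts(HPSequence("HHH"),
                               Conformation(c("R", "LU"))), 1L)
  expect_equal(countHHContacts(HPSequence("PPPP"),
                               Conformation(c("R", "R", "RU"))), 0L)
  expect_equal(countHHContacts(HPSequence("HH"), Conformation("R")), 0L)
  expect_error(countHHContacts(HPSequence("HH"), decodeConformation(
    Conformation(c("R", "R")))), "does not match")
})

test_that("energy equals minus the contact count and rejects collisions", {
  expect_equal(hpEnergy(HPSequence("HHH"), Conformation(c("R", "LU"))), -1L)
  expect_equal(hpEnergy(HPSequence("PPPP"),
                        Conformation(c("R", "RU", "L"))), 0L)
  expect_error(hpEnergy(HPSequence("HHH"), Conformation(c("R", "L"))),
               "not self-avoiding")
  expect_error(hpEnergy(HPSequence("HHH"), Conformation("R")), "n - 1")
})

test_that("the optimum of HHHH is -2, agreeing with the naive enumeration", {
  expect_equal(naiveMinEnergy("HHHH"), -2L)
  expect_equal(minEnergy(enumerateMinEnergy(HPSequence("HHHH"))), -2L)
})

test_that("fitness matches energy when feasible and penalises collisions", {
  seq3 <- HPSequence("HHH")
  valid <- Conformation(c("R", "LU"))
  expect_equal(hpFitness(seq3, valid), hpEnergy(seq3, valid))
  # one colliding pair, zero unit-distance H-H contacts
  expect_equal(hpFitness(seq3, Conformation(c("R", "L"))), 4 * 3)
  expect_equal(hpFitness(seq3, Conformation(c("R", "L")),
                         penaltyPerCollision = 100), 100)
})

test_that("R-surface fitness agrees with the search engine on random folds", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:16, 1)
    s <- HPSequence(randomHPString(n))
    conf <- randomFoldConformation(n - 1L)
    engine <- trifold:::.cpp_evaluate(trifold:::.residueIsH(s),
                                      trifold:::.dirIndex(folds(conf)),
                                      4 * n)
    expect_equal(hpFitness(s, conf), engine$fitness)
    expect_equal(countHHContacts(s, conf), as.integer(engine$contacts))
  }
})

test_that("energy is invariant under global rotation and chain reversal", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(5:14, 1)
    s <- HPSequence(randomHPString(n))
    conf <- randomSAWConformation(n)
    e <- hpEnergy(s, conf)
    for (k in 1:5) {
      rot <- rotateConformation(conf, k)
      expect_true(isSelfAvoiding(rot))
      expect_equal(hpEnergy(s, rot), e)
    }
    sRev <- HPSequence(paste(rev(strsplit(hpResidues(s), "")[[1]]),
                             collapse = ""))
    expect_equal(hpEnergy(sRev, reverseConformation(conf)), e)
  }
})

test_that("energies of random valid conformations respect the HP bounds", {
  set.seed(43)
  for (i in 1:40) {
    n <- sample(5:16, 1)
    s <- HPSequence(randomHPString(n))
    conf <- randomSAWConformation(n)
    e <- hpEnergy(s, conf)
    nH <- sum(strsplit(hpResidues(s), "")[[1]] == "H")
    expect_lte(e, 0)
    expect_gte(e, -2 * nH) # each residue caps at 4 contacts, 2 residues each
  }
})
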