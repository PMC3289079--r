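test_that("power notation expands the benchmark registry to its lengths", {
  reg <- triBenchmarks()
  for (i in seq_len(nrow(reg))) {
    expect_equal(nchar(expandHPNotation(reg$notation[i])), reg$length[i],
                 info = paste("benchmark", reg$id[i]))
  }
})

test_that("notation expansion handles identity, nesting and plain strings", {
  expect_equal(expandHPNotation("H"), "H")
  expect_equal(expandHPNotation("((PH)^2)^3"), "PHPHPHPHPHPH")
  expect_equal(expandHPNotation("H^12"), strrep("H", 12))
  expect_equal(hpResidues(parseHP("HPHP")), "HPHP")
  expect_equal(nResidues(parseHP("H^2P^2(HP^2)^6H^2")), 24L)
})

test_that("malformed notation fails with a position-labelled error", {
  expect_error(expandHPNotation("(HP"), "position 1.*unbalanced")
  expect_error(expandHPNotation("HP)"), "position 3.*unmatched")
  expect_error(expandHPNotation("H^0P"), "positive integer")
  expect_error(expandHPNotation("H^"), "expected an exponent")
  expect_error(expandHPNotation("HXP"), "position 2.*unexpected character 'X'")
  expect_error(HPSequence("HXP"), "only 'H' and 'P'")
})

test_that("FASTA-like files round-trip and auto-detect notation", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">plain", "HPHHP", ">compact", "(HP)^3", "PH"), tf)
  seqs <- readHPFasta(tf)
  expect_named(seqs, c("plain", "compact"))
  expect_equal(hpResidues(seqs$plain), "HPHHP")
  expect_equal(hpResidues(seqs$compact), "HPHPHPPH") # lines concatenated
  tf2 <- tempfile(fileext = ".fasta")
  writeHPFasta(seqs, tf2)
  expect_equal(lapply(readHPFasta(tf2), hpResidues), lapply(seqs, hpResidues))
  expect_error(suppressWarnings(readHPFasta(tempfile())),
               "cannot open|No such file")
})

test_that("conformation records round-trip through the TSV format", {
  confs <- list(a = Conformation(c("R", "RU", "LU")),
                b = Conformation(c("L", "LD")))
  tf <- tempfile(fileext = ".tsv")
  writeConformations(confs, c(-2, 0), tf)
  back <- readConformations(tf)
  expect_equal(back$name, c("a", "b"))
  expect_equal(back$energy, c(-2, 0))
  expect_equal(folds(attr(back, "conformations")$a), c("R", "RU", "LU"))
  expect_equal(foldString(parseFoldString("R-RU-LU")), "R-RU-LU")
  expect_equal(length(parseFoldString("")), 0L)
})

test_that("GA configs load from JSON with defaults for missing keys", {
  skip_if_not_installed("jsonlite")
  tf <- tempfile(fileext = ".json")
  writeLines('{"populationSize": 50, "mutationRate": 0.1}', tf)
  cfg <- readGAConfig(tf)
  expect_s4_class(cfg, "GAConfig")
  expect_equal(cfg@populationSize, 50L)
  expect_equal(cfg@mutationRate, 0.1)
  expect_equal(cfg@crossoverRate, 0.8) # default kept
  writeLines('{"popSize": 50}', tf)
  expect_error(readGAConfig(tf), "unknown config key")
})
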