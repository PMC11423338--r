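test_that("canonicalization is idempotent and flags invalid molecules", {
  expect_identical(canonicalizeSmiles("CCO"), "CCO")
  can <- canonicalizeSmiles("OCC")
  expect_false(is.na(can))
  expect_identical(canonicalizeSmiles(can), can)   # idempotent
  expect_true(is.na(canonicalizeSmiles("C(((")))
  expect_true(is.na(canonicalizeSmiles("CC)")))
  # idempotence over a whole corpus
  corpus <- fxCorpus(30L)
  can1 <- canonicalizeSmiles(corpus)
  expect_false(anyNA(can1))
  expect_identical(canonicalizeSmiles(can1), can1)
})

test_that("largest-component retention picks the heaviest parseable part", {
  expect_identical(keepLargestComponent("CCO.O"), "CCO")
  expect_identical(keepLargestComponent("CCO"), "CCO")
  expect_identical(keepLargestComponent("[Na+].CC(=O)[O-]"), "CC(=O)[O-]")
  expect_true(is.na(keepLargestComponent("C(((.C(((")))
  # returned component is literally one of the input components
  s <- "CCN.CCCCCC.O"
  expect_true(keepLargestComponent(s) %in% strsplit(s, ".", fixed = TRUE)[[1]])
})

test_that("molecular weights match reference values", {
  # ethanol 46.07, water 18.02 (standard atomic weights)
  expect_equal(molecularWeight("CCO"), 46.07, tolerance = 1e-3)
  expect_equal(molecularWeight("O"), 18.02, tolerance = 1e-3)
  expect_true(molecularWeight("CC(=O)[O-]") > molecularWeight("[Na+]"))
})

test_that("deduplication keeps first occurrences of canonical forms", {
  expect_identical(deduplicateSmiles(c("CCO", "OCC", "CCN")), c("CCO", "CCN"))
  expect_identical(deduplicateSmiles(character()), character())
  distinct <- c("CCO", "CCN", "CCC")
  expect_identical(deduplicateSmiles(distinct), distinct)
})

test_that("vocabulary treats multi-character tokens as single units", {
  v <- buildVocabulary(c("CCO", "CCCl"))
  expect_true("Cl" %in% vocabTokens(v))
  v2 <- buildVocabulary("C%12CCCCCCCCCCC%12")
  expect_true("%12" %in% vocabTokens(v2))
  v3 <- buildVocabulary("C")
  expect_identical(vocabTokens(v3), "C")
  expect_equal(vocabSize(v3), 5L)  # 4 specials + C
  expect_error(buildVocabulary(character()), "non-empty")
})

test_that("tokenize/detokenize round-trips every corpus SMILES", {
  corpus <- fxCorpus(30L)
  v <- buildVocabulary(corpus)
  for (s in corpus) {
    tk <- tokenizeSmiles(s, v)
    expect_false(is.null(tk))
    expect_identical(detokenizeSmiles(tk, v), s)
  }
  # structure: start/end framing and the empty string
  tk <- tokenizeSmiles("CCO", buildVocabulary("CCO"))
  expect_identical(tk[1], 2L)
  expect_identical(tk[length(tk)], 3L)
  expect_length(tk, 5L)
  expect_identical(tokenizeSmiles("", buildVocabulary("C")), c(2L, 3L))
  # out-of-vocabulary handling
  expect_null(tokenizeSmiles("CCBr", buildVocabulary("CCO")))
  unk <- tokenizeSmiles("CCBr", buildVocabulary("CCO"), oov = "unk")
  expect_true(4L %in% unk)
})

test_that("circular fingerprints are deterministic fixed-length bitsets", {
  fp <- ecfpFingerprint("c1ccccc1O")
  expect_length(fp, 2048L)
  expect_identical(fp, ecfpFingerprint("c1ccccc1O"))
  expect_false(identical(ecfpFingerprint("C"), ecfpFingerprint("CCCCCCCC")))
  expect_length(ecfpFingerprint("CCO", nbits = 1024L), 1024L)
  expect_lte(sum(fp), 2048L)
  expect_true(all(is.na(ecfpFingerprint("C((("))))
})

test_that("cluster split partitions records with one test compound per cluster", {
  corpus <- fxCorpus(30L)
  sp <- clusterSplit(corpus, k = 3L, seed = 42L)
  expect_length(sp$test, 3L)
  expect_length(sp$train, 27L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(corpus))
  # determinism
  sp2 <- clusterSplit(corpus, k = 3L, seed = 42L)
  expect_identical(sp$test, sp2$test)
  # k = 1
  sp1 <- clusterSplit(corpus[1:5], k = 1L, seed = 1L)
  expect_length(sp1$test, 1L)
  expect_error(clusterSplit(corpus[1:2], k = 3L), "at least k")
})

test_that("smi files round-trip", {
  f <- tempfile(fileext = ".smi")
  smis <- c("CCO", "c1ccccc1", "CC(=O)O")
  writeSmi(smis, f)
  expect_identical(readSmi(f), smis)
})
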