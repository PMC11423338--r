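test_that("Tanimoto matches bit enumeration and the popcount identity", {
  S <- 2048L
  mkfp <- function(on) { f <- rep(FALSE, S); f[on] <- TRUE; f }
  fp <- ecfpFingerprint("c1ccccc1O")
  expect_equal(tanimotoSimilarity(fp, fp), 1)
  expect_equal(tanimotoSimilarity(mkfp(1:3), mkfp(4:6)), 0)
  # {1,2,3} vs {2,3,4}: t = 2, f = 2044 -> 2 / (2048 - 2044) = 0.5
  expect_equal(tanimotoSimilarity(mkfp(1:3), mkfp(2:4)), 0.5)
  expect_warning(und <- tanimotoSimilarity(mkfp(integer()), mkfp(integer())),
                 "undefined")
  expect_true(is.na(und))
  # t/(S-f) == t/(a+b-t) on random bitsets
  set.seed(21)
  for (i in 1:200) {
    a <- stats::runif(S) < 0.02
    b <- stats::runif(S) < 0.02
    if (!any(a) && !any(b)) next
    t <- sum(a & b)
    expect_equal(tanimotoSimilarity(a, b), t / (sum(a) + sum(b) - t),
                 tolerance = 1e-12)
  }
})

test_that("internal diversity equals the brute-force pair loop", {
  expect_equal(internalDiversity("CCO"), 0)          # singleton: self-pair only
  expect_equal(internalDiversity(c("CCO", "CCO", "CCO")), 0)
  # two molecules with disjoint fingerprints -> 1 - (1+0+0+1)/4 = 0.5
  fp <- rbind(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(internalDiversity(fp), 0.5)
  # oracle equivalence on a real molecule set
  smis <- fxCorpus(15L)
  M <- ecfpMatrix(smis)
  oracle <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(nrow(M)))
    oracle <- oracle + tanimotoSimilarity(M[i, ], M[j, ])
  oracle <- 1 - oracle / nrow(M)^2
  expect_equal(internalDiversity(smis), oracle, tolerance = 1e-12)
})

test_that("basic metrics count validity, uniqueness and diversity", {
  toy <- c("CCO", "CCN", "CCC")
  bm <- basicMetrics(toy)
  expect_equal(bm$validity, 100)
  expect_equal(bm$uniqueness, 1)
  # 10 samples, 1 invalid -> 90%
  bm2 <- basicMetrics(c(rep("CCO", 9), "C((("))
  expect_equal(bm2$validity, 90)
  # 4 valid of which 2 identical (as canonical forms) -> 0.75
  bm3 <- basicMetrics(c("CCO", "OCC", "CCN", "CCC"))
  expect_equal(bm3$uniqueness, 0.75)
  # no valid molecule: undefined uniqueness/diversity
  bm4 <- basicMetrics(c("C(((", ")("))
  expect_true(is.na(bm4$uniqueness) && is.na(bm4$diversity))
})

test_that("interaction metrics enforce thresholds against the seed", {
  pk <- fxPocket(4L)
  seedS <- "NCCO"
  seedIev <- computeIev(placePose(seedS, pk, seed = 2L), pk)
  # generated set = the seed itself: cosine 1 (>= 0.7) but Tanimoto 1 (> 0.5)
  rep1 <- interactionMetrics(seedS, seedS, seedIev, pocket = pk, seed = 2L)
  expect_identical(rep1@nIevComputable, 1L)
  expect_identical(rep1@nCosGe, 1L)
  expect_identical(rep1@nCosGeTanLe, 0L)
  # empty generated set
  rep0 <- interactionMetrics(character(), seedS, seedIev, pocket = pk)
  expect_identical(c(rep0@nIevComputable, rep0@nCosGe, rep0@nCosGeTanLe),
                   c(0L, 0L, 0L))
  # counts equal a brute-force recount on a fixture set, and the
  # monotonicity chain holds
  gen <- fxCorpus(12L)
  rep2 <- interactionMetrics(gen, seedS, seedIev, pocket = pk, seed = 2L)
  nIev <- 0L; nCos <- 0L; nBoth <- 0L
  seedFp <- ecfpFingerprint(seedS)
  for (s in gen) {
    v <- computeIev(placePose(s, pk, seed = 2L), pk)
    nIev <- nIev + 1L
    cs <- ievCosine(v, seedIev)
    if (cs >= 0.7) {
      nCos <- nCos + 1L
      if (tanimotoSimilarity(ecfpFingerprint(s), seedFp) <= 0.5)
        nBoth <- nBoth + 1L
    }
  }
  expect_identical(rep2@nIevComputable, nIev)
  expect_identical(rep2@nCosGe, nCos)
  expect_identical(rep2@nCosGeTanLe, nBoth)
  expect_true(rep2@nCosGeTanLe <= rep2@nCosGe &&
                rep2@nCosGe <= rep2@nIevComputable &&
                rep2@nIevComputable <= length(gen))
  # an external IEV table replaces the open backend
  tab <- list(); tab[[canonicalizeSmiles(seedS)]] <- seedIev
  rep3 <- interactionMetrics(c(seedS, "CCCCC"), seedS, seedIev,
                             ievTable = tab)
  expect_identical(rep3@nIevComputable, 1L)
})

test_that("property profile returns bounded QED and sensible logP", {
  smis <- c("CCO", "CCCCCCCCO", "c1ccccc1")
  pp <- propertyProfile(smis)
  expect_identical(nrow(pp), 3L)
  expect_true(all(pp$qed >= 0 & pp$qed <= 1))
  expect_true(all(is.finite(pp$logp)))
  # ethanol is less lipophilic than octanol
  expect_lt(pp$logp[1], pp$logp[2])
  # identical molecules get identical properties; invalids are skipped
  pp2 <- propertyProfile(c("CCO", "CCO", "C((("))
  expect_identical(nrow(pp2), 2L)
  expect_identical(pp2$qed[1], pp2$qed[2])
})

test_that("chemical-space projection yields ordered principal components", {
  smis <- fxCorpus(12L)
  xy <- projectChemicalSpace(smis)
  expect_identical(dim(xy), c(12L, 2L))
  expect_gte(stats::var(xy[, 1]), stats::var(xy[, 2]))
  # a duplicated molecule maps to identical coordinates
  xy2 <- projectChemicalSpace(c(smis, smis[1]))
  expect_equal(xy2[1, ], xy2[13, ], tolerance = 1e-9)
  expect_error(projectChemicalSpace(smis[1:2]), "at least 3")
})
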