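test_that("toy corpus is valid, unique and seed-deterministic", {
  cp <- makeToyCorpus(50L, seed = 9L)
  expect_length(cp, 50L)
  expect_true(all(isValidSmiles(cp)))
  expect_false(anyDuplicated(cp) > 0)
  expect_identical(cp, makeToyCorpus(50L, seed = 9L))
  expect_false(identical(cp, makeToyCorpus(50L, seed = 10L)))
  # uniqueness = 1 under the evaluation metrics
  expect_equal(basicMetrics(cp)$uniqueness, 1)
})

test_that("toy pocket round-trips through PDB and sits inside the radius", {
  f <- tempfile(fileext = ".pdb")
  pk <- makeToyPocket(5L, seed = 4L, file = f)
  expect_length(pocketResidues(pk), 5L)
  a <- pocketAtoms(pk)
  d <- sqrt(a$x^2 + a$y^2 + a$z^2)
  expect_true(all(d[a$element != "H"] <= 12))
  # write -> read gives the identical parameterized pocket
  pk2 <- selectPocketResidues(f, center = c(0, 0, 0), radius = 12)
  expect_identical(pocketResidues(pk2), pocketResidues(pk))
  expect_equal(pocketAtoms(pk2), pocketAtoms(pk))
  # the amide hydrogens came back as donors
  expect_true(any(pocketAtoms(pk2)$hbrole == "donorH"))
  # IEV length is three residues times three terms
  v <- computeIev(placePose("CCO", pk, seed = 1L), pk)
  expect_length(v@values, 15L)
})

test_that("pose placement is deterministic and centered in the pocket", {
  pk <- fxPocket(4L)
  p1 <- placePose("NCC(=O)O", pk, seed = 5L)
  p2 <- placePose("NCC(=O)O", pk, seed = 5L)
  expect_identical(p1@atoms, p2@atoms)
  p3 <- placePose("NCC(=O)O", pk, seed = 6L)
  expect_false(identical(p1@atoms, p3@atoms))
  heavy <- p1@atoms[p1@atoms$element != "H", ]
  centroid <- colMeans(heavy[, c("x", "y", "z")])
  expect_lt(sqrt(sum((centroid - pk@center)^2)), 2)
  # polar molecule has a finite, nonzero interaction profile
  v <- computeIev(p1, pk)
  expect_true(all(is.finite(v@values)))
  expect_gt(sum(abs(v@values)), 0)
  # donor hydrogens are attached to heteroatoms
  don <- p1@atoms[p1@atoms$hbrole == "donorH", ]
  expect_true(all(p1@atoms$element[don$hbparent] %in% c("N", "O", "S")))
  expect_error(placePose("C(((", pk), "embedding failure")
})

test_that("paired dataset plants a structure-interaction relationship", {
  spec <- fixtureSpec(nMolecules = 40L, nResidues = 4L, noise = 0, seed = 31L)
  ds <- makePairedDataset(spec)
  expect_identical(length(pairedSmiles(ds)), nrow(pairedIev(ds)))
  expect_identical(ncol(pairedIev(ds)), 12L)
  # noise = 0: IEVs exactly reproducible from the poses
  i <- 7L
  v <- computeIev(placePose(pairedSmiles(ds)[i], ds@pocket, seed = 31L),
                  ds@pocket)
  expect_equal(unname(pairedIev(ds)[i, ]), v@values, tolerance = 1e-12)
  # full determinism of the generator
  ds2 <- makePairedDataset(spec)
  expect_identical(pairedIev(ds), pairedIev(ds2))
  expect_identical(pairedSmiles(ds), pairedSmiles(ds2))
  # structurally similar pairs have more similar IEVs than dissimilar pairs
  M <- ecfpMatrix(pairedSmiles(ds))
  iev <- pairedIev(ds)
  n <- nrow(M)
  simT <- c(); simI <- c()
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    simT <- c(simT, tanimotoSimilarity(M[a, ], M[b, ]))
    simI <- c(simI, sum(iev[a, ] * iev[b, ]) /
                sqrt(sum(iev[a, ]^2) * sum(iev[b, ]^2)))
  }
  # most-similar tenth of pairs vs least-similar tenth
  hi <- simI[simT >= stats::quantile(simT, 0.9)]
  lo <- simI[simT <= stats::quantile(simT, 0.1)]
  expect_gt(stats::median(hi), stats::median(lo))
})
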