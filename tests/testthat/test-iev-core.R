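test_that("pocket selection respects the radius and residue-number order", {
  # two residues at 5 and 13 Angstrom from the center, radius 12 -> 1 kept
  f <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = f,
                   xyz = c(5, 0, 0, 13, 0, 0),
                   resno = c(45L, 12L), resid = c("ALA", "GLY"),
                   chain = c("A", "A"), eleno = 1:2,
                   elety = c("CA", "CA"), elesy = c("C", "C"))
  pk <- selectPocketResidues(f, center = c(0, 0, 0), radius = 12)
  expect_length(pocketResidues(pk), 1L)
  expect_match(pocketResidues(pk), "^A:45:")
  # both in range: ordered by residue number regardless of file order
  bio3d::write.pdb(file = f,
                   xyz = c(5, 0, 0, 0, 6, 0),
                   resno = c(45L, 12L), resid = c("ALA", "GLY"),
                   chain = c("A", "A"), eleno = 1:2,
                   elety = c("CA", "CA"), elesy = c("C", "C"))
  pk2 <- selectPocketResidues(f, center = c(0, 0, 0), radius = 12)
  expect_identical(pocketResidues(pk2), c("A:12:GLY", "A:45:ALA"))
  expect_error(selectPocketResidues(f, center = c(0, 0, 0), radius = 0),
               "empty pocket")
})

test_that("pair energies match their closed forms", {
  p <- defaultEnergyParams()
  p$dielectric <- "constant"
  mk <- function(x, q = 0, eps = 0, sigma = 3, role = "none")
    list(x = x, y = 0, z = 0, charge = q, eps = eps, sigma = sigma,
         hbrole = role)
  # Coulomb: unit charges at 1 Angstrom, D = 1
  e <- pairEnergies(mk(0, q = 1), mk(1, q = 1), p)
  expect_equal(unname(e["coulomb"]), 332.0636, tolerance = 1e-12)
  # all-zero parameters give the zero triple
  e0 <- pairEnergies(mk(0), mk(2), p)
  expect_identical(unname(e0), c(0, 0, 0))
  # LJ minimum: at r = 2^(1/6) sigma the well depth is exactly -eps
  r <- 2^(1/6) * 3
  elj <- pairEnergies(mk(0, eps = 0.1), mk(r, eps = 0.1), p)
  expect_equal(unname(elj["vdw"]), -0.1, tolerance = 1e-12)
  # distance floor is clamped with a warning
  expect_warning(pairEnergies(mk(0, q = 1), mk(1e-4, q = 1), p),
                 "clamped")
  # 12-10 hydrogen-bond term: depth -1 at r0 for a donorH/acceptor pair
  hb <- pairEnergies(mk(0, role = "donorH"), mk(p$hbond$r0, role = "acceptor"), p)
  expect_equal(unname(hb["hbond"]), -p$hbond$depth, tolerance = 1e-12)
  # no H-bond between two acceptors
  aa <- pairEnergies(mk(0, role = "acceptor"), mk(2, role = "acceptor"), p)
  expect_identical(unname(aa["hbond"]), 0)
})

test_that("computeIev equals the brute-force all-pairs oracle", {
  set.seed(11)
  for (rep in 1:5) {
    pk <- randomPocket(R = sample(2:4, 1))
    ps <- randomPose(n = sample(3:6, 1),
                     avoid = as.matrix(pocketAtoms(pk)[, c("x", "y", "z")]))
    v <- computeIev(ps, pk)
    expect_length(v@values, 3L * length(pocketResidues(pk)))
    expect_equal(v@values, unname(bruteForceIev(ps, pk)), tolerance = 1e-9)
  }
})

test_that("IEV is invariant to rigid motion and residue input order", {
  set.seed(12)
  pk <- randomPocket(R = 3)
  ps <- randomPose(5)
  v0 <- computeIev(ps, pk)
  # rigid rotation + translation applied to pose AND pocket together
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% Rz
    df$x <- xyz[, 1] + 3; df$y <- xyz[, 2] - 1; df$z <- xyz[, 3] + 2
    df
  }
  pk2 <- pk; pk2@atoms <- move(pk@atoms)
  ps2 <- ps; ps2@atoms <- move(ps@atoms)
  v2 <- computeIev(ps2, pk2)
  expect_equal(v0@values, v2@values, tolerance = 1e-9)
  # permuting atom rows within the pocket leaves the IEV unchanged
  ordr <- order(pk@atoms$resno, decreasing = TRUE)
  pk3 <- new("Pocket", center = pk@center, radius = pk@radius,
             atoms = {
               a <- pk@atoms[ordr, ]
               a$hbparent <- match(a$hbparent, ordr)
               rownames(a) <- NULL
               a
             },
             residueIds = rev(pk@residueIds))
  v3 <- computeIev(ps, pk3)
  # same triplets, reversed residue blocks
  m0 <- matrix(v0@values, nrow = 3)
  m3 <- matrix(v3@values, nrow = 3)
  expect_equal(m0[, rev(seq_len(ncol(m0)))], m3, tolerance = 1e-9)
})

test_that("IEV cosine behaves like a cosine", {
  v <- iev(c(1, 2, 3, -1, 0, 2))
  expect_equal(ievCosine(v, v), 1)
  a <- iev(c(1, 0, 0)); b <- iev(c(0, 1, 0))
  expect_equal(ievCosine(a, b), 0)
  c1 <- iev(c(1, 0, 0)); c2 <- iev(c(1, 1, 0))
  expect_equal(ievCosine(c1, c2), 0.70710678, tolerance = 1e-7)
  # scale invariance for positive scalars
  va <- iev(stats::rnorm(6)); vb <- iev(stats::rnorm(6))
  va3 <- iev(3.7 * va@values)
  expect_equal(ievCosine(va, vb), ievCosine(va3, vb), tolerance = 1e-12)
  # errors and undefined cases
  expect_error(ievCosine(iev(rep(1, 3)), iev(rep(1, 6))), "incompatible")
  expect_warning(z <- ievCosine(iev(c(0, 0, 0)), iev(c(1, 1, 1))),
                 "undefined")
  expect_true(is.na(z))
})

test_that("IEV tables round-trip bitwise and reject malformed input", {
  set.seed(13)
  pk <- randomPocket(2)
  ievs <- lapply(1:10, function(i) computeIev(randomPose(4), pk))
  names(ievs) <- paste0("m", 1:10)
  f <- tempfile(fileext = ".csv")
  writeIevTable(ievs, f)
  back <- readIevTable(f)
  expect_identical(names(back), names(ievs))
  for (i in seq_along(ievs)) {
    expect_identical(back[[i]]@values, ievs[[i]]@values)
    expect_identical(back[[i]]@labels, ievs[[i]]@labels)
  }
  # empty file -> empty map
  f2 <- tempfile(); writeLines(character(), f2)
  expect_identical(readIevTable(f2), list())
  # header with wrong term order
  f3 <- tempfile()
  writeLines(c("id,r1_coulomb,r1_vdw,r1_hbond", "a,1,2,3"), f3)
  expect_error(readIevTable(f3), "triplet")
  # ragged row reports the line number
  f4 <- tempfile()
  writeLines(c("id,r1_vdw,r1_coulomb,r1_hbond", "a,1,2"), f4)
  expect_error(readIevTable(f4), "line 2")
  # non-numeric cell
  f5 <- tempfile()
  writeLines(c("id,r1_vdw,r1_coulomb,r1_hbond", "a,1,x,3"), f5)
  expect_error(readIevTable(f5), "non-numeric")
})
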