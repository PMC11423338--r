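# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk.

fx <- new.env(parent = emptyenv())

fxCorpus <- function(n = 30L, seed = 101L) {
  key <- paste0("corpus", n, "_", seed)
  if (is.null(fx[[key]])) fx[[key]] <- makeToyCorpus(n, seed = seed)
  fx[[key]]
}

fxPocket <- function(R = 5L, seed = 7L) {
  key <- paste0("pocket", R, "_", seed)
  if (is.null(fx[[key]])) fx[[key]] <- makeToyPocket(R, seed = seed)
  fx[[key]]
}

# a random parameterized atom table for energy-oracle tests; atoms are kept
# at least 1.4 Angstrom apart (physically sane geometries keep the pairwise
# energies within double-precision reach of the scalar oracle)
randomAtoms <- function(n, center = c(0, 0, 0), spread = 3,
                        avoid = matrix(0, 0L, 3L)) {
  xyz <- matrix(0, 0L, 3L)
  while (nrow(xyz) < n) {
    cand <- center + stats::rnorm(3L, sd = spread)
    all_xyz <- rbind(avoid, xyz)
    if (nrow(all_xyz) == 0L ||
        min(sqrt(rowSums(sweep(all_xyz, 2L, cand)^2))) >= 1.4)
      xyz <- rbind(xyz, cand)
  }
  data.frame(
    atom = paste0("X", seq_len(n)), element = sample(c("C", "N", "O", "H"),
                                                     n, replace = TRUE),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = stats::runif(n, -0.5, 0.5),
    eps = stats::runif(n, 0.01, 0.3),
    sigma = stats::runif(n, 2.5, 3.8),
    hbrole = sample(c("donorH", "acceptor", "none"), n, replace = TRUE,
                    prob = c(0.2, 0.3, 0.5)),
    hbparent = NA_integer_,
    stringsAsFactors = FALSE)
}

randomPocket <- function(R, atomsPerRes = 3L) {
  seen <- matrix(0, 0L, 3L)
  rows <- lapply(seq_len(R), function(i) {
    a <- randomAtoms(atomsPerRes, center = stats::rnorm(3, sd = 5),
                     avoid = seen)
    seen <<- rbind(seen, as.matrix(a[, c("x", "y", "z")]))
    cbind(data.frame(chain = "A", resno = i,
                     resname = "RES", stringsAsFactors = FALSE), a)
  })
  df <- do.call(rbind, rows)
  # donor hydrogens need a parent heavy atom for the angle gate; point each
  # at the first heavy atom of its own residue (or drop the role)
  for (k in which(df$hbrole == "donorH")) {
    res <- df$resno[k]
    heavy <- which(df$resno == res & df$element != "H" &
                     seq_len(nrow(df)) != k)
    if (length(heavy)) df$hbparent[k] <- heavy[1] else df$hbrole[k] <- "none"
  }
  new("Pocket", center = c(0, 0, 0), radius = 15,
      atoms = df[, c("chain", "resno", "resname", "atom", "element",
                     "x", "y", "z", "charge", "eps", "sigma", "hbrole",
                     "hbparent")],
      residueIds = unique(paste(df$chain, df$resno, df$resname, sep = ":")))
}

randomPose <- function(n = 6L, avoid = matrix(0, 0L, 3L)) {
  a <- randomAtoms(n, spread = 2, avoid = avoid)
  for (k in which(a$hbrole == "donorH")) {
    heavy <- which(a$element != "H" & seq_len(nrow(a)) != k)
    if (length(heavy)) a$hbparent[k] <- heavy[1] else a$hbrole[k] <- "none"
  }
  new("LigandPose", smiles = "synthetic", atoms = a)
}

# independent brute-force oracle: scalar double loop over every atom pair
# via pairEnergies(), per-residue sums
bruteForceIev <- function(pose, pocket, params = defaultEnergyParams()) {
  la <- pose@atoms; pa <- pocket@atoms
  withParent <- function(df, i) {
    at <- as.list(df[i, ])
    if (!is.na(at$hbparent))
      at$hbParentXyz <- as.numeric(df[at$hbparent, c("x", "y", "z")])
    at
  }
  rid <- paste(pa$chain, pa$resno, pa$resname, sep = ":")
  vals <- numeric(0)
  for (res in pocket@residueIds) {
    acc <- c(vdw = 0, coulomb = 0, hbond = 0)
    for (i in seq_len(nrow(la))) {
      for (j in which(rid == res)) {
        acc <- acc + pairEnergies(withParent(la, i), withParent(pa, j),
                                  params)
      }
    }
    vals <- c(vals, acc)
  }
  vals
}

# small paired dataset + pretrained halves for the fusion tests, built once
fxFusionParts <- function() {
  if (is.null(fx$fusionParts)) {
    ds <- suppressWarnings(
      makePairedDataset(fixtureSpec(nMolecules = 30L, nResidues = 3L,
                                    noise = 0.05, seed = 41L)))
    sv <- pretrainSmilesVae(pairedSmiles(ds),
                            smilesVaeConfig(embDim = 16L, encHidden = 24L,
                                            decHidden = 32L, batchSize = 10L,
                                            epochs = 3L, dropout = 0,
                                            maxLength = 60L), seed = 8L)
    iv <- pretrainIevVae(pairedIev(ds),
                         ievVaeConfig(latentDim = 6L,
                                      convChannels = c(4L, 6L), kernel = 3L,
                                      fcHidden = 16L, batchSize = 10L,
                                      epochs = 3L), seed = 9L)
    fx$fusionParts <- list(ds = ds, sv = sv, iv = iv)
  }
  fx$fusionParts
}

# small, quick SMILES-VAE used by several tests (built lazily, ~20 s)
fxTinyVae <- function() {
  if (is.null(fx$tinyVae)) {
    cfg <- smilesVaeConfig(embDim = 16L, encHidden = 24L, decHidden = 32L,
                           batchSize = 10L, epochs = 3L, dropout = 0,
                           maxLength = 60L)
    fx$tinyVae <- pretrainSmilesVae(fxCorpus(20L), cfg, seed = 3L)
  }
  fx$tinyVae
}
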