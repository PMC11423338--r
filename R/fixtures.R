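# Synthetic fixtures: toy SMILES corpora from a small fragment grammar, toy
# binding pockets with parameterized residues, deterministic ligand poses,
# and paired (SMILES, IEV) datasets with a planted structure->interaction
# relationship. Everything is a pure function of its seed, so fixture-based
# tests are exactly reproducible.

.ELECTRONEG <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
                 P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66)

.stable_seed <- function(seed, text) {
  as.integer((as.numeric(seed) * 7919 + .hash_ints(utf8ToInt(text))) %%
               2147483629)
}

#' Fixture specification
#'
#' Bundles the knobs of the synthetic paired dataset: corpus size, pocket
#' residue count, pocket radius, the standard deviation of the additive
#' Gaussian noise applied to each IEV entry (kcal/mol; emulates docking
#' noise), and the master seed that fully determines every output.
#'
#' @param nMolecules corpus size.
#' @param nResidues pocket residue count R (IEV length 3R).
#' @param radius pocket radius in Angstrom (default 12).
#' @param noise IEV noise standard deviation, kcal/mol (default 0.1).
#' @param seed master seed.
#' @return named list.
#' @export
fixtureSpec <- function(nMolecules = 120L, nResidues = 8L, radius = 12,
                        noise = 0.1, seed = 1L) {
  stopifnot(nMolecules >= 1L, nResidues >= 1L, noise >= 0, radius > 0)
  list(nMolecules = as.integer(nMolecules), nResidues = as.integer(nResidues),
       radius = radius, noise = noise, seed = as.integer(seed))
}

#' Generate a toy SMILES corpus
#'
#' Assembles molecules from a small fragment grammar (short heteroatom
#' backbones with halogen, nitrile, phenyl, carboxyl and alkyl branches),
#' canonicalizes, and keeps unique valid molecules until `n` are collected.
#' Deterministic for a given seed.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return character vector of `n` unique canonical SMILES.
#' @export
makeToyCorpus <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))
  backbone_pool <- c("C", "C", "C", "C", "N", "O")
  branch_pool <- c("F", "Cl", "Br", "O", "N", "C", "CC", "C#N",
                   "c1ccccc1", "C(=O)O", "C(=O)N", "OC", "C(C)C", "S",
                   "CO", "CN", "C(F)(F)F", "CCl", "c1ccncc1", "C=C")
  out <- character()
  guard <- 0L
  while (length(out) < n && guard < 200L * n) {
    guard <- guard + 1L
    len <- sample(2:6, 1L)
    atoms <- sample(backbone_pool, len, replace = TRUE)
    s <- ""
    for (i in seq_len(len)) {
      s <- paste0(s, atoms[i])
      if (atoms[i] == "C" && stats::runif(1) < 0.35)
        s <- paste0(s, "(", sample(branch_pool, 1L), ")")
    }
    can <- canonicalizeSmiles(s)
    if (!is.na(can) && !(can %in% out)) out <- c(out, can)
  }
  if (length(out) < n) stop("fragment grammar exhausted before reaching n")
  out
}

#' Build a toy binding pocket
#'
#' Places `R` small residues (N, CA, C=O backbone fragment plus an amide
#' hydrogen) on a shell 4-10 Angstrom from the pocket center, parameterized
#' with the built-in charge/LJ tables; the amide H is a hydrogen-bond donor,
#' backbone N/O are acceptors. Coordinates are rounded to 0.001 Angstrom so
#' the pocket survives a PDB write/read round trip bit-exactly. When `file`
#' is given the structure is also written as a PDB file readable by
#' [selectPocketResidues].
#'
#' @param R residue count.
#' @param seed integer seed.
#' @param radius pocket radius recorded on the object (default 12).
#' @param file optional PDB output path.
#' @param center pocket center (default origin).
#' @return a [Pocket-class].
#' @export
makeToyPocket <- function(R, seed = 1L, radius = 12, file = NULL,
                          center = c(0, 0, 0)) {
  stopifnot(R >= 1L)
  set.seed(as.integer(seed))
  golden <- pi * (3 - sqrt(5))
  rows <- vector("list", R)
  resnames <- rep(c("ALA", "SER", "THR", "VAL", "GLY", "LEU", "ASN", "ASP"),
                  length.out = R)
  for (i in seq_len(R)) {
    # quasi-uniform shell directions, shell radius in [4, 10]
    t <- (i - 0.5) / R
    zdir <- 1 - 2 * t
    rho <- sqrt(max(0, 1 - zdir^2))
    th <- golden * (i - 1) + stats::runif(1, -0.2, 0.2)
    dir <- c(rho * cos(th), rho * sin(th), zdir)
    rc <- center + dir * stats::runif(1, 4, 10)
    # local frame for the residue fragment
    perp <- c(-dir[2], dir[1], 0)
    if (sum(perp^2) < 1e-8) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    perp2 <- c(dir[2] * perp[3] - dir[3] * perp[2],
               dir[3] * perp[1] - dir[1] * perp[3],
               dir[1] * perp[2] - dir[2] * perp[1])
    posN <- rc
    posCA <- rc + 1.46 * perp
    posC <- posCA + 1.52 * perp2
    posO <- posC + 1.23 * dir
    posH <- posN - 1.00 * perp2  # amide H on N
    coords <- round(rbind(posN, posCA, posC, posO, posH), 3)
    rows[[i]] <- data.frame(
      chain = "A", resno = i, resname = resnames[i],
      atom = c("N", "CA", "C", "O", "H"),
      element = c("N", "C", "C", "O", "H"),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df <- .parameterize_protein_atoms(df, defaultEnergyParams())
  pocket <- new("Pocket", center = as.numeric(center),
                radius = as.numeric(radius), atoms = df,
                residueIds = unique(paste(df$chain, df$resno, df$resname,
                                          sep = ":")))
  if (!is.null(file)) writePocketPdb(pocket, file)
  pocket
}

#' Write a pocket as a PDB file
#'
#' @param pocket a [Pocket-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writePocketPdb <- function(pocket, file) {
  a <- pocket@atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$atom,
                   elesy = a$element)
  invisible(file)
}

.parameterize_ligand_graph <- function(g, coords, params) {
  # coords: (n heavy + n H) x 3 in the order heavy atoms, then hydrogens
  # appended parent-by-parent
  el <- g$atoms$element
  el[el == "*"] <- "C"
  nheavy <- length(el)
  hparent <- integer(0)
  for (i in seq_len(nheavy)) hparent <- c(hparent, rep(i, g$atoms$nH[i]))
  allel <- c(el, rep("H", length(hparent)))
  n <- length(allel)
  q <- numeric(n)
  chi <- .ELECTRONEG[allel]
  chi[is.na(chi)] <- 2.55
  transfer <- function(i, j) {
    d <- 0.16 * (chi[j] - chi[i])
    q[i] <<- q[i] + d
    q[j] <<- q[j] - d
  }
  if (nrow(g$bonds) > 0L)
    for (b in seq_len(nrow(g$bonds))) transfer(g$bonds$a1[b], g$bonds$a2[b])
  for (h in seq_along(hparent)) transfer(nheavy + h, hparent[h])
  q[seq_len(nheavy)] <- q[seq_len(nheavy)] + g$atoms$charge

  lj <- .lj_lookup(allel, params$lj)
  bsum <- numeric(nheavy)
  if (nrow(g$bonds) > 0L)
    for (b in seq_len(nrow(g$bonds))) {
      bsum[g$bonds$a1[b]] <- bsum[g$bonds$a1[b]] + g$bonds$order[b]
      bsum[g$bonds$a2[b]] <- bsum[g$bonds$a2[b]] + g$bonds$order[b]
    }
  hbrole <- rep("none", n)
  hbparent <- rep(NA_integer_, n)
  acceptor <- (el == "O") | (el == "N" & bsum + g$atoms$nH < 4 &
                               g$atoms$charge <= 0)
  hbrole[seq_len(nheavy)][acceptor] <- "acceptor"
  for (h in seq_along(hparent)) {
    if (el[hparent[h]] %in% c("N", "O", "S")) {
      hbrole[nheavy + h] <- "donorH"
      hbparent[nheavy + h] <- hparent[h]
    }
  }
  data.frame(atom = c(paste0(el, seq_len(nheavy)),
                      paste0("H", seq_along(hparent))),
             element = allel, x = coords[, 1], y = coords[, 2],
             z = coords[, 3], charge = q, eps = lj$eps, sigma = lj$sigma,
             hbrole = hbrole, hbparent = hbparent,
             stringsAsFactors = FALSE)
}

#' Place a deterministic 3D pose of a molecule in a pocket
#'
#' Embeds the molecular graph with a deterministic internal 3D layout
#' (breadth-first placement at standard bond lengths, clash-avoiding
#' direction search driven by a seeded RNG, explicit hydrogens), translates
#' the heavy-atom centroid to the pocket center, and parameterizes the atoms
#' (electronegativity-equalization partial charges, element LJ table, H-bond
#' roles from connectivity). The layout is a synthetic stand-in for a
#' docking pose: identical (molecule, seed) pairs give identical
#' coordinates.
#'
#' @param smiles a valid SMILES string.
#' @param pocket a [Pocket-class].
#' @param seed integer seed.
#' @param params energy parameter set (see [defaultEnergyParams]).
#' @return a [LigandPose-class].
#' @export
placePose <- function(smiles, pocket, seed = 1L,
                      params = defaultEnergyParams()) {
  g <- parseSmiles(smiles)
  if (is.null(g)) stop("embedding failure: unparseable molecule")
  set.seed(.stable_seed(seed, smiles))
  nheavy <- nrow(g$atoms)
  adj <- vector("list", nheavy)
  if (nrow(g$bonds) > 0L)
    for (b in seq_len(nrow(g$bonds))) {
      adj[[g$bonds$a1[b]]] <- c(adj[[g$bonds$a1[b]]], g$bonds$a2[b])
      adj[[g$bonds$a2[b]]] <- c(adj[[g$bonds$a2[b]]], g$bonds$a1[b])
    }
  pk_xyz <- as.matrix(pocket@atoms[, c("x", "y", "z")])
  # fixed candidate directions (icosahedron-like spiral): the layout is a
  # canonical, purely graph-determined conformation, so structurally
  # similar molecules get geometrically similar poses
  ndir <- 16L
  tgold <- pi * (3 - sqrt(5))
  dirs <- t(vapply(seq_len(ndir), function(i) {
    zd <- 1 - 2 * (i - 0.5) / ndir
    rho <- sqrt(max(0, 1 - zd^2))
    c(rho * cos(tgold * (i - 1)), rho * sin(tgold * (i - 1)), zd)
  }, numeric(3)))
  pos <- matrix(NA_real_, nheavy, 3L)
  place_one <- function(origin, blen, placed) {
    best <- NULL; bestd <- -Inf
    for (k in seq_len(ndir)) {
      cand <- origin + blen * dirs[k, ]
      d <- if (length(placed)) min(sqrt(rowSums(
        (pos[placed, , drop = FALSE] - matrix(cand, length(placed), 3L,
                                              byrow = TRUE))^2))) else Inf
      if (d > bestd + 1e-9) { bestd <- d; best <- cand }
    }
    best
  }
  placed <- integer()
  for (root in seq_len(nheavy)) {
    if (root %in% placed) next
    pos[root, ] <- if (length(placed) == 0L) c(0, 0, 0)
                   else place_one(pos[placed[length(placed)], ], 3.0, placed)
    placed <- c(placed, root)
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (w %in% placed) next
        pos[w, ] <- place_one(pos[v, ], 1.5, placed)
        placed <- c(placed, w)
        queue <- c(queue, w)
      }
    }
  }
  hpos <- NULL
  for (i in seq_len(nheavy)) {
    nh <- g$atoms$nH[i]
    if (nh > 0L)
      for (k in seq_len(nh)) {
        hp <- place_one(pos[i, ], 1.0, placed)
        hpos <- rbind(hpos, hp)
      }
  }
  coords0 <- rbind(pos, hpos)
  centroid <- colMeans(pos)
  coords0 <- sweep(coords0, 2L, centroid, "-")
  # seeded jitter emulates pose noise without destroying determinism
  coords0 <- coords0 + matrix(stats::rnorm(length(coords0), sd = 0.05),
                              nrow(coords0))
  # docking keeps the best-scored pose: score a fixed set of rigid
  # orientations of the canonical conformer at the pocket center and keep
  # the lowest-energy one (this also rules out steric clashes, whose
  # energies explode)
  rotmat <- function(axis, th) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3L)
    diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  offsets <- rbind(c(0, 0, 0), 1.5 * diag(3L), -1.5 * diag(3L))
  best <- NULL; bestE <- Inf
  for (o in seq_len(8L)) {
    Rm <- rotmat(dirs[o, ], o * 2.399963)
    rot <- coords0 %*% Rm
    for (f in seq_len(nrow(offsets))) {
      cand <- sweep(rot, 2L, pocket@center + offsets[f, ], "+")
      atoms <- .parameterize_ligand_graph(g, cand, params)
      E <- sum(suppressWarnings(
        computeIev(new("LigandPose", smiles = smiles, atoms = atoms),
                   pocket, params))@values)
      if (E < bestE) { bestE <- E; best <- atoms }
    }
  }
  atoms <- best
  # donor-parent indices refer to rows of this same atom table
  new("LigandPose", smiles = smiles, atoms = atoms)
}

#' Build a paired SMILES/IEV dataset
#'
#' For each molecule of a toy corpus, computes its IEV from a deterministic
#' pose in a shared toy pocket and adds i.i.d. Gaussian noise of standard
#' deviation `spec$noise` to every entry. The interaction profile is thus a
#' planted (noisy) function of the structure — the synthetic analogue of an
#' actives set with docking-derived interaction energies.
#'
#' @param spec a [fixtureSpec] list.
#' @return a [PairedIevDataset-class].
#' @export
makePairedDataset <- function(spec = fixtureSpec()) {
  corpus <- makeToyCorpus(spec$nMolecules, seed = spec$seed)
  pocket <- makeToyPocket(spec$nResidues, seed = spec$seed + 1L,
                          radius = spec$radius)
  ievs <- NULL; kept <- character()
  for (s in corpus) {
    pose <- tryCatch(placePose(s, pocket, seed = spec$seed),
                     error = function(e) NULL)
    if (is.null(pose)) { message("embedding failed for ", s, "; skipped"); next }
    v <- computeIev(pose, pocket)
    ievs <- rbind(ievs, v@values)
    kept <- c(kept, s)
  }
  labels <- computeIev(placePose(kept[1], pocket, seed = spec$seed),
                       pocket)@labels
  if (spec$noise > 0) {
    set.seed(spec$seed + 2L)
    ievs <- ievs + matrix(stats::rnorm(length(ievs), sd = spec$noise),
                          nrow(ievs))
  }
  colnames(ievs) <- labels
  new("PairedIevDataset", smiles = kept, iev = ievs, labels = labels,
      pocket = pocket, spec = spec)
}

#' @describeIn makePairedDataset IEV matrix of a paired dataset.
#' @param x a [PairedIevDataset-class].
#' @export
pairedIev <- function(x) x@iev

#' @describeIn makePairedDataset SMILES of a paired dataset.
#' @export
pairedSmiles <- function(x) x@smiles
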