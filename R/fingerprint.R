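# Circular (Morgan-style) substructure fingerprint, radius 2, hashed to a
# fixed bit length. Same algorithm family as ECFP4: iteratively refined atom
# environment identifiers, one hashed bit per (atom, radius) environment.
# The hash is the package's own (deterministic, documented), so bit positions
# are not interchangeable with other toolkits' ECFP implementations —
# everything downstream (Tanimoto, diversity, clustering, PCA) only needs a
# deterministic fixed-length bitset.

.MOD31 <- 2147483647  # 2^31 - 1; keeps hash arithmetic exact in doubles

.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% .MOD31)) %% .MOD31
  h
}

#' Circular fingerprint of a molecule
#'
#' Morgan-algorithm circular fingerprint: initial atom invariants are
#' (atomic number, heavy degree, total H count, formal charge, aromaticity,
#' ring membership); each iteration hashes an atom's invariant with the
#' (bond order, neighbour invariant) pairs sorted canonically. Environments
#' of radius 0..`radius` each set one bit (radius 2 corresponds to ECFP4
#' diameter-4 environments).
#'
#' @param smiles a single SMILES string (or a parsed graph from
#'   [parseSmiles]).
#' @param radius neighbourhood radius (default 2).
#' @param nbits fingerprint length, typically 1024 or 2048 (default 2048).
#' @return logical vector of length `nbits`, or `NA` for an invalid molecule.
#' @examples
#' sum(ecfpFingerprint("c1ccccc1O"))
#' @export
ecfpFingerprint <- function(smiles, radius = 2L, nbits = 2048L) {
  g <- if (is.list(smiles)) smiles else parseSmiles(smiles)
  if (is.null(g)) return(NA)
  a <- g$atoms; b <- g$bonds
  n <- nrow(a)
  el <- a$element; el[el == "*"] <- "C"
  inv <- vapply(seq_len(n), function(i) .hash_ints(c(
    .ATOMIC_NUM[[el[i]]], a$degree[i], a$nH[i], a$charge[i] + 10,
    as.integer(a$aromatic[i]), as.integer(a$inRing[i]))), 0)
  nbr <- vector("list", n)
  if (nrow(b) > 0L) {
    for (i in seq_len(nrow(b))) {
      o <- as.integer(round(b$order[i] * 2))  # 2,3,4,6 for -,:,=,#
      nbr[[b$a1[i]]] <- rbind(nbr[[b$a1[i]]], c(o, b$a2[i]))
      nbr[[b$a2[i]]] <- rbind(nbr[[b$a2[i]]], c(o, b$a1[i]))
    }
  }
  bits <- rep(FALSE, nbits)
  bits[(inv %% nbits) + 1] <- TRUE
  for (r in seq_len(radius)) {
    newinv <- numeric(n)
    for (i in seq_len(n)) {
      if (is.null(nbr[[i]])) { newinv[i] <- .hash_ints(c(r, inv[i])); next }
      pairs <- cbind(nbr[[i]][, 1], inv[nbr[[i]][, 2]])
      ord <- order(pairs[, 1], pairs[, 2])
      newinv[i] <- .hash_ints(c(r, inv[i], t(pairs[ord, , drop = FALSE])))
    }
    inv <- newinv
    bits[(inv %% nbits) + 1] <- TRUE
  }
  bits
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles character vector of SMILES.
#' @inheritParams ecfpFingerprint
#' @return logical matrix, molecules x bits; rows of invalid molecules are NA.
#' @export
ecfpMatrix <- function(smiles, radius = 2L, nbits = 2048L) {
  out <- matrix(NA, nrow = length(smiles), ncol = nbits)
  for (i in seq_along(smiles)) {
    fp <- ecfpFingerprint(smiles[i], radius = radius, nbits = nbits)
    if (!all(is.na(fp))) out[i, ] <- fp
  }
  out
}
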