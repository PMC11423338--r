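# Pocket selection and parameterization from PDB structures.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.element_from_pdb <- function(elesy, atomName) {
  el <- toupper(trimws(elesy))
  bad <- is.na(el) | !nzchar(el)
  if (any(bad)) {
    nm <- gsub("[0-9']", "", trimws(atomName[bad]))
    two <- substr(nm, 1, 2) %in% c("CL", "BR", "NA", "MG", "ZN", "SE", "FE")
    el[bad] <- ifelse(two, substr(nm, 1, 2), substr(nm, 1, 1))
  }
  el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
  el
}

.parameterize_protein_atoms <- function(df, params) {
  lj <- .lj_lookup(df$element, params$lj)
  df$eps <- lj$eps
  df$sigma <- lj$sigma
  chg <- params$proteinCharge[df$element]
  chg[is.na(chg)] <- 0
  df$charge <- unname(chg)
  # H-bond roles: N/O are acceptors; an H whose nearest heavy atom within
  # 1.3 Angstrom is N/O is a donor hydrogen attached to it
  df$hbrole <- ifelse(df$element %in% c("N", "O"), "acceptor", "none")
  df$hbparent <- NA_integer_
  hidx <- which(df$element == "H")
  heavy <- which(df$element != "H")
  if (length(hidx) && length(heavy)) {
    hm <- as.matrix(df[hidx, c("x", "y", "z")])
    pm <- as.matrix(df[heavy, c("x", "y", "z")])
    for (k in seq_along(hidx)) {
      d2 <- colSums((t(pm) - hm[k, ])^2)
      j <- which.min(d2)
      if (d2[j] < 1.3^2 && df$element[heavy[j]] %in% c("N", "O", "S")) {
        df$hbrole[hidx[k]] <- "donorH"
        df$hbparent[hidx[k]] <- heavy[j]
      }
    }
  }
  df
}

#' Select pocket residues around a grid center
#'
#' A residue is part of the pocket iff any of its heavy atoms lies within
#' `radius` of `center` (`scheme = "heavy"`, default) or its C-alpha does
#' (`scheme = "calpha"`). Residues are ordered ascending by (chain, residue
#' number) — the order the residue numbers are assigned in the PDB file —
#' which fixes the IEV layout. Waters, ions and other hetero residues are
#' excluded unless `includeHetero = TRUE`.
#'
#' @param structure a `bio3d` pdb object (from [bio3d::read.pdb]) or a path
#'   to a PDB file.
#' @param center numeric xyz of the grid center (Angstrom), typically the
#'   cocrystal ligand centroid.
#' @param radius inclusion radius in Angstrom (default 12).
#' @param scheme residue inclusion test, "heavy" or "calpha".
#' @param includeHetero include non-standard residues (default FALSE).
#' @param params nonbonded parameter set (see [defaultEnergyParams]).
#' @return a [Pocket-class] object.
#' @export
selectPocketResidues <- function(structure, center, radius = 12,
                                 scheme = c("heavy", "calpha"),
                                 includeHetero = FALSE,
                                 params = defaultEnergyParams()) {
  scheme <- match.arg(scheme)
  stopifnot(length(center) == 3L, is.finite(center), radius >= 0)
  pdb <- if (is.character(structure)) bio3d::read.pdb(structure) else structure
  at <- pdb$atom
  if (!includeHetero) at <- at[at$resid %in% .AA3, , drop = FALSE]
  if (nrow(at) == 0L) stop("structure contains no protein residue")
  at$chain[is.na(at$chain)] <- "A"
  df <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                   atom = at$elety,
                   element = .element_from_pdb(at$elesy, at$elety),
                   x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  rid <- paste(df$chain, df$resno, df$resname, sep = ":")
  d <- sqrt((df$x - center[1])^2 + (df$y - center[2])^2 +
            (df$z - center[3])^2)
  test_atom <- if (scheme == "heavy") df$element != "H"
               else df$atom == "CA"
  keep_rid <- unique(rid[test_atom & d <= radius])
  if (length(keep_rid) == 0L)
    stop("empty pocket: no residue within ", radius,
         " Angstrom of the center")
  df <- df[rid %in% keep_rid, , drop = FALSE]
  ord <- order(df$chain, df$resno,
               match(paste(df$chain, df$resno, df$resname, sep = ":"),
                     unique(rid)))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df <- .parameterize_protein_atoms(df, params)
  new("Pocket", center = as.numeric(center), radius = as.numeric(radius),
      atoms = df,
      residueIds = unique(paste(df$chain, df$resno, df$resname, sep = ":")))
}

#' @describeIn selectPocketResidues residue identifiers of a pocket, in IEV
#'   order.
#' @param pocket a [Pocket-class].
#' @export
pocketResidues <- function(pocket) pocket@residueIds

#' @describeIn selectPocketResidues parameterized atom table of a pocket.
#' @export
pocketAtoms <- function(pocket) pocket@atoms
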