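# Pairwise nonbonded energies and the interaction energy vector.
#
# Open energy backend: Lennard-Jones 12-6 with Lorentz-Berthelot combining
# rules, Coulomb with a distance-dependent dielectric (D = r) by default,
# and a 12-10 hydrogen-bond term gated on donor-H/acceptor pairs within a
# distance cutoff and a minimum donor-H...acceptor angle. Users with access
# to docking software that exports interaction energies can bypass this
# backend entirely via readIevTable().

#' Pairwise interaction energies between two atoms
#'
#' Returns the (vdw, coulomb, hbond) energy triple in kcal/mol for one
#' ligand-atom/residue-atom pair. `atom1` and `atom2` are one-row data.frames
#' (or lists) with fields x, y, z, charge, eps, sigma, hbrole and optionally
#' the coordinates `hbParentXyz` of the donor heavy atom when the atom is a
#' donor hydrogen.
#'
#' The terms are: Lennard-Jones
#' \eqn{4\epsilon_{ij}[(\sigma_{ij}/r)^{12}-(\sigma_{ij}/r)^6]} with
#' \eqn{\epsilon_{ij}=\sqrt{\epsilon_i\epsilon_j}},
#' \eqn{\sigma_{ij}=(\sigma_i+\sigma_j)/2}; Coulomb
#' \eqn{k\,q_1 q_2/(D\,r)} with k = 332.0636 kcal A / (mol e^2) and D = r by
#' default; and a 12-10 potential
#' \eqn{\epsilon_{hb}[5(r_0/r)^{12}-6(r_0/r)^{10}]} applied only to
#' (donor-H, acceptor) pairs passing the geometric gate, else 0.
#' Interatomic distances below `params$rMin` are clamped with a warning
#' (degenerate pose).
#'
#' @param atom1,atom2 parameterized atoms (see above).
#' @param params energy parameters (see [defaultEnergyParams]).
#' @return named numeric vector c(vdw=, coulomb=, hbond=).
#' @examples
#' a <- list(x = 0, y = 0, z = 0, charge = 1, eps = 0, sigma = 3,
#'           hbrole = "none")
#' b <- list(x = 1, y = 0, z = 0, charge = 1, eps = 0, sigma = 3,
#'           hbrole = "none")
#' p <- defaultEnergyParams(); p$dielectric <- "constant"
#' pairEnergies(a, b, p)["coulomb"]  # 332.0636
#' @export
pairEnergies <- function(atom1, atom2, params = defaultEnergyParams()) {
  dx <- atom1$x - atom2$x; dy <- atom1$y - atom2$y; dz <- atom1$z - atom2$z
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (r < params$rMin) {
    warning("interatomic distance ", signif(r, 3), " below ", params$rMin,
            " Angstrom; clamped (degenerate pose)")
    r <- params$rMin
  }
  epsij <- sqrt(atom1$eps * atom2$eps)
  sigij <- (atom1$sigma + atom2$sigma) / 2
  sr6 <- (sigij / r)^6
  vdw <- 4 * epsij * (sr6 * sr6 - sr6)
  D <- if (identical(params$dielectric, "distance")) r
       else params$dielectricConstant
  coulomb <- params$coulombK * atom1$charge * atom2$charge / (D * r)
  hbond <- 0
  roles <- c(atom1$hbrole, atom2$hbrole)
  if (("donorH" %in% roles) && ("acceptor" %in% roles) &&
      atom1$hbrole != atom2$hbrole) {
    hb <- params$hbond
    if (r <= hb$cutoff) {
      donor <- if (atom1$hbrole == "donorH") atom1 else atom2
      acceptor <- if (atom1$hbrole == "donorH") atom2 else atom1
      ok <- TRUE
      if (!is.null(donor$hbParentXyz) && !anyNA(donor$hbParentXyz)) {
        hd <- c(donor$x, donor$y, donor$z)
        v1 <- donor$hbParentXyz - hd
        v2 <- c(acceptor$x, acceptor$y, acceptor$z) - hd
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ok <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= hb$angleMin
      }
      if (ok) {
        rr10 <- (hb$r0 / r)^10
        hbond <- hb$depth * (5 * rr10 * (hb$r0 / r)^2 - 6 * rr10)
      }
    }
  }
  c(vdw = vdw, coulomb = coulomb, hbond = hbond)
}

.atoms_with_parent_xyz <- function(df) {
  # attach donor-parent coordinates as columns px/py/pz for vectorized use
  df$px <- NA_real_; df$py <- NA_real_; df$pz <- NA_real_
  has <- !is.na(df$hbparent)
  if (any(has)) {
    df$px[has] <- df$x[df$hbparent[has]]
    df$py[has] <- df$y[df$hbparent[has]]
    df$pz[has] <- df$z[df$hbparent[has]]
  }
  df
}

#' Compute the interaction energy vector of a pose in a pocket
#'
#' For each pocket residue, sums the pairwise (vdw, coulomb, hbond) energies
#' over all (ligand atom, residue atom) pairs, producing one energy triplet
#' per residue in pocket residue order; the vector length is therefore three
#' times the number of pocket residues.
#'
#' @param pose a [LigandPose-class].
#' @param pocket a [Pocket-class] (non-empty).
#' @param params energy parameters (see [defaultEnergyParams]).
#' @return an [IEV-class].
#' @export
computeIev <- function(pose, pocket, params = defaultEnergyParams()) {
  la <- .atoms_with_parent_xyz(pose@atoms)
  pa <- .atoms_with_parent_xyz(pocket@atoms)
  if (nrow(pa) == 0L) stop("empty pocket")
  nl <- nrow(la); np <- nrow(pa)

  dx <- outer(la$x, pa$x, "-"); dy <- outer(la$y, pa$y, "-")
  dz <- outer(la$z, pa$z, "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (any(r < params$rMin)) {
    warning(sum(r < params$rMin), " atom pair(s) closer than ", params$rMin,
            " Angstrom; clamped (degenerate pose)")
    r[r < params$rMin] <- params$rMin
  }
  epsij <- sqrt(outer(la$eps, pa$eps))
  sigij <- outer(la$sigma, pa$sigma, "+") / 2
  sr6 <- (sigij / r)^6
  vdw <- 4 * epsij * (sr6 * sr6 - sr6)
  D <- if (identical(params$dielectric, "distance")) r
       else params$dielectricConstant
  coulomb <- params$coulombK * outer(la$charge, pa$charge) / (D * r)

  hbond <- matrix(0, nl, np)
  hb <- params$hbond
  # ligand donor-H vs pocket acceptor, and pocket donor-H vs ligand acceptor
  for (dir in 1:2) {
    if (dir == 1L) {
      di <- which(la$hbrole == "donorH"); ai <- which(pa$hbrole == "acceptor")
      if (!length(di) || !length(ai)) next
      dX <- la[di, ]; aX <- pa[ai, ]
    } else {
      di <- which(pa$hbrole == "donorH"); ai <- which(la$hbrole == "acceptor")
      if (!length(di) || !length(ai)) next
      dX <- pa[di, ]; aX <- la[ai, ]
    }
    for (u in seq_along(di)) {
      hx <- c(dX$x[u], dX$y[u], dX$z[u])
      pvec <- c(dX$px[u], dX$py[u], dX$pz[u])
      for (v in seq_along(ai)) {
        rr <- if (dir == 1L) r[di[u], ai[v]] else r[ai[v], di[u]]
        if (rr > hb$cutoff) next
        ok <- TRUE
        if (!anyNA(pvec)) {
          v1 <- pvec - hx
          v2 <- c(aX$x[v], aX$y[v], aX$z[v]) - hx
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          ok <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= hb$angleMin
        }
        if (ok) {
          rr10 <- (hb$r0 / rr)^10
          e <- hb$depth * (5 * rr10 * (hb$r0 / rr)^2 - 6 * rr10)
          if (dir == 1L) hbond[di[u], ai[v]] <- hbond[di[u], ai[v]] + e
          else hbond[ai[v], di[u]] <- hbond[ai[v], di[u]] + e
        }
      }
    }
  }

  rid <- paste(pa$chain, pa$resno, pa$resname, sep = ":")
  grp <- factor(rid, levels = pocket@residueIds)
  per_res <- function(m) as.numeric(rowsum(colSums(m), as.integer(grp)))
  vr <- per_res(vdw); cr <- per_res(coulomb); hr <- per_res(hbond)
  values <- as.numeric(rbind(vr, cr, hr))
  labels <- as.character(t(outer(pocket@residueIds,
                                 c("vdw", "coulomb", "hbond"), paste,
                                 sep = "_")))
  new("IEV", values = values, labels = labels)
}

#' @describeIn computeIev energy values of an IEV.
#' @param iev an [IEV-class].
#' @export
ievValues <- function(iev) stats::setNames(iev@values, iev@labels)

#' @describeIn computeIev labels of an IEV.
#' @export
ievLabels <- function(iev) iev@labels

#' Cosine similarity between two interaction energy vectors
#'
#' Standard cosine of the value vectors. The two IEVs must have identical
#' labels (same pocket, same layout); a zero vector has no direction and
#' yields `NA` with a warning.
#'
#' @param a,b [IEV-class] objects with identical labels.
#' @return cosine similarity in `[-1, 1]`, or `NA` when undefined.
#' @export
ievCosine <- function(a, b) {
  if (!identical(a@labels, b@labels))
    stop("incompatible IEVs: labels differ")
  na <- sqrt(sum(a@values^2)); nb <- sqrt(sum(b@values^2))
  if (na == 0 || nb == 0) {
    warning("cosine similarity undefined for a zero IEV")
    return(NA_real_)
  }
  sum(a@values * b@values) / (na * nb)
}
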