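# Built-in nonbonded parameter tables. Lennard-Jones well depths (kcal/mol)
# and diameters (Angstrom) are generic element-level values in the range of
# common biomolecular force fields; partial charges for protein atoms come
# from a small per-element table. Everything is overridable through the
# `params` argument of the user-facing functions.

.LJ_TABLE <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  eps     = c(0.0157, 0.0860, 0.1700, 0.2100, 0.0610, 0.2000, 0.2500,
              0.2650, 0.3200, 0.4000),
  sigma   = c(2.50, 3.40, 3.25, 2.96, 3.12, 3.74, 3.55, 3.47, 3.60, 3.83),
  stringsAsFactors = FALSE)

.PROTEIN_CHARGE <- c(H = 0.15, C = 0.05, N = -0.35, O = -0.40, S = -0.10,
                     P = 0.40)

# H-bond 12-10 potential: well depth (kcal/mol) and optimum H...acceptor
# distance (Angstrom); geometric gate: distance cutoff and minimum
# donor-H...acceptor angle (degrees)
.HB_DEFAULTS <- list(depth = 1.0, r0 = 1.9, cutoff = 3.5, angleMin = 120)

#' Default nonbonded parameters
#'
#' Returns the package's built-in parameter set: per-element Lennard-Jones
#' (eps kcal/mol, sigma Angstrom), per-element protein partial charges, the
#' 12-10 hydrogen-bond constants, the Coulomb constant
#' 332.0636 kcal Angstrom / (mol e^2) and the dielectric model
#' ("distance", i.e. D = r, or "constant"). Pass a modified copy to the
#' energy functions to override any of them.
#'
#' @return named list with elements `lj`, `proteinCharge`, `hbond`,
#'   `coulombK`, `dielectric`, `dielectricConstant`, `rMin`.
#' @export
defaultEnergyParams <- function() {
  list(lj = .LJ_TABLE, proteinCharge = .PROTEIN_CHARGE, hbond = .HB_DEFAULTS,
       coulombK = 332.0636, dielectric = "distance", dielectricConstant = 1,
       rMin = 0.1)
}

.lj_lookup <- function(elements, lj = .LJ_TABLE) {
  i <- match(elements, lj$element)
  miss <- is.na(i)
  eps <- lj$eps[i]; sigma <- lj$sigma[i]
  # unknown elements get carbon-like defaults rather than failing the run
  eps[miss] <- 0.0860; sigma[miss] <- 3.40
  list(eps = eps, sigma = sigma)
}
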