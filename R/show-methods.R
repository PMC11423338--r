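#' Construct an interaction energy vector
#'
#' @param values numeric energies, kcal/mol, one (vdw, coulomb, hbond)
#'   triplet per residue.
#' @param residueIds character residue identifiers, one per triplet.
#' @return an [IEV-class].
#' @export
iev <- function(values, residueIds = NULL) {
  values <- as.numeric(values)
  if (is.null(residueIds))
    residueIds <- paste0("A:", seq_len(length(values) %/% 3L), ":RES")
  labels <- as.character(t(outer(residueIds, c("vdw", "coulomb", "hbond"),
                                 paste, sep = "_")))
  new("IEV", values = values, labels = labels)
}

setMethod("show", "Vocabulary", function(object) {
  cat("Vocabulary of", length(object@tokens), "chemical tokens +",
      length(object@specials), "specials; maxLength",
      object@maxLength, "\n")
  cat(" tokens:", paste(utils::head(object@tokens, 15), collapse = " "),
      if (length(object@tokens) > 15) "...\n" else "\n")
})

setMethod("show", "IEV", function(object) {
  R <- length(object@values) %/% 3L
  cat("IEV:", length(object@values), "energies (", R, "residues x 3 terms )\n")
  cat(" |v| =", format(sqrt(sum(object@values^2)), digits = 4),
      "kcal/mol; range",
      paste(format(range(object@values), digits = 3), collapse = " .. "),
      "\n")
})

setMethod("show", "Pocket", function(object) {
  cat("Pocket:", length(object@residueIds), "residues,",
      nrow(object@atoms), "atoms within", object@radius,
      "Angstrom of (", paste(format(object@center, digits = 3),
                             collapse = ", "), ")\n")
})

setMethod("show", "LigandPose", function(object) {
  cat("LigandPose of", object@smiles, "-", nrow(object@atoms), "atoms\n")
})

setMethod("show", "SmilesVae", function(object) {
  cat("SmilesVae: latent", object@config$latentDim, "| encoder biGRU",
      object@config$encHidden, "| decoder", object@config$decLayers,
      "x GRU", object@config$decHidden, "\n")
  if (nrow(object@trainLog))
    cat(" trained", nrow(object@trainLog), "epochs; final loss",
        format(utils::tail(object@trainLog$total, 1), digits = 4), "\n")
})

setMethod("show", "IevVae", function(object) {
  cat("IevVae: input", object@inputDim, "-> latent",
      object@config$latentDim, "\n")
  if (nrow(object@trainLog))
    cat(" trained", nrow(object@trainLog), "epochs; final loss",
        format(utils::tail(object@trainLog$total, 1), digits = 4), "\n")
})

setMethod("show", "FusionModel", function(object) {
  cat("FusionModel: (128 + 56) -> fusion", paste(object@config$hidden,
                                                 collapse = " -> "),
      "-> 128 -> SMILES decoder\n")
})

setMethod("show", "GenerationResult", function(object) {
  cat("GenerationResult:", object@nRequested, "samples,",
      sum(object@valid), "valid (seed", object@seed, ")\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat("  validity      ", format(object@validity, digits = 4), "%\n")
  cat("  uniqueness    ", format(object@uniqueness, digits = 4), "\n")
  cat("  diversity     ", format(object@diversity, digits = 4), "\n")
  cat("  IEV computable", object@nIevComputable, "\n")
  cat("  IEV cos >=", object@thresholds["cosine"], ":",
      object@nCosGe, "\n")
  cat("  ... and Tanimoto <=", object@thresholds["tanimoto"], ":",
      object@nCosGeTanLe, "\n")
})

setMethod("show", "PairedIevDataset", function(object) {
  cat("PairedIevDataset:", length(object@smiles), "molecules, IEV dim",
      ncol(object@iev), "(noise sd", object@spec$noise, "kcal/mol)\n")
})
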