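#' @import methods
NULL

#' Vocabulary of SMILES tokens
#'
#' Ordered chemical token set plus the four special tokens (pad, start, end,
#' unknown) used by the SMILES variational autoencoder. Chemical tokens come
#' after the specials in the index space, so index 1 is always the pad token.
#'
#' @slot tokens character vector of unique chemical tokens (sorted).
#' @slot specials named character vector with entries pad, start, end, unk.
#' @slot maxLength maximum token count (excluding start, including end) a
#'   sequence may have; longer SMILES are rejected at vocabulary build time.
#' @exportClass Vocabulary
setClass("Vocabulary",
  representation(tokens = "character", specials = "character",
                 maxLength = "integer"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@tokens)) msg <- c(msg, "tokens must be unique")
    if (!identical(sort(names(object@specials)),
                   sort(c("pad", "start", "end", "unk"))))
      msg <- c(msg, "specials must be named pad, start, end, unk")
    if (any(object@specials %in% object@tokens))
      msg <- c(msg, "specials must be disjoint from chemical tokens")
    if (length(object@maxLength) != 1L || object@maxLength < 1L)
      msg <- c(msg, "maxLength must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' Interaction energy vector
#'
#' Per-residue (vdW, Coulomb, H-bond) interaction energies between a ligand
#' pose and the residues of a binding pocket, in kcal/mol. The layout is one
#' triplet per pocket residue, residues in ascending (chain, residue number)
#' order and terms in the fixed order vdw, coulomb, hbond within each triplet,
#' so the vector length is always three times the residue count.
#'
#' @slot values numeric energy values, kcal/mol.
#' @slot labels character labels, one per value, of the form
#'   `<chain>:<resno>:<resname>_<term>` with term in vdw/coulomb/hbond.
#' @exportClass IEV
setClass("IEV",
  representation(values = "numeric", labels = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@values)
    if (n != length(object@labels))
      msg <- c(msg, "values and labels must have equal length")
    if (n %% 3L != 0L)
      msg <- c(msg, "length must be a multiple of 3 (one triplet per residue)")
    if (n > 0L) {
      terms <- sub("^.*_", "", object@labels)
      if (!identical(terms, rep(c("vdw", "coulomb", "hbond"), n %/% 3L)))
        msg <- c(msg, "labels must repeat (vdw, coulomb, hbond) per residue")
    }
    if (length(msg)) msg else TRUE
  })

#' Binding pocket definition
#'
#' The residues of a protein whose heavy atoms fall within `radius` of the
#' grid `center`, with per-atom nonbonded parameters. Atoms are stored as one
#' data.frame with columns chain, resno, resname, atom, element, x, y, z,
#' charge (e), eps (kcal/mol), sigma (Angstrom), hbrole
#' (one of "donorH", "acceptor", "none") and hbparent (row index of the donor
#' heavy atom for a donor hydrogen, NA otherwise). Residues are ordered
#' ascending by (chain, resno).
#'
#' @slot center numeric xyz of the grid center, Angstrom.
#' @slot radius numeric inclusion radius, Angstrom.
#' @slot atoms data.frame of parameterized atoms (schema above).
#' @slot residueIds character residue identifiers `<chain>:<resno>:<resname>`
#'   in pocket order.
#' @exportClass Pocket
setClass("Pocket",
  representation(center = "numeric", radius = "numeric",
                 atoms = "data.frame", residueIds = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@center) != 3L) msg <- c(msg, "center must be length 3")
    if (object@radius < 0) msg <- c(msg, "radius must be non-negative")
    need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z",
              "charge", "eps", "sigma", "hbrole", "hbparent")
    if (!all(need %in% names(object@atoms)))
      msg <- c(msg, "atoms is missing required columns")
    else {
      if (nrow(object@atoms) > 0L) {
        if (any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
          msg <- c(msg, "coordinates must be finite")
        if (any(object@atoms$eps < 0)) msg <- c(msg, "eps must be >= 0")
        if (any(object@atoms$sigma <= 0)) msg <- c(msg, "sigma must be > 0")
        rid <- paste(object@atoms$chain, object@atoms$resno,
                     object@atoms$resname, sep = ":")
        if (!identical(unique(rid), object@residueIds))
          msg <- c(msg, "residueIds must match atom order")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Ligand pose
#'
#' A 3D-placed ligand with the same per-atom parameter schema as
#' [Pocket-class] atoms (minus residue bookkeeping).
#'
#' @slot smiles canonical SMILES of the molecule.
#' @slot atoms data.frame with columns atom, element, x, y, z, charge, eps,
#'   sigma, hbrole, hbparent.
#' @exportClass LigandPose
setClass("LigandPose",
  representation(smiles = "character", atoms = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@atoms) == 0L) msg <- c(msg, "pose must contain atoms")
    else if (any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
      msg <- c(msg, "coordinates must be finite")
    if (length(msg)) msg else TRUE
  })

#' SMILES variational autoencoder
#'
#' Bidirectional GRU encoder to a 128-dimensional diagonal Gaussian latent,
#' 3-layer GRU decoder with dropout. Parameters live in a flat named list of
#' matrices; `trainLog` records one row per epoch.
#'
#' @slot vocab the [Vocabulary-class] the model was trained with.
#' @slot params named list of parameter matrices.
#' @slot config named list of hyperparameters (see [smilesVaeConfig]).
#' @slot trainLog data.frame with columns epoch, lSmiles, lKl, alpha, lr, total.
#' @exportClass SmilesVae
setClass("SmilesVae",
  representation(vocab = "Vocabulary", params = "list", config = "list",
                 trainLog = "data.frame"))

#' IEV variational autoencoder
#'
#' Conv1d + fully-connected encoder to a 56-dimensional latent and a
#' fully-connected decoder; trained with L1 reconstruction + KL.
#'
#' @slot params named list of parameter matrices and batchnorm running stats.
#' @slot config named list of hyperparameters (see [ievVaeConfig]).
#' @slot inputDim length of the IEVs (3 x residue count).
#' @slot labels IEV labels the model expects, in order.
#' @slot trainLog data.frame with columns epoch, lIev, lKl, lr, total.
#' @exportClass IevVae
setClass("IevVae",
  representation(params = "list", config = "list", inputDim = "integer",
                 labels = "character", trainLog = "data.frame"))

#' Fused conditional generator
#'
#' The end-to-end model: a frozen SMILES-VAE encoder, a frozen IEV-VAE, a
#' trainable fusion network (three fully connected layers mapping the
#' concatenated 128+56 latent back to the 128-dimensional SMILES latent) and
#' the fine-tuned SMILES decoder.
#'
#' @slot smilesVae the (decoder fine-tuned) [SmilesVae-class].
#' @slot ievVae the frozen [IevVae-class].
#' @slot zdnn named list of fusion-network weight matrices.
#' @slot config named list of hyperparameters (see [fusionConfig]).
#' @slot trainLog data.frame with columns epoch, lSmiles, lr.
#' @exportClass FusionModel
setClass("FusionModel",
  representation(smilesVae = "SmilesVae", ievVae = "IevVae", zdnn = "list",
                 config = "list", trainLog = "data.frame"))

#' Result of conditional generation
#'
#' @slot targetIev the conditioning [IEV-class].
#' @slot smiles generated SMILES strings (possibly invalid).
#' @slot valid logical parser-validity flag per sample.
#' @slot nRequested number of samples requested.
#' @slot seed integer seed used.
#' @exportClass GenerationResult
setClass("GenerationResult",
  representation(targetIev = "IEV", smiles = "character", valid = "logical",
                 nRequested = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@smiles) != object@nRequested)
      msg <- c(msg, "number of samples must equal nRequested")
    if (length(object@smiles) != length(object@valid))
      msg <- c(msg, "valid flags must match samples")
    if (length(msg)) msg else TRUE
  })

#' Evaluation metrics for a generated set
#'
#' The six headline statistics for a generated set against its seed compound:
#' validity (percent of requested samples that parse), uniqueness (fraction of
#' valid samples with distinct canonical SMILES), internal diversity
#' (1 - mean pairwise Tanimoto), and the three interaction-retention counts.
#'
#' @slot validity percent in `[0, 100]`.
#' @slot uniqueness fraction in `[0, 1]` (NA when no valid molecule).
#' @slot diversity internal diversity in `[0, 1]` (NA when no valid molecule).
#' @slot nIevComputable number of valid samples an IEV could be computed for.
#' @slot nCosGe of those, number with IEV cosine to the seed >= the cosine
#'   threshold.
#' @slot nCosGeTanLe of those, number additionally with Tanimoto to the seed
#'   <= the Tanimoto threshold.
#' @slot thresholds numeric named vector (cosine, tanimoto).
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(validity = "numeric", uniqueness = "numeric",
                 diversity = "numeric", nIevComputable = "integer",
                 nCosGe = "integer", nCosGeTanLe = "integer",
                 thresholds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@uniqueness) &&
        (object@uniqueness < 0 || object@uniqueness > 1))
      msg <- c(msg, "uniqueness must lie in [0, 1]")
    if (object@nCosGeTanLe > object@nCosGe ||
        object@nCosGe > object@nIevComputable)
      msg <- c(msg, "counts must satisfy nCosGeTanLe <= nCosGe <= nIevComputable")
    if (length(msg)) msg else TRUE
  })

#' Paired SMILES/IEV dataset
#'
#' Synthetic training data for the conditional generator: one IEV per
#' molecule, computed from a deterministic pose in a shared toy pocket (plus
#' optional Gaussian noise), so the interaction profile is a planted function
#' of the structure.
#'
#' @slot smiles canonical SMILES, one per row of `iev`.
#' @slot iev numeric matrix, molecules x (3 x residues), kcal/mol.
#' @slot labels IEV column labels.
#' @slot pocket the shared [Pocket-class].
#' @slot spec the fixture specification list used to build the dataset.
#' @exportClass PairedIevDataset
setClass("PairedIevDataset",
  representation(smiles = "character", iev = "matrix", labels = "character",
                 pocket = "Pocket", spec = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@iev) != length(object@smiles))
      msg <- c(msg, "one IEV row per SMILES required")
    if (ncol(object@iev) != length(object@labels))
      msg <- c(msg, "IEV columns must match labels")
    if (length(msg)) msg else TRUE
  })
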