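# Evaluation metrics for generated molecule sets: the MOSES-style validity /
# uniqueness / internal-diversity triple, interaction-retention counts
# against a seed compound, property profiling and chemical-space projection.

#' Tanimoto coefficient of two fingerprints
#'
#' `T = t / (S - f)` where t is the number of bits set in both fingerprints,
#' f the number set in neither and S the fingerprint length; algebraically
#' equal to `t / (a + b - t)` for on-bit counts a and b (intersection over
#' union). Undefined (NA with a warning) when both fingerprints are empty.
#'
#' @param fp1,fp2 logical vectors of equal length.
#' @return similarity in `[0, 1]`, or NA when undefined.
#' @export
tanimotoSimilarity <- function(fp1, fp2) {
  stopifnot(length(fp1) == length(fp2))
  t <- sum(fp1 & fp2)
  f <- sum(!fp1 & !fp2)
  S <- length(fp1)
  if (S - f == 0) {
    warning("Tanimoto undefined: both fingerprints are all-zero")
    return(NA_real_)
  }
  t / (S - f)
}

#' Internal diversity of a molecule set
#'
#' `1 - mean(T(m1, m2)^p)` over all ordered pairs of the set, self-pairs
#' included (the MOSES IntDiv convention); `p = 1` by default. A singleton
#' set has diversity 0.
#'
#' @param smiles character vector of valid SMILES, or a logical fingerprint
#'   matrix (rows = molecules).
#' @param p exponent on the Tanimoto coefficient (default 1).
#' @param nbits fingerprint length when `smiles` is character (default 2048,
#'   radius 2).
#' @param includeSelf include self-pairs (default TRUE).
#' @return diversity in `[0, 1]`.
#' @export
internalDiversity <- function(smiles, p = 1, nbits = 2048L,
                              includeSelf = TRUE) {
  M <- if (is.character(smiles)) ecfpMatrix(smiles, nbits = nbits)
       else as.matrix(smiles)
  if (nrow(M) == 0L || anyNA(M)) stop("diversity needs valid molecules only")
  storage.mode(M) <- "numeric"
  inter <- M %*% t(M)
  a <- rowSums(M)
  union <- outer(a, a, "+") - inter
  Tm <- ifelse(union == 0, 0, inter / union)
  if (!includeSelf) diag(Tm) <- NA
  1 - mean(Tm^p, na.rm = TRUE)
}

#' Validity, uniqueness and diversity of a generated set
#'
#' Validity is the percentage of requested samples that parse; uniqueness is
#' the fraction of valid samples with distinct canonical SMILES; diversity
#' is [internalDiversity] of the valid samples (ECFP-style 2048-bit
#' fingerprints). With zero valid molecules, uniqueness and diversity are NA.
#'
#' @param generated a [GenerationResult-class], or a character vector of
#'   SMILES (validity judged by the parser).
#' @return named list (validity, uniqueness, diversity).
#' @export
basicMetrics <- function(generated) {
  if (methods::is(generated, "GenerationResult")) {
    smi <- generated@smiles; ok <- generated@valid
  } else {
    smi <- generated; ok <- isValidSmiles(smi)
  }
  n <- length(smi)
  validity <- if (n == 0L) NA_real_ else 100 * sum(ok) / n
  if (!any(ok))
    return(list(validity = validity, uniqueness = NA_real_,
                diversity = NA_real_))
  valid <- smi[ok]
  can <- canonicalizeSmiles(valid)
  can[is.na(can)] <- valid[is.na(can)]
  uniqueness <- length(unique(can)) / length(valid)
  diversity <- internalDiversity(valid)
  list(validity = validity, uniqueness = uniqueness, diversity = diversity)
}

#' Interaction-retention metrics against a seed compound
#'
#' Counts, among the valid generated molecules, (1) those an IEV could be
#' obtained for (the open-backend stand-in for "able to dock"), (2) those
#' whose IEV cosine similarity to the seed IEV reaches `cosThreshold`, and
#' (3) those additionally with fingerprint Tanimoto to the seed of at most
#' `tanThreshold` — i.e. similar interaction profile but dissimilar
#' structure.
#'
#' IEVs are obtained either from `ievTable` (a named list of [IEV-class]
#' keyed by canonical SMILES, e.g. imported from an external docking tool
#' via [readIevTable]) or, when a `pocket` is given, by posing each molecule
#' with [placePose] and scoring with [computeIev].
#'
#' @param generated a [GenerationResult-class] or character vector of SMILES.
#' @param seedSmiles the seed compound's SMILES.
#' @param seedIev the seed compound's [IEV-class].
#' @param pocket a [Pocket-class] (open-backend route).
#' @param ievTable named list of IEVs (external route; wins when given).
#' @param cosThreshold,tanThreshold thresholds (defaults 0.7 and 0.5).
#' @param seed RNG seed for pose placement.
#' @return a [MetricsReport-class].
#' @export
interactionMetrics <- function(generated, seedSmiles, seedIev, pocket = NULL,
                               ievTable = NULL, cosThreshold = 0.7,
                               tanThreshold = 0.5, seed = 1L) {
  bm <- basicMetrics(generated)
  smi <- if (methods::is(generated, "GenerationResult")) generated@smiles
         else generated
  ok <- if (methods::is(generated, "GenerationResult")) generated@valid
        else isValidSmiles(smi)
  valid <- smi[ok]
  seedFp <- ecfpFingerprint(seedSmiles, nbits = 2048L)
  nIev <- 0L; nCos <- 0L; nBoth <- 0L
  cache <- new.env(parent = emptyenv())   # poses are deterministic per SMILES
  for (s in valid) {
    iev <- NULL
    if (!is.null(ievTable)) {
      key <- canonicalizeSmiles(s)
      if (!is.na(key) && !is.null(ievTable[[key]])) iev <- ievTable[[key]]
      else if (!is.null(ievTable[[s]])) iev <- ievTable[[s]]
    } else if (!is.null(pocket)) {
      if (is.null(cache[[s]])) {
        pose <- tryCatch(suppressWarnings(placePose(s, pocket, seed = seed)),
                         error = function(e) NULL)
        cache[[s]] <- if (is.null(pose)) list(NULL)
                      else list(computeIev(pose, pocket))
      }
      iev <- cache[[s]][[1]]
    }
    if (is.null(iev)) next
    nIev <- nIev + 1L
    cs <- suppressWarnings(ievCosine(iev, seedIev))
    if (!is.na(cs) && cs >= cosThreshold) {
      nCos <- nCos + 1L
      tn <- suppressWarnings(tanimotoSimilarity(
        ecfpFingerprint(s, nbits = 2048L), seedFp))
      if (!is.na(tn) && tn <= tanThreshold) nBoth <- nBoth + 1L
    }
  }
  new("MetricsReport",
      validity = bm$validity,
      uniqueness = bm$uniqueness,
      diversity = bm$diversity,
      nIevComputable = nIev, nCosGe = nCos, nCosGeTanLe = nBoth,
      thresholds = c(cosine = cosThreshold, tanimoto = tanThreshold))
}

#' QED and logP property profile
#'
#' Computes the quantitative estimate of drug-likeness (QED, in `[0, 1]`)
#' and the Crippen logP for each valid molecule with RDKit (invoked through
#' the system `python`, the toolkit conventionally used for these
#' descriptors). Invalid molecules are skipped with a message.
#'
#' @param smiles character vector of SMILES.
#' @param python python executable to use (default "python").
#' @return data.frame with columns smiles, qed, logp (one row per valid
#'   molecule).
#' @export
propertyProfile <- function(smiles, python = Sys.which("python")) {
  ok <- isValidSmiles(smiles)
  if (any(!ok)) message(sum(!ok), " invalid molecule(s) skipped")
  valid <- smiles[ok]
  if (length(valid) == 0L)
    return(data.frame(smiles = character(), qed = numeric(),
                      logp = numeric()))
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  writeLines(valid, fin)
  script <- paste(
    "import sys, csv",
    "from rdkit import Chem",
    "from rdkit.Chem import QED, Crippen",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "w = csv.writer(open(sys.argv[2], 'w'))",
    "for line in open(sys.argv[1]):",
    "    s = line.strip()",
    "    m = Chem.MolFromSmiles(s)",
    "    if m is None:",
    "        w.writerow([s, '', ''])",
    "    else:",
    "        w.writerow([s, QED.qed(m), Crippen.MolLogP(m)])",
    sep = "\n")
  status <- system2(python, c("-c", shQuote(script), shQuote(fin),
                              shQuote(fout)))
  if (status != 0L || !file.exists(fout))
    stop("property calculation via RDKit/python failed")
  out <- utils::read.csv(fout, header = FALSE,
                         col.names = c("smiles", "qed", "logp"))
  bad <- is.na(out$qed)
  if (any(bad)) message(sum(bad), " molecule(s) rejected by RDKit; skipped")
  out[!bad, , drop = FALSE]
}

#' Project molecules into a 2-D chemical space by PCA
#'
#' First two principal components of the 2048-bit fingerprint vectors
#' (deterministic up to sign).
#'
#' @param smiles character vector of at least 3 valid SMILES, or a
#'   fingerprint matrix.
#' @return matrix with 2 columns (PC1, PC2), one row per molecule.
#' @export
projectChemicalSpace <- function(smiles) {
  M <- if (is.character(smiles)) ecfpMatrix(smiles) else as.matrix(smiles)
  if (nrow(M) < 3L) stop("need at least 3 molecules for a PCA projection")
  if (anyNA(M)) stop("projection needs valid molecules only")
  storage.mode(M) <- "numeric"
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  pc$x[, 1:2, drop = FALSE]
}
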