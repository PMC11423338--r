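# Dataset preparation: canonicalization, largest-component retention,
# deduplication, vocabulary building, tokenization and cluster splitting.

.ob_canonical <- function(smiles) {
  # batch conversion through OpenBabel; one line in, one line out
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste(smiles, collapse = "\n")),
    error = function(e) NULL)
  if (is.null(out)) return(rep(NA_character_, length(smiles)))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("[ \t]+$", "", lines)
  if (length(lines) != length(smiles)) {
    # fall back to per-molecule conversion so one bad entry cannot shift rows
    return(vapply(smiles, function(s) {
      o <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
      o <- sub("[ \t\n]+$", "", o)
      if (nzchar(o)) o else NA_character_
    }, "", USE.NAMES = FALSE))
  }
  ifelse(nzchar(lines), lines, NA_character_)
}

#' Canonicalize SMILES strings
#'
#' Validates each string with the package's SMILES parser (syntax + valence),
#' then obtains a canonical form from OpenBabel. Canonicalization is
#' idempotent: the canonical form maps to itself. Invalid molecules yield
#' `NA` rather than an error, so batch jobs are never aborted by one bad
#' entry.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where invalid.
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO", "C((("))
#' @export
canonicalizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character())
  out <- rep(NA_character_, length(smiles))
  ok <- isValidSmiles(smiles)
  if (any(ok)) out[ok] <- .ob_canonical(smiles[ok])
  out
}

#' Keep the heaviest component of a multi-component SMILES
#'
#' Salt/solvent stripping: a SMILES with '.'-separated components is reduced
#' to the single component with the greatest molecular weight (ties keep the
#' first). Components that fail to parse are ignored; if none parses the
#' result is `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector with one component per input, `NA` where nothing
#'   parses.
#' @examples
#' keepLargestComponent("[Na+].CC(=O)[O-]")
#' @export
keepLargestComponent <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_character_)
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) return(NA_character_)
    mw <- molecularWeight(parts)
    if (all(is.na(mw))) return(NA_character_)
    parts[which.max(mw)]
  }, "", USE.NAMES = FALSE)
}

#' Remove duplicate molecules
#'
#' Keeps the first occurrence of each canonical SMILES; order is otherwise
#' preserved. Inputs are canonicalized first, so different writings of the
#' same molecule (e.g. "OCC" and "CCO") collapse.
#'
#' @param smiles character vector of SMILES strings.
#' @param canonicalize canonicalize before comparing (default TRUE; set to
#'   FALSE if the input is already canonical).
#' @return character vector of unique canonical SMILES (invalid entries are
#'   dropped with a warning).
#' @examples
#' deduplicateSmiles(c("CCO", "OCC", "CCN"))
#' @export
deduplicateSmiles <- function(smiles, canonicalize = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character())
  can <- if (canonicalize) canonicalizeSmiles(smiles) else smiles
  if (anyNA(can)) {
    warning(sum(is.na(can)), " invalid molecule(s) dropped during deduplication")
    can <- can[!is.na(can)]
  }
  can[!duplicated(can)]
}

#' Build a SMILES token vocabulary from a corpus
#'
#' Tokenizes every corpus entry with [smilesTokens] and collects the unique
#' chemical tokens; multi-character tokens (Cl, Br, bracket atoms, `%nn` ring
#' closures) are single vocabulary entries. Entries that fail to tokenize or
#' exceed `maxLength` tokens are rejected with a warning.
#'
#' @param corpus character vector of SMILES strings (non-empty).
#' @param maxLength maximum allowed token count (default 120).
#' @return a [Vocabulary-class] object.
#' @examples
#' vocabTokens(buildVocabulary(c("CCO", "CCCl")))
#' @export
buildVocabulary <- function(corpus, maxLength = 120L) {
  if (length(corpus) == 0L) stop("corpus must be non-empty")
  tokl <- lapply(corpus, smilesTokens)
  bad <- vapply(tokl, function(t) (length(t) == 1L && is.na(t[1])) ||
                  length(t) > maxLength - 1L, TRUE)
  if (any(bad)) {
    warning(sum(bad), " corpus entr(y/ies) rejected ",
            "(untokenizable or longer than maxLength)")
    tokl <- tokl[!bad]
  }
  if (length(tokl) == 0L) stop("no corpus entry survived tokenization")
  toks <- sort(unique(unlist(tokl)))
  new("Vocabulary", tokens = toks,
      specials = c(pad = "<pad>", start = "<bos>", end = "<eos>",
                   unk = "<unk>"),
      maxLength = as.integer(maxLength))
}

#' @describeIn buildVocabulary chemical tokens of a vocabulary.
#' @param vocab a [Vocabulary-class].
#' @export
vocabTokens <- function(vocab) vocab@tokens

#' @describeIn buildVocabulary total index-space size
#'   (specials + chemical tokens); the V of the decoder softmax.
#' @export
vocabSize <- function(vocab) length(vocab@tokens) + length(vocab@specials)

.vocab_index <- function(vocab) {
  # pad=1, start=2, end=3, unk=4, chemical tokens from 5
  idx <- seq_along(vocab@tokens) + 4L
  names(idx) <- vocab@tokens
  idx
}

#' Encode a SMILES string as vocabulary indices
#'
#' Produces `[start, tokens..., end]` indices. Out-of-vocabulary tokens are
#' rejected by default (`NULL` return) or mapped to the unknown token with
#' `oov = "unk"`.
#'
#' @param smiles a single SMILES string (the empty string is allowed and
#'   encodes to `[start, end]`).
#' @param vocab a [Vocabulary-class].
#' @param oov "reject" (default) or "unk".
#' @return integer vector of indices, or `NULL` when rejected.
#' @examples
#' v <- buildVocabulary(c("CCO"))
#' tokenizeSmiles("CCO", v)
#' @export
tokenizeSmiles <- function(smiles, vocab, oov = c("reject", "unk")) {
  oov <- match.arg(oov)
  toks <- smilesTokens(smiles)
  if (length(toks) == 1L && is.na(toks[1])) return(NULL)
  if (length(toks) > vocab@maxLength - 1L) return(NULL)
  map <- .vocab_index(vocab)
  idx <- unname(map[toks])
  if (anyNA(idx)) {
    if (oov == "reject") return(NULL)
    idx[is.na(idx)] <- 4L
  }
  c(2L, as.integer(idx), 3L)
}

#' Decode vocabulary indices back to a SMILES string
#'
#' Inverse of [tokenizeSmiles]: drops the start token, stops at the first end
#' token, and concatenates the chemical tokens. Round-trips every
#' in-vocabulary SMILES.
#'
#' @param indices integer vector of vocabulary indices.
#' @param vocab a [Vocabulary-class].
#' @return a SMILES string.
#' @export
detokenizeSmiles <- function(indices, vocab) {
  stopifnot(is.numeric(indices))
  indices <- as.integer(indices)
  if (length(indices) && indices[1] == 2L) indices <- indices[-1]
  stop_at <- which(indices == 3L)
  if (length(stop_at)) indices <- indices[seq_len(stop_at[1] - 1L)]
  indices <- indices[indices >= 5L]  # drop any specials that remain
  paste(vocab@tokens[indices - 4L], collapse = "")
}

#' Cluster-based train/test split in fingerprint space
#'
#' K-means clustering of the 1024-bit circular fingerprints; the single
#' compound nearest (Euclidean distance on the bit vectors) each cluster
#' centroid becomes a test compound, everything else is training data. Ties
#' are broken by the lowest record index. The split is deterministic for a
#' given seed (k-means++-style multi-restart via `nstart`).
#'
#' @param smiles character vector of (canonical) SMILES, length >= k.
#' @param k number of clusters / test compounds.
#' @param seed integer RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   covering the input) and the fitted `kmeans` object.
#' @examples
#' \donttest{
#' sp <- clusterSplit(makeToyCorpus(30, seed = 1), k = 3, seed = 1)
#' length(sp$test)
#' }
#' @export
clusterSplit <- function(smiles, k, seed = 1L, nstart = 10L) {
  n <- length(smiles)
  if (n < k) stop("need at least k records to form k clusters")
  fp <- t(vapply(smiles, function(s) as.numeric(ecfpFingerprint(s, nbits = 1024L)),
                 numeric(1024L), USE.NAMES = FALSE))
  if (anyNA(fp)) stop("all records must be valid molecules")
  set.seed(as.integer(seed))
  km <- stats::kmeans(fp, centers = k, nstart = nstart, iter.max = 100L)
  test <- integer(k)
  for (j in seq_len(k)) {
    d <- colSums((t(fp) - km$centers[j, ])^2)
    d[test[test > 0L]] <- Inf          # one test compound per cluster
    test[j] <- which(d == min(d))[1]   # lowest index on ties
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test, kmeans = km)
}

#' Read / write newline-delimited SMILES files
#'
#' `readSmi` reads a `.smi` file (one SMILES per line, optional
#' whitespace-separated name ignored); `writeSmi` writes one.
#'
#' @param path file path.
#' @return `readSmi`: character vector of SMILES.
#' @export
readSmi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(trimws(lines), "[ \t]+"), `[[`, "", 1L)
}

#' @rdname readSmi
#' @param smiles character vector to write.
#' @export
writeSmi <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
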