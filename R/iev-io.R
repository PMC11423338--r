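# IEV table I/O. The CSV schema makes the vector layout explicit: a header
# `id,<residue>_vdw,<residue>_coulomb,<residue>_hbond,...` with residues in
# pocket order, one row per compound. Tables exported from other energy
# backends (e.g. commercial docking suites) can be fed to the generator
# through this reader in place of the package's open backend.

#' Write a set of interaction energy vectors to CSV
#'
#' @param ievs a named list of [IEV-class] objects with identical labels, or
#'   a single IEV.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeIevTable <- function(ievs, path) {
  if (is(ievs, "IEV")) ievs <- list(iev = ievs)
  stopifnot(length(ievs) > 0L)
  labs <- ievs[[1]]@labels
  for (v in ievs) if (!identical(v@labels, labs))
    stop("incompatible IEVs: labels differ across entries")
  ids <- names(ievs)
  if (is.null(ids)) ids <- paste0("cpd", seq_along(ievs))
  rows <- vapply(seq_along(ievs), function(i) {
    paste(c(shQuote(ids[i], type = "cmd"),
            formatC(ievs[[i]]@values, digits = 17, format = "g")),
          collapse = ",")
  }, "")
  writeLines(c(paste(c("\"id\"", shQuote(labs, type = "cmd")),
                     collapse = ","), rows), path)
  invisible(path)
}

#' Read a CSV table of interaction energy vectors
#'
#' Inverse of [writeIevTable]; the round trip preserves values bitwise (the
#' writer prints full double precision). Structural problems are reported
#' with the offending line number.
#'
#' @param path CSV file with header `id,<residue>_<term>,...`.
#' @return named list of [IEV-class] objects (empty list for a header-only or
#'   empty file).
#' @export
readIevTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  split1 <- function(l) {
    x <- scan(text = l, what = character(), sep = ",", quiet = TRUE,
              strip.white = TRUE)
    x
  }
  header <- split1(lines[1])
  if (length(header) < 2L || header[1] != "id")
    stop("line 1: header must start with 'id' followed by label columns")
  labs <- header[-1]
  terms <- sub("^.*_", "", labs)
  if (length(labs) %% 3L != 0L ||
      !identical(terms, rep(c("vdw", "coulomb", "hbond"), length(labs) %/% 3L)))
    stop("line 1: label columns must be per-residue ",
         "(vdw, coulomb, hbond) triplets")
  out <- list()
  for (i in seq_along(lines)[-1]) {
    f <- split1(lines[i])
    if (length(f) != length(header))
      stop("line ", i, ": expected ", length(header), " fields, found ",
           length(f))
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals))
      stop("line ", i, ": non-numeric energy value")
    out[[f[1]]] <- new("IEV", values = vals, labels = labs)
  }
  out
}
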