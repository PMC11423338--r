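# SMILES tokenizer and molecular-graph parser.
#
# OpenBabel silently "repairs" malformed SMILES (e.g. it parses "C(((" as
# methane), which breaks the invalid-molecule contract that validity
# statistics depend on, so syntax and valence checking is done here on a
# purpose-built parser. The graph it produces also drives molecular weight,
# implicit-hydrogen counting, H-bond role assignment and the circular
# fingerprint.

.SMI_TOKEN_RE <- paste0(
  "\\[[^\\]]*\\]",              # bracket atom
  "|Cl|Br",                     # two-letter organic-subset atoms
  "|[BCNOPSFI]",                # one-letter organic subset
  "|[bcnops]",                  # aromatic organic subset
  "|%[0-9]{2}",                 # two-digit ring closure
  "|[0-9]",                     # ring closure
  "|[-=#$:/\\\\.()~*]"          # bonds, branches, dot, wildcard
)

.ATOMIC_NUM <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
                 P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Zn = 30, Se = 34,
                 Br = 35, I = 53)
.ATOMIC_WT <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                F = 18.998, Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06,
                Cl = 35.45, K = 39.098, Ca = 40.078, Zn = 65.38, Se = 78.971,
                Br = 79.904, I = 126.904)
# smallest-first standard valences used for implicit-H assignment
.VALENCES <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                  S = c(2, 4, 6), F = 1, Cl = c(1, 3, 5, 7),
                  Br = c(1, 3, 5, 7), I = c(1, 3, 5, 7))

#' Split a SMILES string into tokens
#'
#' Regex-based lossless tokenization: bracket atoms, `Cl`/`Br` and two-digit
#' ring closures (`%nn`) are single tokens; everything else is one character.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens, or `NA` if any character cannot be
#'   tokenized.
#' @examples
#' smilesTokens("CC(=O)Cl")
#' @export
smilesTokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles)) return(NA_character_)
  if (!nzchar(smiles)) return(character())
  m <- gregexpr(.SMI_TOKEN_RE, smiles, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NA_character_)
  toks <- regmatches(smiles, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(smiles)) return(NA_character_)
  toks
}

.parse_bracket <- function(tok) {
  inner <- substr(tok, 2L, nchar(tok) - 1L)
  m <- regexec(
    "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{1,2}|@TH[12])?(H[0-9]*)?((?:\\+[0-9]*|-[0-9]*|\\++|-+))?(:[0-9]+)?$",
    inner)
  g <- regmatches(inner, m)[[1]]
  if (length(g) == 0L) return(NULL)
  sym <- g[3]
  aromatic <- sym == tolower(sym) && sym != "*"
  elem <- if (sym == "*") "*" else paste0(toupper(substr(sym, 1, 1)),
                                          substr(sym, 2, nchar(sym)))
  if (elem != "*" && !(elem %in% names(.ATOMIC_NUM))) return(NULL)
  htok <- g[5]
  nH <- if (!nzchar(htok)) 0L
        else if (htok == "H") 1L
        else as.integer(substr(htok, 2L, nchar(htok)))
  ctok <- g[6]
  charge <- 0L
  if (nzchar(ctok)) {
    sign <- if (substr(ctok, 1, 1) == "+") 1L else -1L
    digits <- gsub("[+-]", "", ctok)
    charge <- if (nzchar(digits)) sign * as.integer(digits)
              else sign * nchar(ctok)
  }
  list(element = elem, aromatic = aromatic, charge = charge, nH = nH,
       bracket = TRUE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Stack-based parser covering the organic subset, bracket atoms with charge
#' and explicit hydrogen counts, aromatic lowercase atoms, ring closures
#' (including `%nn`), branches, dots and bond symbols. Stereochemistry tokens
#' are accepted and ignored. Implicit hydrogens are assigned from the
#' smallest standard valence that accommodates the bond order sum; an atom
#' that exceeds its maximum standard valence makes the molecule invalid.
#'
#' @param smiles a single SMILES string.
#' @return a list with elements `atoms` (data.frame: element, aromatic,
#'   charge, nH, inRing, degree), `bonds` (data.frame: a1, a2, order,
#'   aromatic) and `ncomp` (number of dot-separated components), or `NULL`
#'   for an invalid SMILES.
#' @examples
#' g <- parseSmiles("c1ccccc1O")
#' g$atoms$nH
#' @export
parseSmiles <- function(smiles) {
  toks <- smilesTokens(smiles)
  if (length(toks) == 1L && is.na(toks)) return(NULL)
  if (length(toks) == 0L) return(NULL)

  atoms <- list(); bonds <- list()
  prev <- NA_integer_         # atom awaiting the next bond
  stack <- integer()          # open branches
  pending <- ""               # bond symbol awaiting the next atom
  rings <- list()             # open ring closures: id -> list(atom, bond)
  ncomp <- 1L
  bond_order <- c("-" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1.5,
                  "/" = 1, "\\" = 1, "~" = 1)

  add_bond <- function(a1, a2, sym, arom_pair) {
    if (a1 == a2) return(FALSE)
    if (sym == "") {
      order <- if (arom_pair) 1.5 else 1
      arom <- arom_pair
    } else {
      order <- bond_order[[sym]]
      arom <- sym == ":"
    }
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = order,
                                         aromatic = arom)
    TRUE
  }

  for (tok in toks) {
    if (tok %in% c("-", "=", "#", "$", ":", "/", "\\", "~")) {
      if (pending != "" || is.na(prev)) return(NULL)
      pending <- tok
    } else if (tok == "(") {
      if (is.na(prev) || pending != "") return(NULL)
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L || pending != "") return(NULL)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      if (pending != "" || length(stack) > 0L || is.na(prev)) return(NULL)
      prev <- NA_integer_
      ncomp <- ncomp + 1L
    } else if (grepl("^%?[0-9]", tok)) {
      if (is.na(prev)) return(NULL)
      id <- sub("^%", "", tok)
      if (!is.null(rings[[id]])) {
        op <- rings[[id]]
        if (op$atom == prev) return(NULL)
        sym <- if (pending != "") pending else op$bond
        arom_pair <- atoms[[op$atom]]$aromatic && atoms[[prev]]$aromatic
        if (!add_bond(op$atom, prev, sym, arom_pair)) return(NULL)
        rings[[id]] <- NULL
      } else {
        rings[[id]] <- list(atom = prev, bond = pending)
      }
      pending <- ""
    } else {
      # an atom token
      if (startsWith(tok, "[")) {
        at <- .parse_bracket(tok)
        if (is.null(at)) return(NULL)
      } else if (tok == "*") {
        at <- list(element = "*", aromatic = FALSE, charge = 0L, nH = NA_integer_,
                   bracket = FALSE)
      } else {
        arom <- tok %in% c("b", "c", "n", "o", "p", "s")
        elem <- if (arom) toupper(tok) else tok
        at <- list(element = elem, aromatic = arom, charge = 0L,
                   nH = NA_integer_, bracket = FALSE)
      }
      atoms[[length(atoms) + 1L]] <- at
      idx <- length(atoms)
      if (!is.na(prev)) {
        arom_pair <- atoms[[prev]]$aromatic && at$aromatic
        if (!add_bond(prev, idx, pending, arom_pair)) return(NULL)
      }
      prev <- idx
      pending <- ""
    }
  }
  if (pending != "" || length(stack) > 0L || length(rings) > 0L) return(NULL)
  if (length(atoms) == 0L) return(NULL)

  n <- length(atoms)
  adf <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    nH = vapply(atoms, function(a) as.integer(a$nH), 0L),
    bracket = vapply(atoms, `[[`, TRUE, "bracket"),
    stringsAsFactors = FALSE)
  bdf <- if (length(bonds))
    data.frame(a1 = vapply(bonds, `[[`, 0L, "a1"),
               a2 = vapply(bonds, `[[`, 0L, "a2"),
               order = vapply(bonds, `[[`, 0, "order"),
               aromatic = vapply(bonds, `[[`, TRUE, "aromatic"))
  else data.frame(a1 = integer(), a2 = integer(), order = numeric(),
                  aromatic = logical())
  if (nrow(bdf) > 0L &&
      anyDuplicated(t(apply(bdf[, c("a1", "a2")], 1L, sort))))
    return(NULL)

  # bond order sums (aromatic bonds as 1.5, and separately as 1) and degree
  bsum <- numeric(n); asum <- numeric(n); deg <- integer(n)
  if (nrow(bdf) > 0L) {
    for (i in seq_len(nrow(bdf))) {
      o <- bdf$order[i]
      oa <- if (bdf$aromatic[i]) 1 else o
      bsum[bdf$a1[i]] <- bsum[bdf$a1[i]] + o
      bsum[bdf$a2[i]] <- bsum[bdf$a2[i]] + o
      asum[bdf$a1[i]] <- asum[bdf$a1[i]] + oa
      asum[bdf$a2[i]] <- asum[bdf$a2[i]] + oa
      deg[bdf$a1[i]] <- deg[bdf$a1[i]] + 1L
      deg[bdf$a2[i]] <- deg[bdf$a2[i]] + 1L
    }
  }

  # implicit hydrogens + valence check. Organic-subset rules: aromatic carbon
  # gets one extra valence unit for the delocalized pi bond; aromatic N/P/O/S
  # written without brackets carry no implicit H (pyrrole-type NH must be
  # written [nH]). Bracket atoms keep their explicit H count.
  for (i in seq_len(n)) {
    el <- adf$element[i]
    if (el == "*") { adf$nH[i] <- 0L; next }
    if (adf$bracket[i]) {
      vmax <- if (el %in% names(.VALENCES))
        max(.VALENCES[[el]]) + abs(adf$charge[i]) else 8
      if (ceiling(bsum[i]) + adf$nH[i] > vmax + 1L) return(NULL)
      next
    }
    vals <- .VALENCES[[el]]
    if (is.null(vals)) return(NULL)
    if (adf$aromatic[i]) {
      conn <- asum[i] + if (el == "C") 1 else 0
      if (conn > max(vals)) return(NULL)
      adf$nH[i] <- if (el == "C") as.integer(max(0, 4 - conn)) else 0L
    } else {
      conn <- ceiling(bsum[i])
      fit <- vals[vals >= conn]
      if (length(fit) == 0L) return(NULL)
      adf$nH[i] <- as.integer(round(fit[1] - conn))
    }
  }

  # ring membership: a bond is in a ring iff its endpoints stay connected
  # after removing it
  inRingBond <- rep(FALSE, nrow(bdf))
  if (nrow(bdf) > 0L) {
    adj <- vector("list", n)
    for (i in seq_len(nrow(bdf))) {
      adj[[bdf$a1[i]]] <- c(adj[[bdf$a1[i]]], i)
      adj[[bdf$a2[i]]] <- c(adj[[bdf$a2[i]]], i)
    }
    connected_without <- function(b) {
      src <- bdf$a1[b]; dst <- bdf$a2[b]
      seen <- rep(FALSE, n); seen[src] <- TRUE; queue <- src
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (bi in adj[[v]]) {
          if (bi == b) next
          w <- if (bdf$a1[bi] == v) bdf$a2[bi] else bdf$a1[bi]
          if (!seen[w]) {
            if (w == dst) return(TRUE)
            seen[w] <- TRUE; queue <- c(queue, w)
          }
        }
      }
      FALSE
    }
    inRingBond <- vapply(seq_len(nrow(bdf)), connected_without, TRUE)
  }
  inRing <- rep(FALSE, n)
  if (any(inRingBond)) {
    inRing[unique(c(bdf$a1[inRingBond], bdf$a2[inRingBond]))] <- TRUE
  }
  adf$inRing <- inRing
  adf$degree <- deg
  bdf$inRing <- inRingBond
  list(atoms = adf[, c("element", "aromatic", "charge", "nH", "inRing",
                       "degree")],
       bonds = bdf, ncomp = ncomp)
}

#' Test SMILES validity
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector; TRUE where the string parses and passes the
#'   valence check.
#' @examples
#' isValidSmiles(c("CCO", "C((("))
#' @export
isValidSmiles <- function(smiles) {
  vapply(smiles, function(s) !is.na(s) && !is.null(parseSmiles(s)), TRUE,
         USE.NAMES = FALSE)
}

#' Molecular weight from a SMILES string
#'
#' Average-atomic-weight sum over the parsed graph, implicit and explicit
#' hydrogens included.
#'
#' @param smiles character vector of SMILES strings.
#' @return numeric vector of molecular weights (g/mol), NA where invalid.
#' @examples
#' molecularWeight("CCO")  # 46.07
#' @export
molecularWeight <- function(smiles) {
  vapply(smiles, function(s) {
    g <- if (is.na(s)) NULL else parseSmiles(s)
    if (is.null(g)) return(NA_real_)
    el <- g$atoms$element
    el[el == "*"] <- "C"
    sum(.ATOMIC_WT[el]) + sum(g$atoms$nH) * .ATOMIC_WT[["H"]]
  }, 0, USE.NAMES = FALSE)
}
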