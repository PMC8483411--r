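# Substructure matching.
#
# Two routes, used for different jobs:
#   * substructure_match() returns explicit atom-index mappings. It runs a
#     DFS backtracking matcher over the mol_graph against a documented SMARTS
#     subset (elements, aromaticity, wildcards, charge/H/degree/ring
#     primitives, "," / ";" / "&" / "!" logic, bond symbols - = # : ~ and the
#     single-or-aromatic default). Indices refer to the canonical atom order
#     of the molecule.
#   * smarts_count() delegates to Open Babel's full SMARTS engine (recursive
#     patterns and all) and returns unique-match counts; the alert catalogs
#     go through this route.

#' Count SMARTS matches via the Open Babel engine
#'
#' Supports full SMARTS (including recursive patterns). Matches that use the
#' same set of atoms in a different order are counted once when
#' `unique_matches = TRUE`.
#'
#' @param mol a `mol_graph` or SMILES string.
#' @param pattern a SMARTS string.
#' @param unique_matches collapse symmetric mappings.
#' @param explicit_h match against the explicit-hydrogen form of the molecule
#'   (required for patterns that reference `[#1]`).
#' @return integer match count.
#' @export
smarts_count <- function(mol, pattern, unique_matches = TRUE,
                         explicit_h = FALSE) {
  mol <- as_mol(mol)
  cnt <- ob_smarts_count(mol$smiles, pattern, unique_matches = unique_matches,
                         explicit_h = explicit_h)[1, 1]
  if (is.na(cnt))
    stop("Open Babel could not parse SMARTS: ", pattern, call. = FALSE)
  as.integer(cnt)
}

# ---- SMARTS-subset pattern compiler -------------------------------------

# A pattern atom compiles to a list of OR-alternatives, each a list of
# primitive tests (possibly negated). Primitives: element symbol, aromatic
# flag, atomic number (#n), wildcards * A a, charge, H<n>, D<n> (explicit
# degree), X<n> (connections incl. H), R / R0 (ring membership).
compile_smarts_atom <- function(raw, bracket) {
  if (!bracket) {
    if (raw %in% c("*", "A", "a")) {
      prim <- switch(raw,
        "*" = list(kind = "any"),
        "A" = list(kind = "arom", value = FALSE),
        "a" = list(kind = "arom", value = TRUE))
      return(list(list(list(neg = FALSE, prim = prim))))
    }
    stop("internal: organic-subset atoms are compiled directly")
  }
  ors <- strsplit(raw, ",", fixed = TRUE)[[1]]
  if (any(!nzchar(ors)))
    stop("empty alternative in SMARTS atom [", raw, "]", call. = FALSE)
  lapply(ors, function(alt) {
    terms <- strsplit(alt, "[;&]")[[1]]
    terms <- terms[nzchar(terms)]
    unlist(lapply(terms, compile_smarts_terms), recursive = FALSE)
  })
}

# One ';'/'&' term may still concatenate primitives ("nX3" etc.); scan it.
compile_smarts_terms <- function(term) {
  out <- list()
  i <- 1
  n <- nchar(term)
  while (i <= n) {
    neg <- FALSE
    if (substr(term, i, i) == "!") { neg <- TRUE; i <- i + 1 }
    rest <- substr(term, i, n)
    m <- regexpr(
      "^(#[0-9]+|\\*|A(?![a-z])|a|R[0-9]?|H[0-9]?|D[0-9]?|X[0-9]?|\\+[0-9]*|-[0-9]*|[A-Z][a-z]?|[a-z])",
      rest, perl = TRUE)
    if (m < 0)
      stop("unsupported SMARTS primitive near \"", rest, "\"", call. = FALSE)
    tok <- regmatches(rest, m)
    i <- i + attr(m, "match.length")
    prim <- smarts_primitive(tok)
    out[[length(out) + 1L]] <- list(neg = neg, prim = prim)
  }
  out
}

ELEMENT_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                     P = 15, S = 16, Cl = 17, Se = 34, Br = 35, I = 53)

smarts_primitive <- function(tok) {
  if (tok == "*") return(list(kind = "any"))
  if (tok == "a") return(list(kind = "arom", value = TRUE))
  if (tok == "A") return(list(kind = "arom", value = FALSE))
  if (grepl("^#", tok))
    return(list(kind = "elemnum", value = as.integer(substr(tok, 2, 99))))
  if (grepl("^R", tok)) {
    nr <- substr(tok, 2, 99)
    if (nr == "") return(list(kind = "ring", value = TRUE))
    if (nr == "0") return(list(kind = "ring", value = FALSE))
    return(list(kind = "ring", value = TRUE))  # R2 etc: in >=1 ring (approx)
  }
  if (grepl("^H", tok)) {
    nh <- substr(tok, 2, 99)
    return(list(kind = "hcount", value = if (nh == "") 1L else as.integer(nh)))
  }
  if (grepl("^D", tok)) {
    nd <- substr(tok, 2, 99)
    return(list(kind = "degree", value = if (nd == "") 1L else as.integer(nd)))
  }
  if (grepl("^X", tok)) {
    nx <- substr(tok, 2, 99)
    return(list(kind = "connections",
                value = if (nx == "") 1L else as.integer(nx)))
  }
  if (grepl("^\\+", tok)) {
    v <- substr(tok, 2, 99)
    return(list(kind = "charge",
                value = if (v == "") 1L else as.integer(v)))
  }
  if (grepl("^-", tok)) {
    v <- substr(tok, 2, 99)
    return(list(kind = "charge",
                value = if (v == "") -1L else -as.integer(v)))
  }
  # element symbol; lowercase = aromatic, uppercase = aliphatic
  arom <- tok == tolower(tok)
  el <- paste0(toupper(substr(tok, 1, 1)), substr(tok, 2, nchar(tok)))
  list(kind = "element", value = el, aromatic = arom)
}

# molecule atom feature table used by the matcher
mol_atom_features <- function(mol) {
  at <- mol$atoms
  deg <- integer(nrow(at))
  ring_atom <- logical(nrow(at))
  if (nrow(mol$bonds) > 0) {
    tab <- table(factor(c(mol$bonds$from, mol$bonds$to),
                        levels = seq_len(nrow(at))))
    deg <- as.integer(tab)
    cyc <- cyclic_bonds(nrow(at), mol$bonds)
    ring_atom[unique(c(mol$bonds$from[cyc], mol$bonds$to[cyc]))] <- TRUE
  }
  data.frame(element = at$element, aromatic = at$aromatic,
             charge = at$charge, hcount = at$hcount, degree = deg,
             connections = deg + at$hcount, ring = ring_atom,
             elemnum = unname(ELEMENT_NUMBERS[at$element]))
}

atom_matches <- function(feat_row, alts) {
  for (alt in alts) {
    ok <- TRUE
    for (t in alt) {
      p <- t$prim
      v <- switch(p$kind,
        any = TRUE,
        arom = feat_row$aromatic == p$value,
        elemnum = !is.na(feat_row$elemnum) && feat_row$elemnum == p$value,
        element = feat_row$element == p$value &&
          (is.na(p$aromatic) || feat_row$aromatic == p$aromatic),
        ring = feat_row$ring == p$value,
        hcount = feat_row$hcount == p$value,
        degree = feat_row$degree == p$value,
        connections = feat_row$connections == p$value,
        charge = feat_row$charge == p$value,
        FALSE)
      if (t$neg) v <- !v
      if (!isTRUE(v)) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

bond_matches <- function(bond, sym) {
  if (sym == "~") return(TRUE)
  if (sym == ":") return(bond$aromatic)
  if (sym == "=") return(!bond$aromatic && bond$order == 2)
  if (sym == "#") return(!bond$aromatic && bond$order == 3)
  if (sym %in% c("-", "/", "\\")) return(!bond$aromatic && bond$order == 1)
  # default: single or aromatic
  bond$aromatic || bond$order == 1
}

#' Find substructure matches with atom-index mappings
#'
#' Matches a SMARTS-subset pattern (see Details) against a molecule by DFS
#' backtracking and returns every mapping as a vector of molecule atom
#' indices (canonical ordering), one entry per pattern atom.
#'
#' Supported pattern language: organic-subset and bracket atoms with element
#' symbols (lowercase = aromatic), `*`, `A`, `a`, atomic number `#n`, charge,
#' `H`/`D`/`X`/`R` primitives, negation `!`, OR `,` and AND `;`/`&`; bond
#' symbols `-`, `=`, `#`, `:`, `~` plus the single-or-aromatic default; rings
#' and branches. Recursive SMARTS are not supported here - use
#' [smarts_count()] for full SMARTS.
#'
#' @param mol a `mol_graph` or SMILES string.
#' @param pattern a SMARTS-subset string.
#' @param unique_sets drop mappings that reuse the same set of atoms in a
#'   different order (default TRUE, so a nitro group counts once).
#' @return a list of integer vectors; empty list when there is no match.
#' @examples
#' substructure_match("O=[N+]([O-])c1ccccc1", "[N+](=O)[O-]")
#' @export
substructure_match <- function(mol, pattern, unique_sets = TRUE) {
  mol <- as_mol(mol)
  if (!is.character(pattern) || length(pattern) != 1 || !nzchar(pattern))
    stop("pattern must be a single SMARTS string", call. = FALSE)
  scan <- scan_smiles(pattern, mode = "smarts")
  pat_atoms <- lapply(scan$atoms, function(a) {
    if (!is.na(a$raw) && (a$bracket || a$raw %in% c("*", "A", "a"))) {
      if (grepl("$", a$raw, fixed = TRUE))
        stop("recursive SMARTS are not supported by substructure_match(); ",
             "use smarts_count()", call. = FALSE)
      compile_smarts_atom(a$raw, bracket = a$bracket)
    } else {
      # organic-subset pattern atom: element + aromaticity
      list(list(list(neg = FALSE,
                     prim = list(kind = "element", value = a$element,
                                 aromatic = a$aromatic))))
    }
  })
  np <- length(pat_atoms)
  pat_bonds <- scan$bonds
  feats <- mol_atom_features(mol)
  nm <- nrow(feats)
  if (np > nm) return(list())

  # adjacency of the molecule with bond rows for the edge test
  mol_adj <- vector("list", nm)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      f <- mol$bonds$from[k]; t <- mol$bonds$to[k]
      mol_adj[[f]] <- c(mol_adj[[f]], k)
      mol_adj[[t]] <- c(mol_adj[[t]], k)
    }
  }
  mol_bond_between <- function(i, j) {
    for (k in mol_adj[[i]]) {
      b <- mol$bonds[k, ]
      if ((b$from == i && b$to == j) || (b$from == j && b$to == i)) return(b)
    }
    NULL
  }
  # pattern edges grouped by the later-visited atom (DFS order = atom index,
  # since scan order connects each atom to an earlier one except ring bonds)
  pedges <- vector("list", np)
  if (length(pat_bonds) > 0) {
    for (e in pat_bonds) {
      hi <- max(e$from, e$to); lo <- min(e$from, e$to)
      pedges[[hi]] <- c(pedges[[hi]], list(list(other = lo, sym = e$sym)))
    }
  }
  results <- list()
  assign_vec <- integer(np)
  used <- logical(nm)
  recurse <- function(p) {
    if (p > np) {
      results[[length(results) + 1L]] <<- assign_vec
      return(invisible())
    }
    edges <- pedges[[p]]
    for (cand in seq_len(nm)) {
      if (used[cand]) next
      if (!atom_matches(feats[cand, ], pat_atoms[[p]])) next
      ok <- TRUE
      if (length(edges) > 0) {
        for (e in edges) {
          b <- mol_bond_between(cand, assign_vec[e$other])
          if (is.null(b) || !bond_matches(b, e$sym)) { ok <- FALSE; break }
        }
      } else if (p > 1) {
        # disconnected pattern component: any unused matching atom is fine
        ok <- TRUE
      }
      if (!ok) next
      assign_vec[p] <<- cand
      used[cand] <<- TRUE
      recurse(p + 1)
      used[cand] <<- FALSE
    }
  }
  recurse(1)
  if (unique_sets && length(results) > 1) {
    keys <- vapply(results, function(v) paste(sort(v), collapse = ","),
                   character(1))
    results <- results[!duplicated(keys)]
  }
  results
}
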