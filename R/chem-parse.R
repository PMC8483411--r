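# SMILES parsing and the mol_graph container.
#
# Open Babel is the chemistry authority: every input is canonicalized by it,
# and the atom/bond graph is rebuilt from its canonical SMILES so that atom
# indices always refer to the canonical atom ordering, whatever form the user
# typed. The scanner below exists because Open Babel accepts malformed SMILES
# silently (e.g. "C(" reads as methane); it enforces syntax with character
# positions and derives implicit hydrogen counts for the graph.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

# allowed valences used for implicit-H assignment and light valence checking
STANDARD_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

smiles_error <- function(text, pos, msg) {
  stop(sprintf("SMILES syntax error at position %d in \"%s\": %s",
               pos, text, msg), call. = FALSE)
}

# Single-pass scanner shared by the SMILES reader and the SMARTS-subset
# reader (mode = "smarts" keeps raw bracket contents for the matcher).
scan_smiles <- function(text, mode = c("smiles", "smarts")) {
  mode <- match.arg(mode)
  chars <- strsplit(text, "")[[1]]
  n <- nchar(text)
  atoms <- list()     # per atom: element, aromatic, charge, hcount, bracket, raw
  bonds <- list()     # from, to, sym
  prev <- NA_integer_
  pending_bond <- ""
  branch_stack <- integer()
  ring_open <- list() # label -> list(atom, sym, pos)
  i <- 1
  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_,
                       bracket = FALSE, raw = NA_character_, pos = i) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = charge,
      hcount = hcount, bracket = bracket, raw = raw)
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(from = prev, to = idx,
                                           sym = pending_bond)
    }
    prev <<- idx
    pending_bond <<- ""
    idx
  }
  close_ring <- function(label, pos) {
    if (!is.null(ring_open[[label]])) {
      op <- ring_open[[label]]
      sym <- pending_bond
      if (!nzchar(sym)) sym <- op$sym
      if (nzchar(op$sym) && nzchar(pending_bond) && op$sym != pending_bond)
        smiles_error(text, pos, sprintf(
          "conflicting bond symbols for ring closure %s", label))
      if (is.na(prev))
        smiles_error(text, pos, "ring closure after component separator")
      if (op$atom == prev)
        smiles_error(text, pos, sprintf("ring bond %s closes on its own atom",
                                        label))
      bonds[[length(bonds) + 1L]] <<- list(from = op$atom, to = prev,
                                           sym = sym)
      ring_open[[label]] <<- NULL
      pending_bond <<- ""
    } else {
      if (is.na(prev))
        smiles_error(text, pos, "ring-closure digit before any atom")
      ring_open[[label]] <<- list(atom = prev, sym = pending_bond, pos = pos)
      pending_bond <<- ""
    }
  }
  while (i <= n) {
    ch <- chars[i]
    rest <- substr(text, i, n)
    if (ch == "(") {
      if (is.na(prev)) smiles_error(text, i, "branch opens before any atom")
      branch_stack <- c(branch_stack, prev)
      i <- i + 1
    } else if (ch == ")") {
      if (length(branch_stack) == 0)
        smiles_error(text, i, "unmatched closing parenthesis")
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~")) {
      if (ch == "~" && mode != "smarts")
        smiles_error(text, i, "bond symbol '~' is SMARTS-only")
      pending_bond <- ch
      i <- i + 1
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- ""
      i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n || !grepl("^%[0-9]{2}", rest))
        smiles_error(text, i, "'%' must be followed by two digits")
      close_ring(substr(text, i + 1, i + 2), i)
      i <- i + 3
    } else if (grepl("^[0-9]", ch)) {
      close_ring(ch, i)
      i <- i + 1
    } else if (ch == "[") {
      close_pos <- regexpr("]", rest, fixed = TRUE)
      if (close_pos < 0) smiles_error(text, i, "unterminated bracket atom")
      content <- substr(rest, 2, close_pos - 1)
      if (!nzchar(content)) smiles_error(text, i, "empty bracket atom")
      if (mode == "smarts") {
        add_atom(NA_character_, NA, bracket = TRUE, raw = content, pos = i)
      } else {
        m <- regexec(
          "^([0-9]*)([A-Z][a-z]?|[a-z][a-z]?|\\*)(@{1,2}|@TH[12])?(H[0-9]*)?(\\+\\+|--|\\+[0-9]*|-[0-9]*)?(:[0-9]+)?$",
          content)[[1]]
        if (m[1] < 0)
          smiles_error(text, i, sprintf("cannot read bracket atom \"[%s]\"",
                                        content))
        parts <- regmatches(content, list(m))[[1]]
        sym <- parts[3]
        aromatic <- sym %in% AROMATIC_ORGANIC || sym == tolower(sym) && sym != "*"
        element <- if (sym == "*") "*" else
          paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
        hspec <- parts[5]
        hcount <- if (!nzchar(hspec)) 0L
          else if (hspec == "H") 1L else as.integer(substr(hspec, 2, nchar(hspec)))
        cspec <- parts[6]
        charge <- if (!nzchar(cspec)) 0L
          else if (cspec == "++") 2L else if (cspec == "--") -2L
          else if (cspec == "+") 1L else if (cspec == "-") -1L
          else as.integer(paste0(substr(cspec, 1, 1),
                                 substr(cspec, 2, nchar(cspec))))
        add_atom(element, aromatic, charge = charge, hcount = hcount,
                 bracket = TRUE, raw = content, pos = i)
      }
      i <- i + close_pos
    } else if (grepl("^(Cl|Br)", rest)) {
      add_atom(substr(rest, 1, 2), FALSE, pos = i)
      i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, pos = i)
      i <- i + 1
    } else if (ch %in% AROMATIC_ORGANIC) {
      add_atom(toupper(ch), TRUE, pos = i)
      i <- i + 1
    } else if (mode == "smarts" && ch %in% c("*", "A", "a")) {
      add_atom(ch, NA, bracket = FALSE, raw = ch, pos = i)
      i <- i + 1
    } else if (ch == "*") {
      add_atom("*", FALSE, pos = i)
      i <- i + 1
    } else {
      smiles_error(text, i, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(branch_stack) > 0)
    smiles_error(text, n, "unclosed branch (missing ')')")
  if (length(ring_open) > 0) {
    op <- ring_open[[1]]
    smiles_error(text, op$pos, sprintf(
      "unclosed ring bond '%s'", names(ring_open)[1]))
  }
  if (length(atoms) == 0)
    smiles_error(text, 1, "no atoms found")
  list(atoms = atoms, bonds = bonds)
}

# Which bonds lie in a cycle (needed to decide whether a default bond between
# two aromatic atoms is aromatic, e.g. biphenyl's inter-ring single bond).
cyclic_bonds <- function(n_atoms, bond_df) {
  if (nrow(bond_df) == 0) return(logical(0))
  g <- igraph::graph_from_edgelist(
    as.matrix(bond_df[, c("from", "to")]), directed = FALSE)
  if (igraph::vcount(g) < n_atoms)
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  br <- igraph::bridges(g)
  in_cycle <- rep(TRUE, nrow(bond_df))
  in_cycle[as.integer(br)] <- FALSE
  in_cycle
}

resolve_graph <- function(scan, text) {
  at <- scan$atoms
  atoms <- data.frame(
    element  = vapply(at, `[[`, character(1), "element"),
    aromatic = vapply(at, `[[`, logical(1), "aromatic"),
    charge   = vapply(at, `[[`, integer(1), "charge"),
    hcount   = vapply(at, `[[`, integer(1), "hcount"),
    bracket  = vapply(at, `[[`, logical(1), "bracket"),
    stringsAsFactors = FALSE)
  if (length(scan$bonds) > 0) {
    bonds <- data.frame(
      from = vapply(scan$bonds, `[[`, integer(1), "from"),
      to   = vapply(scan$bonds, `[[`, integer(1), "to"),
      sym  = vapply(scan$bonds, `[[`, character(1), "sym"),
      stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(from = integer(), to = integer(), sym = character(),
                        stringsAsFactors = FALSE)
  }
  in_cycle <- cyclic_bonds(nrow(atoms), bonds)
  both_aromatic <- atoms$aromatic[bonds$from] & atoms$aromatic[bonds$to]
  bonds$aromatic <- (bonds$sym == ":") |
    (bonds$sym %in% c("", "/", "\\") & both_aromatic & in_cycle)
  bonds$order <- ifelse(bonds$sym == "=", 2L,
                 ifelse(bonds$sym == "#", 3L, 1L))
  bonds$order[bonds$aromatic] <- 1L

  # implicit hydrogens + valence check (organic-subset atoms only; bracket
  # atoms carry their H count explicitly)
  bond_val <- numeric(nrow(atoms))
  if (nrow(bonds) > 0) {
    contrib <- ifelse(bonds$aromatic, 1, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bond_val[bonds$from[k]] <- bond_val[bonds$from[k]] + contrib[k]
      bond_val[bonds$to[k]]   <- bond_val[bonds$to[k]] + contrib[k]
    }
  }
  # aromatic atoms carry one extra valence unit for the pi system, unless an
  # explicit exocyclic double/triple bond already accounts for it (e.g. the
  # carbonyl carbon of an aromatic pyranone, written c(=O))
  has_multi <- logical(nrow(atoms))
  if (nrow(bonds) > 0) {
    for (k in which(!bonds$aromatic & bonds$order >= 2)) {
      has_multi[bonds$from[k]] <- TRUE
      has_multi[bonds$to[k]] <- TRUE
    }
  }
  # divalent aromatic heteroatoms (furan O, thiophene S) donate a lone pair,
  # not a kekule double bond, so they get no extra unit; neither does a
  # three-connected aromatic nitrogen (pyrrole-type, as in N-methylated
  # azoles) whose lone pair is the aromatic contribution
  degree <- integer(nrow(atoms))
  if (nrow(bonds) > 0) {
    dtab <- table(factor(c(bonds$from, bonds$to),
                         levels = seq_len(nrow(atoms))))
    degree <- as.integer(dtab)
  }
  bump_el <- atoms$element %in% c("C", "B") |
    (atoms$element %in% c("N", "P") & degree == 2)
  bond_val <- bond_val + ifelse(atoms$aromatic & bump_el & !has_multi, 1, 0)
  for (j in seq_len(nrow(atoms))) {
    if (atoms$bracket[j]) next
    el <- atoms$element[j]
    if (el == "*") { atoms$hcount[j] <- 0L; next }
    vals <- STANDARD_VALENCES[[el]]
    if (is.null(vals)) { atoms$hcount[j] <- 0L; next }
    fit <- vals[vals >= bond_val[j]]
    if (length(fit) == 0)
      stop(sprintf(
        "valence error in \"%s\": atom %d (%s) has bond order sum %g exceeding %s",
        text, j, el, bond_val[j], paste(vals, collapse = "/")), call. = FALSE)
    atoms$hcount[j] <- as.integer(fit[1] - bond_val[j])
  }
  atoms$hcount[is.na(atoms$hcount)] <- 0L
  list(atoms = atoms,
       bonds = bonds[, c("from", "to", "order", "aromatic", "sym")])
}

#' Parse a SMILES string into a molecule graph
#'
#' The input is syntax-checked (unbalanced branches, ring bonds and bracket
#' atoms are reported with their character position), canonicalized with Open
#' Babel, and returned as an atom/bond graph in Open Babel's canonical atom
#' order. Chemically identical inputs therefore yield identical graphs no
#' matter how the SMILES was written.
#'
#' @param text a single SMILES string.
#' @return an object of class `mol_graph` with components `atoms` (data frame:
#'   `element`, `aromatic`, `charge`, `hcount` = implicit hydrogens),
#'   `bonds` (data frame: `from`, `to`, `order`, `aromatic`), `smiles`
#'   (canonical SMILES) and `source_text` (the input).
#' @examples
#' mol <- parse_smiles("c1ccccc1")
#' nrow(mol$atoms)  # 6 aromatic carbons
#' @export
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text))
    stop("parse_smiles() expects a single non-empty SMILES string",
         call. = FALSE)
  scan_smiles(text)                     # syntax + valence screen of the input
  resolve_graph(scan_smiles(text), text)  # valence check runs on input form
  canon <- ob_canonical(text)
  if (is.na(canon) || !nzchar(canon))
    stop(sprintf("Open Babel could not interpret SMILES \"%s\"", text),
         call. = FALSE)
  g <- resolve_graph(scan_smiles(canon), canon)
  structure(list(atoms = g$atoms, bonds = g$bonds,
                 smiles = canon, source_text = text),
            class = "mol_graph")
}

is_mol_graph <- function(x) inherits(x, "mol_graph")

as_mol <- function(x) {
  if (is_mol_graph(x)) return(x)
  if (is.character(x) && length(x) == 1) return(parse_smiles(x))
  stop("expected a mol_graph or a single SMILES string", call. = FALSE)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s\n  %d heavy atoms, %d bonds (%d aromatic atoms)\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds), sum(x$atoms$aromatic)))
  invisible(x)
}

#' Write a molecule graph back to SMILES
#'
#' Returns the canonical SMILES of the graph; re-parsing it reproduces an
#' identical graph.
#' @param mol a `mol_graph`.
#' @return a canonical SMILES string.
#' @export
as_smiles <- function(mol) {
  stopifnot(is_mol_graph(mol))
  mol$smiles
}

#' Canonical structure identity key
#'
#' A collision-safe identity string for deduplication: Open Babel's canonical
#' SMILES. Equal for chemically identical structures regardless of atom
#' ordering, kekulization or input SMILES form; stereochemistry is preserved
#' (`@`/`@@` and `/`\\ marks survive canonicalization). An independent
#' canonicalization oracle cross-checks the induced identity relation in the
#' test suite.
#'
#' @param mol a `mol_graph` or SMILES string.
#' @return a single identity string.
#' @examples
#' canonical_key("CCO") == canonical_key("OCC")            # TRUE
#' canonical_key("c1ccccc1") == canonical_key("C1=CC=CC=C1")  # TRUE
#' @export
canonical_key <- function(mol) {
  mol <- as_mol(mol)
  if (!nzchar(mol$smiles))
    stop("could not derive identity key for ", mol$source_text, call. = FALSE)
  mol$smiles
}
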