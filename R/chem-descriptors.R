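# Physicochemical descriptors feeding the rubric bonuses and the ADME rule
# sets.
#
# Sources, pinned so rule thresholds are auditable:
#   mw, clogp, tpsa, molar_refractivity - Open Babel models (logP and MR are
#     the Wildman-Crippen atom-contribution scheme; TPSA the Ertl
#     fragment-contribution method). The Ghose/Egan bands were calibrated
#     against atom-contribution logP flavours, so one pinned implementation
#     feeds every rule set.
#   hbd / hba - Lipinski's original counting convention: HBD = number of N/O
#     atoms carrying at least one hydrogen, HBA = number of N or O atoms.
#     Stricter pharmacophore definitions differ; this is deliberate.
#   rotatable_bonds - single acyclic bonds between two non-terminal heavy
#     atoms, excluding bonds adjacent to a triple bond (the common strict
#     rotor SMARTS).
#   heavy_atoms, ring_count (SSSR size = bonds - atoms + components),
#   heteroatoms, carbons - from the parsed graph.

ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Physicochemical descriptor set
#'
#' @param mol a `mol_graph` or SMILES string.
#' @return an object of class `descriptor_set` (also a one-row data frame)
#'   with columns `mw` (Da), `clogp`, `hbd`, `hba`, `tpsa` (A^2),
#'   `rotatable_bonds`, `heavy_atoms`, `molar_refractivity`, `ring_count`,
#'   `heteroatoms` and `carbons`.
#' @examples
#' descriptors("OCC")   # ethanol: hbd 1, hba 1
#' @export
descriptors <- function(mol) {
  mol <- as_mol(mol)
  p <- ob_props(mol$smiles)
  at <- mol$atoms
  # hydrogens attached to each heavy atom = implicit count from the canonical
  # form (explicit H atoms are folded into hcount by Open Babel's canonical
  # SMILES for ordinary organic structures)
  is_no <- at$element %in% c("N", "O")
  hbd <- sum(is_no & at$hcount > 0)
  hba <- sum(is_no)
  n_comp <- n_components(mol)
  rot <- ob_smarts_count(mol$smiles, ROTOR_SMARTS, unique_matches = FALSE)
  res <- data.frame(
    mw = p$MW,
    clogp = p$logP,
    hbd = hbd,
    hba = hba,
    tpsa = p$TPSA,
    rotatable_bonds = as.integer(rot[1, 1] / 2),
    heavy_atoms = nrow(at),
    molar_refractivity = p$MR,
    ring_count = nrow(mol$bonds) - nrow(at) + n_comp,
    heteroatoms = sum(!at$element %in% c("C", "*")),
    carbons = sum(at$element == "C")
  )
  class(res) <- c("descriptor_set", "data.frame")
  res
}

n_components <- function(mol) {
  if (nrow(mol$bonds) == 0) return(nrow(mol$atoms))
  g <- igraph::graph_from_edgelist(
    as.matrix(mol$bonds[, c("from", "to")]), directed = FALSE)
  if (igraph::vcount(g) < nrow(mol$atoms))
    g <- igraph::add_vertices(g, nrow(mol$atoms) - igraph::vcount(g))
  igraph::components(g)$no
}

#' Descriptor table for a set of molecules
#'
#' @param mols list of `mol_graph` objects or character vector of SMILES.
#' @return a data frame with one row per molecule (rownames from names).
#' @export
descriptor_table <- function(mols) {
  nm <- mol_set_names(mols)
  mols <- as_mol_list(mols)
  out <- do.call(rbind, lapply(mols, descriptors))
  out <- as.data.frame(out)
  out$smiles <- vapply(mols, `[[`, character(1), "smiles")
  if (!is.null(nm)) rownames(out) <- nm
  out
}
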