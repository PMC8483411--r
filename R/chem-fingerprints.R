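# Molecular fingerprints and Tanimoto similarity.
#
# Three dialects are exposed, matching the analyses they serve:
#   path1024   - Open Babel FP2: all linear paths of length 1-7 hashed to
#                1024 bits; the similarity-network / heatmap default.
#   ecfp4_2048 - extended-connectivity, radius 2 (diameter 4).
#   ecfp6_2048 - extended-connectivity, radius 3 (diameter 6); the novelty
#                criterion's dialect.
# Open Babel emits ECFP bitsets at 4096 bits; they are folded to 2048 by
# OR-ing the two halves so the dialect widths are powers of two as stated.
# The bit assignment is Open Babel's fixed hash, so bitsets are reproducible
# across runs and platforms.

FP_DIALECTS <- list(
  path1024   = list(ob_type = "FP2",   nbits = 1024L, radius_or_depth = 7L),
  ecfp4_2048 = list(ob_type = "ECFP4", nbits = 2048L, radius_or_depth = 2L),
  ecfp6_2048 = list(ob_type = "ECFP6", nbits = 2048L, radius_or_depth = 3L)
)

fold_bits <- function(mat, nbits) {
  while (ncol(mat) > nbits) {
    half <- ncol(mat) / 2
    mat <- (mat[, 1:half, drop = FALSE] |
              mat[, (half + 1):(2 * half), drop = FALSE]) * 1L
  }
  mat
}

#' Compute a molecular fingerprint
#'
#' @param mol a `mol_graph` or SMILES string.
#' @param dialect one of `"path1024"`, `"ecfp4_2048"`, `"ecfp6_2048"`.
#' @param nbits optional width override; must be a power of two no larger
#'   than the dialect's native width (wider requests cannot be un-hashed).
#' @return an object of class `chem_fp`: logical bit vector `bits` plus
#'   `nbits`, `dialect` and `radius_or_depth`.
#' @examples
#' fp <- fingerprint("CCO", "path1024")
#' sum(fp$bits)
#' @export
fingerprint <- function(mol, dialect = c("path1024", "ecfp4_2048",
                                         "ecfp6_2048"),
                        nbits = NULL) {
  dialect <- match.arg(dialect)
  fingerprint_set(list(mol), dialect, nbits)[[1]]
}

# Batch form used by similarity_matrix / novelty checks; returns a list of
# chem_fp sharing one backend call per molecule.
fingerprint_set <- function(mols, dialect = c("path1024", "ecfp4_2048",
                                              "ecfp6_2048"),
                            nbits = NULL) {
  dialect <- match.arg(dialect)
  spec <- FP_DIALECTS[[dialect]]
  if (is.null(nbits)) nbits <- spec$nbits
  if (nbits < 1 || bitwAnd(nbits, nbits - 1L) != 0)
    stop("nbits must be a power of two", call. = FALSE)
  mols <- lapply(mols, as_mol)
  smiles <- vapply(mols, `[[`, character(1), "smiles")
  mat <- ob_fp_matrix(smiles, spec$ob_type)
  if (nbits > ncol(mat))
    stop(sprintf("dialect %s supports at most %d bits", dialect, ncol(mat)),
         call. = FALSE)
  mat <- fold_bits(mat, nbits)
  lapply(seq_len(nrow(mat)), function(i) {
    structure(list(bits = as.logical(mat[i, ]), nbits = nbits,
                   dialect = dialect,
                   radius_or_depth = spec$radius_or_depth),
              class = "chem_fp")
  })
}

#' @export
print.chem_fp <- function(x, ...) {
  cat(sprintf("<chem_fp %s> %d/%d bits set\n", x$dialect, sum(x$bits),
              x$nbits))
  invisible(x)
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|a AND b| / |a OR b|`. Two all-zero fingerprints compare as identical
#' objects and return `zero_zero` (default 1); set `zero_zero = 0` for the
#' stricter convention.
#'
#' @param a,b `chem_fp` objects of the same dialect and width.
#' @param zero_zero value returned when both bitsets are empty.
#' @return a fraction in \[0, 1\].
#' @export
tanimoto <- function(a, b, zero_zero = 1) {
  stopifnot(inherits(a, "chem_fp"), inherits(b, "chem_fp"))
  if (a$dialect != b$dialect || a$nbits != b$nbits)
    stop(sprintf("fingerprint mismatch: %s/%d vs %s/%d",
                 a$dialect, a$nbits, b$dialect, b$nbits), call. = FALSE)
  un <- sum(a$bits | b$bits)
  if (un == 0) return(zero_zero)
  sum(a$bits & b$bits) / un
}

#' Pairwise Tanimoto similarity matrix
#'
#' Entry (i, j) is the Tanimoto coefficient between molecule i of `set_a`
#' and molecule j of `set_b`. With `set_b = NULL` the matrix is square,
#' symmetric and has a unit diagonal.
#'
#' @param set_a,set_b lists of `mol_graph` objects or character vectors of
#'   SMILES (named vectors label the rows/columns).
#' @param dialect fingerprint dialect (see [fingerprint()]).
#' @param zero_zero see [tanimoto()].
#' @return a numeric matrix of Tanimoto coefficients.
#' @export
similarity_matrix <- function(set_a, set_b = NULL,
                              dialect = c("path1024", "ecfp4_2048",
                                          "ecfp6_2048"),
                              zero_zero = 1) {
  dialect <- match.arg(dialect)
  names_a <- mol_set_names(set_a)
  set_a <- as_mol_list(set_a)
  self <- is.null(set_b)
  if (self) {
    set_b <- set_a
    names_b <- names_a
  } else {
    names_b <- mol_set_names(set_b)
    set_b <- as_mol_list(set_b)
  }
  fa <- fp_bit_matrix(fingerprint_set(set_a, dialect))
  fb <- if (self) fa else fp_bit_matrix(fingerprint_set(set_b, dialect))
  inter <- tcrossprod(fa, fb)
  pa <- rowSums(fa)
  pb <- rowSums(fb)
  un <- outer(pa, pb, "+") - inter
  tc <- ifelse(un == 0, zero_zero, inter / pmax(un, 1))
  dimnames(tc) <- list(names_a, names_b)
  tc
}

fp_bit_matrix <- function(fps) {
  do.call(rbind, lapply(fps, function(f) as.integer(f$bits)))
}

as_mol_list <- function(x) {
  if (is_mol_graph(x)) return(list(x))
  if (is.character(x)) return(lapply(x, parse_smiles))
  if (is.list(x)) return(lapply(x, as_mol))
  stop("expected SMILES strings or mol_graph objects", call. = FALSE)
}

mol_set_names <- function(x) {
  if (is_mol_graph(x)) return(NULL)
  names(x)
}
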