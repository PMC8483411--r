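# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately naive (enumeration / closed form) and never call
# the code paths they check.

# twenty structurally varied, parser-friendly molecules
fixture_smiles <- c(
  ethanol = "CCO", benzene = "c1ccccc1", toluene = "Cc1ccccc1",
  phenol = "Oc1ccccc1", pyridine = "c1ccncc1", aniline = "Nc1ccccc1",
  nitrobenzene = "O=[N+]([O-])c1ccccc1", furan = "c1ccoc1",
  thiophene = "c1ccsc1", acetic = "CC(=O)O",
  aspirin = "CC(=O)Oc1ccccc1C(=O)O", caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  naphthalene = "c1ccc2ccccc2c1", cyclohexane = "C1CCCCC1",
  tma = "C[N+](C)(C)C", dmso = "CS(=O)C", urea = "NC(N)=O",
  alanine = "C[C@@H](C(=O)O)N", indole = "c1ccc2[nH]ccc2c1",
  tfa = "OC(=O)C(F)(F)F")

# pairs of SMILES writing the same structure differently
fixture_rewrites <- list(
  c("CCO", "OCC"),
  c("c1ccccc1", "C1=CC=CC=C1"),
  c("Cc1ccccc1", "c1ccccc1C"),
  c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"),
  c("c1ccncc1", "n1ccccc1"),
  c("O=[N+]([O-])c1ccccc1", "[O-][N+](=O)c1ccccc1"),
  c("NC(N)=O", "O=C(N)N"))

# standard atomic masses for the brute-force MW oracle
ORACLE_MASSES <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                   F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                   Cl = 35.45, Br = 79.904, I = 126.904)

oracle_mw <- function(mol) {
  at <- mol$atoms
  sum(ORACLE_MASSES[at$element]) + sum(at$hcount) * ORACLE_MASSES[["H"]]
}

oracle_tanimoto <- function(a, b) {
  on_a <- which(a$bits); on_b <- which(b$bits)
  un <- length(union(on_a, on_b))
  if (un == 0) return(1)
  length(intersect(on_a, on_b)) / un
}

# union-find connected components (oracle for network component labels)
oracle_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# exhaustive subgraph-match oracle: tries every injective assignment of
# pattern atoms to molecule atoms (only feasible for small molecules)
oracle_subgraph_count <- function(mol, pat_elements, pat_aromatic,
                                  pat_edges) {
  feats <- mol$atoms
  nm <- nrow(feats)
  np <- length(pat_elements)
  bond_ok <- function(i, j) {
    b <- mol$bonds
    any((b$from == i & b$to == j) | (b$from == j & b$to == i))
  }
  hits <- 0
  perms <- utils::combn(nm, np, simplify = FALSE)
  for (subset in perms) {
    for (ord in all_perms(subset)) {
      ok <- TRUE
      for (p in seq_len(np)) {
        if (feats$element[ord[p]] != pat_elements[p] ||
            feats$aromatic[ord[p]] != pat_aromatic[p]) { ok <- FALSE; break }
      }
      if (!ok) next
      for (e in pat_edges) {
        if (!bond_ok(ord[e[1]], ord[e[2]])) { ok <- FALSE; break }
      }
      if (ok) { hits <- hits + 1; break }  # count atom sets once
    }
  }
  hits
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# exhaustive best score over all bind/avoid outcome combinations: the
# maximum target-based points a rubric can award
oracle_max_target_points <- function(rubric) {
  best_bind <- sum(vapply(rubric$bind_criteria,
                          function(cr) max(c(0, cr$points)), numeric(1)))
  best_avoid <- sum(vapply(rubric$avoid_criteria,
                           function(cr) max(c(0, cr$points)), numeric(1)))
  best_bind + best_avoid
}

# make a chem_fp by hand (for boundary-exact Tanimoto tests)
manual_fp <- function(on_bits, nbits = 2048, dialect = "ecfp6_2048") {
  bits <- rep(FALSE, nbits)
  bits[on_bits] <- TRUE
  structure(list(bits = bits, nbits = nbits, dialect = dialect,
                 radius_or_depth = 3L), class = "chem_fp")
}

# small all-censored panel covering a rubric
censored_panel <- function(ids, rubric, bound = 30000) {
  tg <- polypharm:::rubric_targets(rubric)
  kd <- matrix(bound, length(ids), length(tg),
               dimnames = list(ids, tg))
  cen <- matrix(TRUE, length(ids), length(tg),
                dimnames = list(ids, tg))
  kd_panel(kd, cen, censor_bound_nM = bound)
}

# set chosen targets of one compound to given Kd values (uncensored)
set_kd <- function(panel, compound, values) {
  kd <- panel$kd_nM; cen <- panel$censored
  for (tg in names(values)) {
    kd[compound, tg] <- values[[tg]]
    cen[compound, tg] <- FALSE
  }
  kd_panel(kd, cen, censor_bound_nM = panel$censor_bound_nM)
}
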