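# Structure parsing, canonical identity, fingerprints, descriptors and
# substructure matching.

test_that("parse_smiles builds correct graphs and rejects malformed input", {
  m <- parse_smiles("CCO")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(nrow(m$bonds), 2)

  benzene <- parse_smiles("c1ccccc1")
  expect_equal(nrow(benzene$atoms), 6)
  expect_true(all(benzene$atoms$aromatic))
  expect_equal(sum(benzene$bonds$aromatic), 6)

  expect_error(parse_smiles("C("), "position 2.*unclosed branch")
  expect_error(parse_smiles("C1CC"), "unclosed ring bond")
  expect_error(parse_smiles("C)C"), "unmatched closing")
  expect_error(parse_smiles("[Qq"), "unterminated bracket")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence error")
})

test_that("aromatic bonds connect aromatic atoms and round-trips are stable", {
  for (smi in fixture_smiles) {
    m <- parse_smiles(smi)
    if (any(m$bonds$aromatic)) {
      ar <- m$bonds[m$bonds$aromatic, ]
      expect_true(all(m$atoms$aromatic[ar$from]),
                  label = paste("aromatic from-atoms of", smi))
      expect_true(all(m$atoms$aromatic[ar$to]),
                  label = paste("aromatic to-atoms of", smi))
    }
    expect_true(all(m$bonds$from >= 1 & m$bonds$from <= nrow(m$atoms)))
    m2 <- parse_smiles(as_smiles(m))
    expect_identical(m$atoms, m2$atoms, label = paste("round-trip of", smi))
    expect_identical(m$bonds, m2$bonds)
  }
})

test_that("canonical_key is invariant to SMILES form and separates molecules", {
  for (pair in fixture_rewrites)
    expect_identical(canonical_key(pair[1]), canonical_key(pair[2]),
                     label = paste(pair[1], "vs", pair[2]))
  expect_false(canonical_key("CCO") == canonical_key("CCN"))
  keys <- vapply(fixture_smiles, canonical_key, character(1))
  expect_equal(anyDuplicated(keys), 0)
})

test_that("canonical identity agrees with an independent rdkit oracle", {
  # rdkit (python) canonicalizes independently of Open Babel; the two must
  # induce the same identity relation over the rewrite pairs
  smis <- unlist(fixture_rewrites)
  out <- system2("python", c("-c", shQuote(paste0(
    "from rdkit import Chem\n",
    "import sys\n",
    "for s in sys.argv[1:]:\n",
    "    print(Chem.MolToSmiles(Chem.MolFromSmiles(s)))")), shQuote(smis)),
    stdout = TRUE, stderr = FALSE)
  expect_length(out, length(smis))
  for (k in seq_along(fixture_rewrites)) {
    i <- 2 * k - 1
    expect_identical(out[i], out[i + 1])  # oracle agrees the pair is equal
    expect_identical(canonical_key(smis[i]), canonical_key(smis[i + 1]))
  }
})

test_that("fingerprints are deterministic and invariant to atom order", {
  for (pair in fixture_rewrites) {
    for (dia in c("path1024", "ecfp4_2048", "ecfp6_2048")) {
      f1 <- fingerprint(pair[1], dia)
      f2 <- fingerprint(pair[2], dia)
      expect_identical(f1$bits, f2$bits,
                       label = sprintf("%s vs %s (%s)", pair[1], pair[2], dia))
    }
  }
  f <- fingerprint("CCO", "path1024")
  expect_identical(f$bits, fingerprint("CCO", "path1024")$bits)
  expect_equal(f$nbits, 1024)
  # methane has at most 3 distinct atom environments within radius 2
  # (radii 0, 1, 2 around the single carbon)
  expect_lte(sum(fingerprint("C", "ecfp4_2048")$bits), 3)
  expect_error(fingerprint("CCO", "path1024", nbits = 1000), "power of two")
})

test_that("tanimoto matches its formula, symmetry and range", {
  a <- manual_fp(c(1, 2)); b <- manual_fp(c(1, 3))
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(manual_fp(1:4), manual_fp(5:8)), 0)
  expect_equal(tanimoto(manual_fp(integer(0)), manual_fp(integer(0))), 1)
  expect_equal(tanimoto(manual_fp(integer(0)), manual_fp(integer(0)),
                        zero_zero = 0), 0)
  expect_error(tanimoto(a, fingerprint("CCO", "path1024")), "mismatch")

  fps <- lapply(fixture_smiles[1:8], fingerprint, dialect = "path1024")
  for (i in 1:7) for (j in (i + 1):8) {
    tij <- tanimoto(fps[[i]], fps[[j]])
    expect_identical(tij, tanimoto(fps[[j]], fps[[i]]))
    expect_gte(tij, 0); expect_lte(tij, 1)
    expect_equal(tij, oracle_tanimoto(fps[[i]], fps[[j]]))
  }
})

test_that("similarity_matrix equals a brute-force tanimoto loop", {
  smis <- fixture_smiles[1:6]
  tc <- similarity_matrix(smis)
  expect_equal(dim(tc), c(6, 6))
  expect_equal(unname(diag(tc)), rep(1, 6))
  expect_equal(tc, t(tc))
  fps <- lapply(smis, fingerprint, dialect = "path1024")
  for (i in 1:6) for (j in 1:6)
    expect_equal(unname(tc[i, j]), tanimoto(fps[[i]], fps[[j]]))
  # rectangular case
  tc2 <- similarity_matrix(smis[1:2], smis[3:6])
  expect_equal(dim(tc2), c(2, 4))
  expect_equal(unname(tc2[2, 1]), tanimoto(fps[[2]], fps[[3]]))
})

test_that("descriptors match direct counts and the MW summation oracle", {
  bz <- descriptors("c1ccccc1")
  expect_equal(bz$tpsa, 0)
  expect_equal(bz$hbd, 0)
  expect_equal(bz$hba, 0)
  expect_equal(bz$ring_count, 1)

  et <- descriptors("OCC")
  expect_equal(et$hbd, 1)
  expect_equal(et$hba, 1)
  expect_equal(et$mw, 46.07, tolerance = 0.001)

  for (smi in fixture_smiles) {
    m <- parse_smiles(smi)
    d <- descriptors(m)
    expect_equal(d$mw, oracle_mw(m), tolerance = 0.01,
                 label = paste("MW of", smi))
    expect_gte(d$tpsa, 0)
    expect_gte(d$hbd, 0)
    expect_equal(d$heavy_atoms, nrow(m$atoms))
  }
  expect_equal(descriptors("c1ccc2ccccc2c1")$ring_count, 2)  # SSSR
  expect_equal(descriptors("CCCC")$rotatable_bonds, 1)
  expect_equal(descriptors("C")$heavy_atoms, 1)  # single atom: no crash
})

test_that("substructure_match agrees with examples and the exhaustive oracle", {
  expect_gte(length(substructure_match("c1ccccc1", "c1ccccc1")), 1)
  expect_length(substructure_match("C", "[OH]"), 0)
  nitro <- substructure_match("O=[N+]([O-])c1ccccc1",
                              "[N+](=O)[O-]")
  expect_length(nitro, 1)
  expect_length(nitro[[1]], 3)
  expect_error(substructure_match("CCO", "[$(CC)]O"), "recursive")

  # element/aromaticity patterns vs exhaustive enumeration on small molecules
  cases <- list(
    list(mol = "CCO", el = c("C", "O"), ar = c(FALSE, FALSE),
         edges = list(c(1, 2)), pat = "CO"),
    list(mol = "Oc1ccccc1", el = c("O", "C"), ar = c(FALSE, TRUE),
         edges = list(c(1, 2)), pat = "Oc"),
    list(mol = "c1ccncc1", el = c("N", "C", "C"), ar = c(TRUE, TRUE, TRUE),
         edges = list(c(1, 2), c(2, 3)), pat = "ncc"),
    list(mol = "CC(C)C", el = c("C", "C"), ar = c(FALSE, FALSE),
         edges = list(c(1, 2)), pat = "CC"))
  for (cs in cases) {
    m <- parse_smiles(cs$mol)
    got <- length(substructure_match(m, cs$pat))
    want <- oracle_subgraph_count(m, cs$el, cs$ar, cs$edges)
    expect_equal(got, want, label = sprintf("%s in %s", cs$pat, cs$mol))
    # independent full-SMARTS engine agrees on the unique-match count
    expect_equal(got, smarts_count(m, cs$pat),
                 label = sprintf("OB count of %s in %s", cs$pat, cs$mol))
  }
})
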