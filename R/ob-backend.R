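# Thin wrappers around ChemmineOB / Open Babel.
#
# All chemical perception (canonical ordering, aromaticity, InChI, logP/TPSA/MR
# models, FP2 and ECFP fingerprints, full SMARTS matching) is delegated to
# Open Babel; this file centralises the calls and their quirks so the rest of
# the package never touches ChemmineOB directly.

# Open Babel prints perception warnings on stderr; they are harmless but noisy
# inside loops, so conversions run with message capture.
ob_quiet <- function(expr) {
  out <- NULL
  utils::capture.output(out <- suppressMessages(suppressWarnings(expr)),
                        type = "message")
  out
}

ob_convert <- function(from, to, source, add_h = FALSE) {
  nms <- character()
  # gen2D for SDF output: Open Babel otherwise warns (loudly, on stderr)
  # about missing coordinates on every record
  if (toupper(to) == "SDF") nms <- c(nms, "gen2D")
  if (add_h) nms <- c(nms, "h")
  opts <- data.frame(names = nms, args = rep("", length(nms)))
  ob_quiet(ChemmineOB::convertFormat(from, to, source, options = opts))
}

# Canonical SMILES, one per input string. Open Babel emits "smiles\tname\n"
# records; empty output marks an unreadable input.
ob_canonical <- function(smiles) {
  vapply(smiles, function(s) {
    out <- ob_convert("SMI", "CAN", s)
    line <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
    if (is.na(line)) return(NA_character_)
    sub("\t.*$", "", trimws(line, which = "right"))
  }, character(1), USE.NAMES = FALSE)
}

# InChI text for a molecule. The ChemmineOB string bridge returns corrupted
# buffers for InChI strings that carry a stereo layer, so the output is
# validated and NA returned when it is not clean printable ASCII (callers
# fall back to another route).
ob_inchi <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(ob_convert("SMI", "INCHI", s), error = function(e) "")
    clean <- !is.na(out) && nzchar(out) &&
      !grepl("[^ -~\n\t]", out, useBytes = TRUE)
    if (!clean) return(NA_character_)
    line <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
    if (is.na(line) || !grepl("^InChI=", line)) NA_character_
    else trimws(line)
  }, character(1), USE.NAMES = FALSE)
}

# Apply f(molRef) to each molecule; explicit_h routes through an SDF with
# explicit hydrogens (needed for SMARTS patterns that use [#1]).
ob_each_mol <- function(smiles, f, explicit_h = FALSE) {
  if (explicit_h) {
    lapply(smiles, function(s) {
      sdf <- ob_convert("SMI", "SDF", s, add_h = TRUE)
      res <- ob_quiet(ChemmineOB::forEachMol("SDF", sdf, f))
      if (length(res) == 0)
        stop("Open Babel could not re-read molecule: ", s)
      res[[1]]
    })
  } else {
    lapply(smiles, function(s) {
      res <- ob_quiet(ChemmineOB::forEachMol("SMILES", s, f))
      if (length(res) == 0)
        stop("Open Babel could not read SMILES: ", s)
      res[[1]]
    })
  }
}

# Physicochemical property block (MW, logP, TPSA, MR, ...) per molecule.
ob_props <- function(smiles) {
  rows <- ob_each_mol(smiles, function(m) ChemmineOB::prop_OB(m))
  do.call(rbind, rows)
}

# Raw Open Babel fingerprint bit matrix (molecules x bits).
ob_fp_matrix <- function(smiles, type) {
  rows <- ob_each_mol(smiles, function(m) {
    as.integer(ChemmineOB::fingerprint_OB(list(m), type))
  })
  do.call(rbind, rows)
}

# Unique-match SMARTS counts; patterns vectorised. NA for unparseable SMARTS.
ob_smarts_count <- function(smiles, patterns, unique_matches = TRUE,
                            explicit_h = FALSE) {
  res <- ob_each_mol(smiles, function(m) {
    vapply(patterns, function(p) {
      tryCatch(
        as.integer(ChemmineOB::smartsSearch_OB(list(m), p,
                                               uniqueMatches = unique_matches)),
        error = function(e) NA_integer_)
    }, integer(1), USE.NAMES = FALSE)
  }, explicit_h = explicit_h)
  mat <- do.call(rbind, res)
  dimnames(mat) <- list(names(smiles), names(patterns))
  mat
}
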