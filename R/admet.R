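# Medicinal-chemistry profiling for the ensemble stage: five drug-likeness
# rule sets plus lead-likeness, two structural-alert catalogs (PAINS, Brenk)
# and the 0-8 composite prioritization score (one point per category without
# a violation or alert; larger = cleaner profile).
#
# Rule thresholds are fixed from the original publications and kept in one
# editable table (`adme_rulesets()`) so divergences from any web-service
# implementation are auditable. All rules are evaluated against this
# package's pinned descriptor implementations; numeric logP/TPSA flavours
# differ slightly between toolkits, which can move borderline compounds.

ADME_RULESETS <- list(
  lipinski = list(
    mw = c(-Inf, 500), clogp = c(-Inf, 5), hbd = c(0, 5), hba = c(0, 10)),
  ghose = list(
    mw = c(160, 480), clogp = c(-0.4, 5.6), molar_refractivity = c(40, 130),
    heavy_atoms = c(20, 70)),
  veber = list(
    rotatable_bonds = c(0, 10), tpsa = c(0, 140)),
  egan = list(
    clogp = c(-Inf, 5.88), tpsa = c(0, 131.6)),
  muegge = list(
    mw = c(200, 600), clogp = c(-2, 5), tpsa = c(0, 150),
    ring_count = c(0, 7), carbons = c(5, Inf), heteroatoms = c(2, Inf),
    rotatable_bonds = c(0, 15), hbd = c(0, 5), hba = c(0, 10)),
  leadlikeness = list(
    mw = c(250, 350), clogp = c(-Inf, 3.5), rotatable_bonds = c(0, 7))
)

#' Drug-likeness rule-set definitions
#'
#' @return the named list of rule sets; each rule set maps a descriptor name
#'   to its allowed `c(min, max)` band.
#' @export
adme_rulesets <- function() ADME_RULESETS

#' Count rule-set violations for one compound
#'
#' @param d a `descriptor_set` (from [descriptors()]).
#' @param ruleset one of `"lipinski"`, `"ghose"`, `"veber"`, `"egan"`,
#'   `"muegge"`, `"leadlikeness"`.
#' @return list with `violations` (count) and `failed` (character vector of
#'   failed criteria, `"descriptor=value not in [lo, hi]"`).
#' @examples
#' rule_violations(descriptors("CCO"), "lipinski")$violations  # 0
#' @export
rule_violations <- function(d, ruleset) {
  if (!ruleset %in% names(ADME_RULESETS))
    stop("unknown rule set: ", ruleset, call. = FALSE)
  rules <- ADME_RULESETS[[ruleset]]
  missing_d <- setdiff(names(rules), names(d))
  if (length(missing_d) > 0)
    stop("descriptor set lacks: ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  failed <- character()
  for (nm in names(rules)) {
    lo <- rules[[nm]][1]; hi <- rules[[nm]][2]
    v <- d[[nm]]
    if (is.na(v) || v < lo || v > hi)
      failed <- c(failed, sprintf("%s=%.4g not in [%.4g, %.4g]", nm, v, lo, hi))
  }
  list(violations = length(failed), failed = failed)
}

# ---- structural alert catalogs ------------------------------------------

alert_catalog_path <- function(catalog) {
  if (!catalog %in% c("pains", "brenk"))
    stop("unknown alert catalog: ", catalog, call. = FALSE)
  system.file("extdata", "alerts", paste0(catalog, ".tsv"),
              package = "polypharm", mustWork = TRUE)
}

#' Load a structural-alert catalog
#'
#' Catalogs ship as plain-text TSV (`smarts<TAB>label`): `"pains"` is the
#' published pan-assay-interference list (480 patterns) and `"brenk"` the
#' published set of 105 reactive / undesirable-moiety alerts.
#'
#' @param catalog `"pains"` or `"brenk"`.
#' @return data frame with columns `smarts`, `label`.
#' @export
alert_catalog <- function(catalog) {
  path <- alert_catalog_path(catalog)
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          col.names = c("smarts", "label"),
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0 || any(!nzchar(df$smarts)))
    stop("corrupt alert catalog: ", path, call. = FALSE)
  df
}

# Match one catalog pattern, handling dot-disconnected SMARTS (not supported
# by the Open Babel engine) by requiring each distinct component to reach its
# multiplicity in unique matches.
match_alert_pattern <- function(smiles, smarts) {
  if (!grepl(".", smarts, fixed = TRUE)) {
    cnt <- ob_smarts_count(smiles, smarts, unique_matches = TRUE,
                           explicit_h = TRUE)[1, 1]
    return(!is.na(cnt) && cnt > 0)
  }
  comps <- strsplit(smarts, ".", fixed = TRUE)[[1]]
  need <- table(comps)
  for (comp in names(need)) {
    cnt <- ob_smarts_count(smiles, comp, unique_matches = TRUE,
                           explicit_h = TRUE)[1, 1]
    if (is.na(cnt) || cnt < need[[comp]]) return(FALSE)
  }
  TRUE
}

#' Structural alerts matched by a molecule
#'
#' Matches the molecule (in explicit-hydrogen form, as several published
#' patterns reference explicit `[#1]` atoms) against every pattern of the
#' catalog and reports one label per matching pattern, in catalog order.
#'
#' @param mol a `mol_graph` or SMILES string.
#' @param catalog `"pains"` or `"brenk"`.
#' @return character vector of matched alert labels (possibly empty).
#' @examples
#' structural_alerts("C", "brenk")          # character(0)
#' @export
structural_alerts <- function(mol, catalog) {
  mol <- as_mol(mol)
  cat_df <- alert_catalog(catalog)
  simple <- !grepl(".", cat_df$smarts, fixed = TRUE)
  hits <- logical(nrow(cat_df))
  if (any(simple)) {
    counts <- ob_smarts_count(mol$smiles, cat_df$smarts[simple],
                              unique_matches = TRUE, explicit_h = TRUE)[1, ]
    hits[simple] <- !is.na(counts) & counts > 0
  }
  for (k in which(!simple))
    hits[k] <- match_alert_pattern(mol$smiles, cat_df$smarts[k])
  cat_df$label[hits]
}

#' Full ADME rule panel for one compound
#'
#' @param mol a `mol_graph` or SMILES string.
#' @param desc optional precomputed `descriptor_set`.
#' @return a `rule_panel_result`: per-rule-set violation counts, per-catalog
#'   alert labels.
#' @export
adme_panel <- function(mol, desc = NULL) {
  mol <- as_mol(mol)
  if (is.null(desc)) desc <- descriptors(mol)
  viol <- lapply(names(ADME_RULESETS), function(rs) rule_violations(desc, rs))
  names(viol) <- names(ADME_RULESETS)
  structure(list(
    smiles = mol$smiles,
    violations = vapply(viol, function(v) as.integer(v$violations),
                        integer(1)),
    failed = lapply(viol, `[[`, "failed"),
    alerts = list(pains = structural_alerts(mol, "pains"),
                  brenk = structural_alerts(mol, "brenk")),
    descriptors = desc),
    class = "rule_panel_result")
}

#' Composite ADME prioritization score
#'
#' One indicator per category - the six rule sets plus the two alert
#' catalogs - worth 1 when the category has zero violations/alerts, summed
#' to a 0-8 composite where larger means a cleaner profile.
#'
#' @param panel a `rule_panel_result` (from [adme_panel()]).
#' @return a `composite_score`: named 0/1 `indicators` and integer `total`.
#' @export
composite_adme_score <- function(panel) {
  stopifnot(inherits(panel, "rule_panel_result"))
  cats <- c(names(ADME_RULESETS), "pains", "brenk")
  ind <- stats::setNames(integer(length(cats)), cats)
  for (rs in names(ADME_RULESETS))
    ind[rs] <- as.integer(panel$violations[[rs]] == 0)
  ind["pains"] <- as.integer(length(panel$alerts$pains) == 0)
  ind["brenk"] <- as.integer(length(panel$alerts$brenk) == 0)
  structure(list(indicators = ind, total = as.integer(sum(ind))),
            class = "composite_score")
}

#' @export
print.composite_score <- function(x, ...) {
  cat(sprintf("<composite_score> %d/8 (%s)\n", x$total,
              paste(names(x$indicators)[x$indicators == 1], collapse = ", ")))
  invisible(x)
}

#' ADME summary table for a compound set
#'
#' One row per compound with the per-category violation/alert counts and the
#' composite score; ranking ties on the composite are broken by higher mean
#' cross-compound Tanimoto similarity and then identifier, for
#' reproducibility.
#'
#' @param mols named character vector of SMILES or list of `mol_graph`.
#' @return data frame sorted by decreasing composite score.
#' @export
adme_table <- function(mols) {
  nm <- mol_set_names(mols)
  mol_list <- as_mol_list(mols)
  if (is.null(nm)) nm <- paste0("cpd", seq_along(mol_list))
  rows <- lapply(seq_along(mol_list), function(i) {
    p <- adme_panel(mol_list[[i]])
    cs <- composite_adme_score(p)
    data.frame(compound = nm[i], smiles = p$smiles,
               lipinski_violations = p$violations[["lipinski"]],
               ghose_violations = p$violations[["ghose"]],
               veber_violations = p$violations[["veber"]],
               egan_violations = p$violations[["egan"]],
               muegge_violations = p$violations[["muegge"]],
               leadlikeness_violations = p$violations[["leadlikeness"]],
               pains_alerts = length(p$alerts$pains),
               brenk_alerts = length(p$alerts$brenk),
               composite_score = cs$total)
  })
  out <- do.call(rbind, rows)
  if (nrow(out) > 1) {
    tc <- similarity_matrix(mols, dialect = "path1024")
    diag(tc) <- NA
    out$mean_tc <- rowMeans(tc, na.rm = TRUE)
  } else {
    out$mean_tc <- NA_real_
  }
  out[order(-out$composite_score, -out$mean_tc, out$compound), , drop = FALSE]
}
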