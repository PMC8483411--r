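---
title: "Scoring multi-target kinase inhibitor candidates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring multi-target kinase inhibitor candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypharm)
```

# The evaluation model

A polypharmacology challenge asks for one molecule with a *profile*: bind a
set of pro-target kinases, avoid a set of anti-targets, and be a plausible
drug. `polypharm` encodes the whole evaluation as four layers:

1. **Binding calls** from a Kd selectivity panel. A pro-target is *bound*
   when Kd <= `pro_bind_nM` (default 10000 nM = 10 uM) and the measurement
   is not censored; an anti-target is *avoided* when the assay saw no hit
   up to its ceiling (censored, or Kd > `anti_avoid_nM` = 30000 nM). The
   interval (10, 30] uM is deliberately neither: such a compound shows
   measurable but weak binding, which neither earns binding points nor
   counts as clean avoidance. Both thresholds live in the rubric and can be
   changed there; the defaults reflect the common assay design of dose
   series starting at 30 uM.

2. **Rubric points.** Each criterion carries a point schedule over the
   number of satisfied targets, constrained to be non-decreasing. Bonus
   criteria are boolean: novelty (maximum ECFP6 Tanimoto against a
   reference-active collection strictly below 0.4), patentability (a
   supplied prior-art hit count below 2 - patent searches are an *input*,
   never a live query), drug-likeness (at least 3 of the 4 Lipinski
   criteria), and, in rubrics that include it, CNS penetration (TPSA
   strictly below 75 Angstrom^2).

3. **Similarity structure** of the submissions: duplicate top-ranked
   structures collapse under a canonical identity key; a Tanimoto matrix
   over 1024-bit path fingerprints feeds a thresholded network whose
   connected components are the candidate subfamilies.

4. **Medicinal-chemistry profile**: six published rule sets and two
   structural-alert catalogs, summarised as the 0-8 composite score (one
   point per clean category).

## The avoidance gate

One scoring rule deserves emphasis because the rubric table alone does not
state it: anti-target avoidance earns points **only when the compound binds
at least one pro-target**. Without this gate, a compound with an
all-censored panel (no measurable binding anywhere) would collect full
avoidance points, and every inert submission would outscore real but
imperfect binders. The published scoreboard behaves exactly as the gated
rule predicts: teams whose compounds bound nothing scored bonus-only totals
(7 per problem), not 7 plus avoidance. The gate also preserves the
monotonicity the suite checks: raising a pro-target's affinity never
lowers a score; adding an anti-target hit never raises it.

## Starred targets

Rubrics mark some targets as *requirements* (starred). The source table's
footnote is ambiguous about scope, and the printed team scores are not
mutually consistent under any single reading, so the engine implements both
defensible semantics and always reports which starred requirements failed:

* `per_criterion` (default): a starred target's own criterion simply scores
  as defined; stars are surfaced in the breakdown but do not zero other
  criteria.
* `gate_all`: any failed starred requirement zeroes *all* target-based
  points for that problem (bonuses are unaffected).

Because the engine exposes full per-criterion breakdowns, a reader can
recompute any aggregate under either reading; the package asserts worked
examples that are invariant to the choice rather than the ambiguous totals.

# Chemistry layer

Open Babel (via ChemmineOB) provides canonicalization, aromaticity
perception, the Wildman-Crippen logP and molar refractivity models, Ertl
TPSA, FP2 path fingerprints and ECFP4/ECFP6 circular fingerprints, and the
full SMARTS engine. Around it the package keeps a thin graph layer:

* `parse_smiles()` validates syntax itself (Open Babel silently accepts
  malformed strings such as `"C("`), reports the offending character
  position, canonicalizes, and rebuilds the atom/bond graph from the
  canonical SMILES. Atom indices therefore always refer to the canonical
  atom ordering, and identical structures give identical graphs however
  they were written.
* `canonical_key()` is the canonical SMILES: a collision-safe identity for
  deduplication that survives kekulized/aromatic rewrites and preserves
  stereo descriptors. The test suite cross-checks the induced identity
  relation against an independent canonicalizer (rdkit).
* Implicit hydrogens follow the standard valence model (B 3; C 4; N 3,5;
  O 2; P 3,5; S 2,4,6; halogens 1). Aromatic C/N in rings carry one extra
  valence unit for the pi system unless an explicit exocyclic double bond
  accounts for it; divalent aromatic heteroatoms (furan O, thiophene S) and
  pyrrole-type three-connected N contribute a lone pair instead. The
  brute-force molecular-weight oracle in the tests pins this model to
  within 0.01 Da on a structurally varied fixture set.
* `substructure_match()` returns explicit atom-index mappings for a
  documented SMARTS subset via DFS backtracking (a default bond matches
  single-or-aromatic, exactly as in SMARTS); recursive patterns go through
  the Open Babel engine (`smarts_count()`), which is also what the alert
  catalogs use. An exhaustive subgraph-enumeration oracle checks the
  matcher on small molecules.

## Fingerprint dialects

| dialect | backend | width | used for |
|---|---|---|---|
| `path1024` | FP2 (linear paths, depth 1-7) | 1024 | similarity matrices, networks, heatmaps |
| `ecfp4_2048` | ECFP4 (radius 2) | 2048 | general circular-fingerprint work |
| `ecfp6_2048` | ECFP6 (radius 3) | 2048 | the novelty criterion |

Open Babel emits ECFP bitsets at 4096 bits; they are folded to 2048 by
OR-ing the halves, the standard folding construction, so the dialect widths
are powers of two. Bits come from Open Babel's fixed hash, making bitsets
reproducible across runs and platforms; bit counts (not counts-per-feature)
are used throughout, as both fingerprint families are binary. The Tanimoto
of two all-zero fingerprints is defined as 1 (identical objects), with
`zero_zero = 0` available for the stricter convention. The path depth of
FP2 is fixed at 7 by the backend - the conventional depth for this
fingerprint family; narrower widths are available by folding, wider ones
are not (hashing cannot be undone).

## Descriptor conventions

HBD counts N/O atoms bearing at least one hydrogen and HBA counts all N/O
atoms - the original Lipinski counting conventions, chosen because the
drug-likeness rules calibrated against them; stricter pharmacophore
definitions would shift rule boundaries. One pinned logP implementation
(Wildman-Crippen, via Open Babel) feeds *all* rule sets; logP flavours
differ across toolkits by a few tenths, which can move borderline compounds
across Ghose/Egan bands - a known, documented source of divergence from any
web-service reimplementation. Ring count is the cyclomatic number
(SSSR size); rotatable bonds use the common strict-rotor SMARTS (acyclic
single bonds between non-terminal atoms, excluding triple-bond neighbours).
The Ghose atom-count band (20-70) is applied to heavy atoms.

## Alert catalogs

The PAINS catalog ships as the published 480-pattern WEHI list and the
Brenk catalog as the published 105-pattern reactive/undesirable-moiety
list, both as plain-text `smarts<TAB>label` files under
`inst/extdata/alerts/` so their provenance and any local edits are
auditable. Two implementation notes:

* Many PAINS patterns constrain explicit hydrogens (`[#1]`); molecules are
  therefore converted to their explicit-hydrogen form before matching.
* One Brenk pattern (`> 2 ester groups`) is a dot-disconnected SMARTS,
  which the Open Babel engine does not parse; it is evaluated by splitting
  on `.` and requiring each identical component to reach its multiplicity
  in unique matches.

# The synthetic-data generator

The generator exists so that every stage has a deterministic, downloadable-
from-nowhere test surface. It emulates the *shapes* of a real challenge:

* **Library**: three chemically distinct scaffold families (an
  anilino-quinazoline, an aliphatic piperidine-sulfonamide, and a
  flavone-like chromenone) decorated from family-specific substituent sets.
  By construction within-family path-fingerprint similarity is high and
  between-family similarity low (empirically: within Tc >= ~0.5, between
  <= ~0.3 at the default library size), which is what the 0.4 network
  threshold and the 0.4 novelty boundary need to be exercised on both
  sides.
* **Kd panels**: planted roles - *ideal* (binds every pro-target at ~100 nM,
  censored on all anti-targets), *near-miss* (binds exactly one pro-target
  at ~5 uM; the one-kinase-hit profile), *background* (censored everywhere
  except a configured fraction of dead-zone cells drawn in (10, 30] uM).
  Kd noise is multiplicative log-normal with sigma 0.2 log10 units,
  reflecting the fold-dilution structure of the assays; a draw that would
  cross its role's threshold is redrawn, so roles are invariants, not
  probabilities. Censoring uses the 30 uM assay ceiling.
* **Submissions**: per-team YAML files following the challenge template
  (up to 5 ranked compounds with vendor fields and rationale text), with an
  optional planted rank-1 duplicate written as two different SMILES strings
  of one structure (via an InChI or SDF round-trip) - the input the
  deduplication step exists for.
* **Reference actives**: drawn from one scaffold family, so same-family
  candidates fail the novelty criterion and other-family candidates pass.

Default study conditions: 10 teams, 5 compounds per team, a 50-compound
library, 90% background censoring, 12 reference actives. Every artifact
draws from its own named RNG stream derived from the master seed, so adding
an output never shifts the others, and equal configs yield byte-identical
files.

What the generator does **not** emulate: real medicinal-chemistry
diversity, assay noise correlations, dose-response curve shapes, or the
tail behaviour of public bioactivity databases. Tests passing on synthetic
instances demonstrate the *engine* is correct (calls, points, networks,
composites, determinism), not that any particular real compound would
score well.

# Numerical and design choices

* Threshold boundaries: Kd = 10000 nM binds; Kd = 30000 nM does not avoid;
  novelty fails at max Tc = 0.4 (strict <); network edges keep Tc =
  threshold (edges *below* the cutoff are filtered); cross-team pairs are
  strict (> threshold); CNS fails at TPSA = 75.
* The interactome bonus is 1 point: the value consistent with every
  published scoreboard row (e.g. 7 + 7 + 1 = 15 and 16 + 11 + 1 = 28);
  it is configurable.
* A rubric target missing from the panel is a hard error, never a silent
  skip; unreadable Kd cells name their row and column.
* Empty novelty reference sets pass vacuously but always warn.
* Degenerate molecules (single atoms, empty fingerprints) are defined
  inputs: descriptors and fingerprints never crash, and all-zero
  fingerprint pairs compare as identical.
* ADME ranking ties break by higher mean cross-compound similarity, then
  identifier - reproducible orderings everywhere.
* Component labels are deterministic (component containing the smallest
  node index first).
* Hold-out splits are by record by default, with optional stratification
  by class and an optional compound-disjoint mode (which of these the
  original hold-out used is unstated; the default is the simplest).

## Problem sizes in the test suite

The suite runs the full pipeline on instances of 15-50 compounds and 6-10
teams, fuzzes invariants with hundreds of random panels, and checks
censoring calibration on a 120-compound panel - sizes chosen so each
property is exercised well clear of its boundary while the whole suite
stays fast on a laptop.

# Known limitations

* Canonical identity is the Open Babel canonical SMILES; tautomers are
  distinct identities (InChI-style tautomer folding is out of scope).
* Descriptor values differ numerically from other toolkits' flavours
  (logP especially); rule-set verdicts near band edges can differ
  accordingly. All thresholds sit in one editable table
  (`adme_rulesets()`).
* `substructure_match()` covers a SMARTS subset (no recursion, no explicit
  `[H]` atom targets); the full engine is always available via
  `smarts_count()`.
* The published team totals that depend on supplementary per-compound
  tables and on the ambiguous starred-target footnote are not asserted;
  the engine exposes breakdowns instead.
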